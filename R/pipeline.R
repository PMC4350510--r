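#' Full study configuration
#'
#' Bundles the cohort and schedule configurations with the analysis
#' switches for an end-to-end reproduction run: which genotype codings to
#' analyse, the covariate for the discriminability ANCOVA, the
#' multiple-comparison correction, and the analytic power calculations to
#' report.
#'
#' @param cohort a [cohort_config()].
#' @param schedule a [schedule_config()].
#' @param codings genotype codings to analyse.
#' @param dprime_covariate subject covariate for the d' ANCOVA (`"age"` or
#'   `NULL`).
#' @param correction multiple-comparison correction for pairwise contrasts.
#' @param power_d effect sizes for the analytic power report (one-sided,
#'   dominant-model group sizes).
#' @param alpha significance level used in the power report.
#' @param exclusion_threshold earnings threshold (GBP) for inclusion.
#' @return an object of class `prt_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       schedule = schedule_config(),
                       codings = c("additive", "dominant"),
                       dprime_covariate = "age",
                       correction = "bonferroni",
                       power_d = c(0.38, 0.37),
                       alpha = 0.05,
                       exclusion_threshold = 5.00) {
  codings <- match.arg(codings, several.ok = TRUE)
  structure(list(cohort = cohort, schedule = schedule, codings = codings,
                 dprime_covariate = dprime_covariate,
                 correction = correction, power_d = power_d, alpha = alpha,
                 exclusion_threshold = exclusion_threshold),
            class = "prt_run_config")
}

#' Read a full run configuration from YAML
#'
#' Top-level keys `cohort` and `schedule` are nested mappings of
#' [cohort_config()] / [schedule_config()] arguments; the remaining keys are
#' [run_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `prt_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cohort)) {
    for (k in c("genotype_effect", "effect_scale", "genotype_counts"))
      if (!is.null(y$cohort[[k]])) y$cohort[[k]] <- unlist(y$cohort[[k]])
    args$cohort <- do.call(cohort_config, y$cohort)
  }
  if (!is.null(y$schedule))
    args$schedule <- do.call(schedule_config, y$schedule)
  for (k in setdiff(names(y), c("cohort", "schedule"))) {
    if (!k %in% names(formals(run_config)))
      stop("unknown run config key: ", k, call. = FALSE)
    args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

long_scores <- function(scored, cohort) {
  df <- merge(scored$blocks,
              as.data.frame(cohort)[, c("participant_id", "genotype",
                                        "risk_dose", "site", "age",
                                        "gender")],
              by = "participant_id")
  df[order(df$participant_id, df$block), ]
}

#' Run the full synthetic study
#'
#' Executes the whole pipeline: build the cohort, simulate one task session
#' per participant, apply the earnings-based exclusion, filter invalid
#' trials and score signal detection per block, then run the analysis
#' sequence: sample checks (Hardy-Weinberg, genotype x site and genotype x
#' gender contingency, age one-way ANOVA), age-discriminability correlation
#' at block 1, mixed ANCOVA on d' (age covariate), mixed ANOVA on criterion
#' under additive and dominant codings, per-block one-way ANOVAs, pairwise
#' corrected contrasts and Cohen's d on mean criterion, the dominant-model
#' independent t-test, a delta-response-bias one-way ANOVA, per-block
#' one-sample t-tests within each genotype group, and analytic power
#' calculations.  Fully reproducible from the configuration seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `cohort.csv`,
#'   `trial_log.csv`, `scores.csv`, `report.json` and `report.txt`.
#' @return object of class `prt_study`: list with `config`, `cohort`,
#'   `exclusions` (report data frame), `scores` (block and participant
#'   tables for included participants), `results` (named list of test
#'   objects), and `log` (stage counts).
#' @export
run_study <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "prt_run_config"))
  cohort <- build_cohort(config$cohort)
  sessions <- simulate_sessions(cohort, config$schedule)
  excl <- apply_earnings_exclusion(sessions, config$exclusion_threshold)
  sessions_in <- excl$included
  cohort_in <- cohort[cohort$participant_id %in% names(sessions_in), ]
  scored <- score_cohort_sessions(sessions_in)
  long <- long_scores(scored, cohort_in)
  parts <- merge(scored$participants,
                 as.data.frame(cohort_in)[, c("participant_id", "genotype",
                                              "site", "age", "gender")],
                 by = "participant_id")

  res <- list()
  counts <- table(factor(cohort_in$genotype, c("AA", "AG", "GG")))
  res$hwe <- hwe_chisq(counts[["AA"]], counts[["AG"]], counts[["GG"]])
  if (length(unique(cohort_in$site)) > 1)
    res$site_by_genotype <-
      contingency_chisq(table(cohort_in$site, cohort_in$genotype))
  if (length(unique(cohort_in$gender)) > 1)
    res$gender_by_genotype <-
      contingency_chisq(table(cohort_in$gender, cohort_in$genotype))
  res$age_by_genotype <- oneway_anova(parts$age, g = parts$genotype)
  b1 <- long[long$block == min(long$block), ]
  res$age_dprime_block1 <- age_association(b1$age, b1$d_prime)

  for (coding in config$codings) {
    long$grp <- genotype_coding(long$genotype, coding)
    res[[paste0("dprime_ancova_", coding)]] <-
      mixed_anova(long, value = "d_prime", group = "grp",
                  covariate = config$dprime_covariate)
    res[[paste0("criterion_anova_", coding)]] <-
      mixed_anova(long, value = "criterion", group = "grp")
  }

  for (b in sort(unique(long$block))) {
    lb <- long[long$block == b, ]
    res[[paste0("criterion_block", b, "_anova")]] <-
      oneway_anova(lb$criterion, g = genotype_coding(lb$genotype))
  }

  parts$grp_add <- genotype_coding(parts$genotype)
  res$criterion_pairwise <-
    pairwise_corrected(parts$mean_criterion, g = parts$grp_add,
                       method = config$correction)
  parts$grp_dom <- genotype_coding(parts$genotype, "dominant")
  res$criterion_dominant_t <-
    independent_t(parts$mean_criterion[parts$grp_dom == "AA/AG"],
                  parts$mean_criterion[parts$grp_dom == "GG"])
  res$delta_bias_anova <-
    oneway_anova(parts$delta_response_bias, g = parts$grp_add)
  res$delta_bias_pairwise <-
    pairwise_corrected(parts$delta_response_bias, g = parts$grp_add,
                       method = config$correction)

  for (gt in c("AA", "AG", "GG")) {
    for (b in sort(unique(long$block))) {
      v <- long$criterion[long$genotype == gt & long$block == b]
      if (length(v) >= 2)
        res[[paste0("bias_vs_zero_", gt, "_block", b)]] <- one_sample_t(v)
    }
  }

  n_dom <- table(parts$grp_dom)
  res$power <- lapply(config$power_d, function(d)
    power_two_sample(d, n_dom[["AA/AG"]], n_dom[["GG"]],
                     alpha = config$alpha, tails = "one-sided"))
  names(res$power) <- paste0("d=", config$power_d)

  study <- structure(
    list(config = config, cohort = cohort, exclusions = excl$report,
         scores = list(blocks = scored$blocks, participants = parts),
         results = res,
         log = list(n_simulated = nrow(cohort),
                    n_included = nrow(cohort_in),
                    n_excluded = nrow(cohort) - nrow(cohort_in),
                    n_trials = sum(vapply(sessions, function(s)
                      nrow(s$outcomes), numeric(1))),
                    n_valid_trials = sum(scored$blocks$n_valid))),
    class = "prt_study")
  if (!is.null(out_dir)) write_study(study, sessions_in, out_dir)
  study
}

htest_record <- function(x) {
  if (inherits(x, "prt_htest"))
    return(list(name = x$name, statistic_name = x$statistic_name,
                statistic = x$statistic, df = x$df, p_value = x$p_value,
                effect_size = x$effect_size, correction = x$correction))
  if (inherits(x, "prt_power"))
    return(list(name = "two-sample power", d = x$d, n1 = x$n1, n2 = x$n2,
                alpha = x$alpha, tails = x$tails, method = x$method,
                power = x$power))
  if (inherits(x, "prt_anova") || is.list(x))
    return(lapply(unclass(x), htest_record))
  x
}

write_study <- function(study, sessions, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(study$cohort, file.path(out_dir, "cohort.csv"))
  write_trial_log(sessions, file.path(out_dir, "trial_log.csv"))
  write_scores_csv(study$scores$blocks, file.path(out_dir, "scores.csv"))
  jsonlite::write_json(lapply(study$results, htest_record),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  txt <- utils::capture.output(print(study))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.prt_study <- function(x, ...) {
  cat("Probabilistic reward task synthetic study\n")
  cat(sprintf("  participants simulated %d, included %d, excluded %d\n",
              x$log$n_simulated, x$log$n_included, x$log$n_excluded))
  cat(sprintf("  trials %d, valid after RT filter %d\n",
              x$log$n_trials, x$log$n_valid_trials))
  cat("\nSample checks\n")
  for (nm in c("hwe", "site_by_genotype", "gender_by_genotype",
               "age_by_genotype", "age_dprime_block1"))
    if (!is.null(x$results[[nm]])) print(x$results[[nm]])
  for (nm in names(x$results)) {
    if (nm %in% c("hwe", "site_by_genotype", "gender_by_genotype",
                  "age_by_genotype", "age_dprime_block1", "power")) next
    obj <- x$results[[nm]]
    cat("\n[", nm, "]\n", sep = "")
    if (inherits(obj, "prt_htest") || inherits(obj, "prt_anova")) print(obj)
    else for (o in obj) print(o)
  }
  cat("\nPower\n")
  for (p in x$results$power) print(p)
  invisible(x)
}

#' Replicate the study and summarise key statistics
#'
#' Runs the full pipeline `n_reps` times with derived seeds and collects the
#' headline statistics of each replicate: the criterion mixed-ANOVA
#' between-group p-value (additive coding), the dominant-model t-test
#' p-value, Cohen's d for AA vs GG and for the dominant contrast.  Rejection
#' rates are reported with a binomial normal-approximation confidence
#' interval.
#'
#' @param config a [run_config()].
#' @param n_reps number of replicates (>= 1).
#' @param alpha significance level for rejection-rate summaries.
#' @return object of class `prt_replicates`: list with `stats` (one row per
#'   replicate) and `summary`.
#' @export
run_replicates <- function(config = run_config(), n_reps = 10, alpha = 0.05) {
  stopifnot(n_reps >= 1)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$cohort$rng_seed <- derive_seed(config$cohort$rng_seed, r,
                                       stream = 7L)
    st <- run_study(cfg)
    parts <- st$scores$participants
    # effect magnitudes reported as GG (nonrisk) minus risk group, the
    # direction in which the deficit is expressed, so both are positive
    # when the risk allele blunts response bias
    d_ag <- tryCatch(
      cohens_d(parts$mean_criterion[parts$genotype == "GG"],
               parts$mean_criterion[parts$genotype == "AA"]),
      error = function(e) NA_real_)
    d_dom <- tryCatch(
      cohens_d(parts$mean_criterion[parts$grp_dom == "GG"],
               parts$mean_criterion[parts$grp_dom == "AA/AG"]),
      error = function(e) NA_real_)
    rows[[r]] <- data.frame(
      replicate = r,
      p_between_additive =
        st$results$criterion_anova_additive$between$p_value,
      p_dominant_t = st$results$criterion_dominant_t$p_value,
      d_AA_vs_GG = d_ag,
      d_dominant = d_dom,
      n_included = st$log$n_included)
  }
  stats <- do.call(rbind, rows)
  rej <- function(p) {
    r <- mean(p < alpha, na.rm = TRUE)
    se <- sqrt(r * (1 - r) / sum(!is.na(p)))
    c(rate = r, lo = max(0, r - 1.96 * se), hi = min(1, r + 1.96 * se))
  }
  structure(list(
    stats = stats,
    summary = list(rejection_between_additive = rej(stats$p_between_additive),
                   rejection_dominant_t = rej(stats$p_dominant_t),
                   mean_d_AA_vs_GG = mean(stats$d_AA_vs_GG, na.rm = TRUE),
                   mean_d_dominant = mean(stats$d_dominant, na.rm = TRUE),
                   alpha = alpha, n_reps = n_reps)),
    class = "prt_replicates")
}

#' @export
print.prt_replicates <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Replicated study summary (%d replicates, alpha = %.3g)\n",
              s$n_reps, s$alpha))
  cat(sprintf("  between-group (additive) rejection rate %.3f [%.3f, %.3f]\n",
              s$rejection_between_additive["rate"],
              s$rejection_between_additive["lo"],
              s$rejection_between_additive["hi"]))
  cat(sprintf("  dominant-model t rejection rate %.3f [%.3f, %.3f]\n",
              s$rejection_dominant_t["rate"], s$rejection_dominant_t["lo"],
              s$rejection_dominant_t["hi"]))
  cat(sprintf("  mean Cohen's d: AA vs GG %.3f; dominant %.3f\n",
              s$mean_d_AA_vs_GG, s$mean_d_dominant))
  invisible(x)
}
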