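#' Cohort configuration for synthetic genotype-phenotype simulation
#'
#' Describes a cohort of simulated participants for the probabilistic reward
#' task: genotype frequencies at a biallelic locus near Hardy-Weinberg
#' equilibrium (risk-allele frequency about 0.33, as for CACNA1C rs1006737
#' in healthy European samples), demographics, and a reward-learning-rate
#' deficit graded by risk-allele dose.  The defaults are calibrated by Monte
#' Carlo (see the package vignette and `inst/calibration/`) so that large
#' simulated samples reproduce standardized effects of about d = 0.66 for
#' the AA-vs-GG contrast on mean criterion and d = 0.37 for the dominant
#' (AA/AG vs GG) contrast, with discriminability identical across genotypes.
#'
#' @param n_participants cohort size.
#' @param risk_allele_freq frequency of the risk (A) allele; genotypes AA,
#'   AG, GG are drawn with Hardy-Weinberg probabilities (p^2, 2pq, q^2).
#' @param genotype_counts optional named counts `c(AA=, AG=, GG=)`; when
#'   given they override Hardy-Weinberg sampling and fix the composition
#'   (useful to reproduce an observed sample such as 23/62/79).
#' @param genotype_effect named vector `c(AA=, AG=, GG=)` of mean
#'   reward-learning rates; must be non-increasing in risk-allele dose
#'   (GG >= AG >= AA).
#' @param learning_rate_sd common within-genotype SD of the learning rate
#'   (draws are truncated at 0).
#' @param baseline_bias_sd between-participant SD of the idiosyncratic
#'   starting response bias (the agent's starting decision threshold, z
#'   units); identical across genotypes, mean 0.
#' @param effect_scale named targets `c(d_AA_vs_GG=, d_dominant=)` the
#'   calibrated defaults aim at; stored for reporting.
#' @param sensitivity_mean,sensitivity_sd distribution of true
#'   discriminability, identical across genotypes (truncated below at 0.2).
#' @param age_mean,age_sd age distribution in years (truncated at 18).
#' @param gender_p_male probability of "M".
#' @param site_labels,site_probs recruitment sites and their proportions.
#' @param rng_seed integer seed; every participant derives a private
#'   sub-seed from it, so any one participant is individually reproducible.
#' @return an object of class `prt_cohort_config`.
#' @export
cohort_config <- function(n_participants = 164L,
                          risk_allele_freq = 0.33,
                          genotype_counts = NULL,
                          genotype_effect = c(AA = 0.0000, AG = 0.0068,
                                              GG = 0.0080),
                          learning_rate_sd = 0.0024,
                          baseline_bias_sd = 0.30,
                          effect_scale = c(d_AA_vs_GG = 0.66,
                                           d_dominant = 0.37),
                          sensitivity_mean = 1.0,
                          sensitivity_sd = 0.15,
                          age_mean = 22.3, age_sd = 4.4,
                          gender_p_male = 0.44,
                          site_labels = c("Bangor", "Cardiff"),
                          site_probs = c(0.79, 0.21),
                          rng_seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              risk_allele_freq = risk_allele_freq,
              genotype_counts = genotype_counts,
              genotype_effect = genotype_effect,
              learning_rate_sd = learning_rate_sd,
              baseline_bias_sd = baseline_bias_sd,
              effect_scale = effect_scale,
              sensitivity_mean = sensitivity_mean,
              sensitivity_sd = sensitivity_sd,
              age_mean = age_mean, age_sd = age_sd,
              gender_p_male = gender_p_male,
              site_labels = site_labels,
              site_probs = site_probs / sum(site_probs),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "prt_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$risk_allele_freq < 0 || cfg$risk_allele_freq > 1)
    stop("risk_allele_freq must lie in [0, 1]", call. = FALSE)
  ge <- cfg$genotype_effect
  if (!all(c("AA", "AG", "GG") %in% names(ge)))
    stop("genotype_effect must name AA, AG and GG", call. = FALSE)
  # deficit graded by risk dose: learning rate non-increasing in A copies
  if (ge[["GG"]] < ge[["AG"]] || ge[["AG"]] < ge[["AA"]])
    stop("genotype_effect must satisfy GG >= AG >= AA (reward-learning ",
         "deficit graded by risk-allele dose); the configured effect ",
         "targets are unreachable otherwise", call. = FALSE)
  if (!is.null(cfg$genotype_counts)) {
    gc <- cfg$genotype_counts
    if (!all(c("AA", "AG", "GG") %in% names(gc)) ||
        sum(gc) != cfg$n_participants)
      stop("genotype_counts must name AA, AG, GG and sum to n_participants",
           call. = FALSE)
  }
  if (cfg$learning_rate_sd < 0 || cfg$sensitivity_sd < 0 ||
      cfg$age_sd < 0 || cfg$baseline_bias_sd < 0)
    stop("spread parameters must be nonnegative", call. = FALSE)
  if (length(cfg$site_labels) != length(cfg$site_probs))
    stop("site_labels and site_probs must have equal length", call. = FALSE)
  invisible(cfg)
}

#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' Genotypes are drawn i.i.d. with probabilities (p^2, 2pq, q^2) for
#' (AA, AG, GG), where p is the risk-allele frequency.
#'
#' @param n number of individuals.
#' @param p_risk risk-allele frequency in [0, 1].
#' @param seed optional integer seed.
#' @return character vector of genotype labels.
#' @export
sample_genotypes <- function(n, p_risk, seed = NULL) {
  stopifnot(n >= 0, p_risk >= 0, p_risk <= 1)
  probs <- c(AA = p_risk^2, AG = 2 * p_risk * (1 - p_risk),
             GG = (1 - p_risk)^2)
  with_seed(seed, sample(names(probs), n, replace = TRUE, prob = probs))
}

risk_dose <- function(genotype) {
  unname(c(AA = 2L, AG = 1L, GG = 0L)[genotype])
}

rtrunc_norm <- function(n, mean, sd, lower) {
  pmax(lower, stats::rnorm(n, mean, sd))
}

#' Build a synthetic cohort
#'
#' Draws genotypes (Hardy-Weinberg, or fixed counts), demographics, and
#' per-participant agent parameters.  The reward-learning rate is drawn from
#' a genotype-specific mean with a common within-genotype spread (truncated
#' at 0); perceptual sensitivity is drawn from one distribution shared by
#' all genotypes, so the cohort encodes a reward-responsiveness deficit with
#' intact discriminability.  The rich stimulus is counterbalanced across
#' participants (alternating short/long by participant index).
#'
#' @param config a [cohort_config()].
#' @return a data frame of class `prt_cohort` with one row per participant:
#'   `participant_id`, `genotype`, `risk_dose`, `site`, `age`, `gender`,
#'   `learning_rate`, `sensitivity`, `baseline_bias`, `rich_stimulus`,
#'   `seed`; the configuration is attached as attribute `"config"`.
#' @export
build_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "prt_cohort_config"))
  validate_cohort_config(config)
  n <- config$n_participants
  with_seed(config$rng_seed, {
    genotype <- if (!is.null(config$genotype_counts)) {
      sample(rep(names(config$genotype_counts), config$genotype_counts))
    } else {
      sample_genotypes(n, config$risk_allele_freq)
    }
    lr_mean <- unname(config$genotype_effect[genotype])
    cohort <- data.frame(
      participant_id = sprintf("P%04d", seq_len(n)),
      genotype = genotype,
      risk_dose = risk_dose(genotype),
      site = sample(config$site_labels, n, replace = TRUE,
                    prob = config$site_probs),
      age = round(pmax(18, stats::rnorm(n, config$age_mean, config$age_sd))),
      gender = ifelse(stats::runif(n) < config$gender_p_male, "M", "F"),
      learning_rate = rtrunc_norm(n, lr_mean, config$learning_rate_sd, 0),
      sensitivity = rtrunc_norm(n, config$sensitivity_mean,
                                config$sensitivity_sd, 0.2),
      baseline_bias = stats::rnorm(n, 0, config$baseline_bias_sd),
      rich_stimulus = rep_len(c("short", "long"), n),
      seed = vapply(seq_len(n), function(i)
        derive_seed(config$rng_seed, i), integer(1)),
      stringsAsFactors = FALSE
    )
  })
  attr(cohort, "config") <- config
  class(cohort) <- c("prt_cohort", "data.frame")
  cohort
}

#' Simulate task sessions for a whole cohort
#'
#' Each participant gets an independently generated schedule (own sub-seed,
#' counterbalanced rich stimulus) and plays it with a learning agent built
#' from their row of the cohort table.
#'
#' @param cohort a [build_cohort()] result.
#' @param schedule_cfg base [schedule_config()]; the per-participant seed
#'   and rich stimulus are filled in from the cohort table.
#' @return named list of `prt_session` objects, names = participant ids.
#' @export
simulate_sessions <- function(cohort, schedule_cfg = schedule_config()) {
  stopifnot(inherits(cohort, "prt_cohort"))
  sessions <- vector("list", nrow(cohort))
  names(sessions) <- cohort$participant_id
  for (i in seq_len(nrow(cohort))) {
    scfg <- schedule_cfg
    scfg$rich_stimulus <- cohort$rich_stimulus[i]
    scfg$rng_seed <- derive_seed(cohort$seed[i], 1L, stream = 1L)
    sched <- generate_schedule(scfg)
    ag <- agent_params(perceptual_sensitivity = cohort$sensitivity[i],
                       reward_learning_rate = cohort$learning_rate[i],
                       criterion_start = cohort$baseline_bias[i])
    resp <- responder_agent(ag, seed = derive_seed(cohort$seed[i], 2L,
                                                   stream = 2L))
    sessions[[i]] <- run_session(sched, resp)
  }
  sessions
}

#' @export
print.prt_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants\n", nrow(x)))
  print(table(genotype = x$genotype))
  cat("mean learning rate by genotype:\n")
  print(round(tapply(x$learning_rate, x$genotype, mean), 4))
  invisible(x)
}

#' Write or read the cohort table
#'
#' Numeric columns are written with full (17 significant digit) precision so
#' the CSV round-trips exactly.
#'
#' @param cohort a `prt_cohort` (or compatible data frame).
#' @param path file path.
#' @return `read_cohort_csv` returns the data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (cl in names(df))
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "genotype", "risk_dose", "site", "age",
              "gender", "learning_rate", "sensitivity")
  if (!all(needed %in% names(df)))
    stop("cohort CSV must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a cohort configuration from YAML
#'
#' Accepts a YAML mapping whose keys are [cohort_config()] argument names
#' (`genotype_effect`, `effect_scale`, `genotype_counts` as nested
#' mappings); unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `prt_cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad) > 0)
    stop("unknown cohort config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in c("genotype_effect", "effect_scale", "genotype_counts"))
    if (!is.null(y[[k]])) y[[k]] <- unlist(y[[k]])
  do.call(cohort_config, y)
}
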