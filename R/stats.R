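new_htest <- function(name, statistic_name, statistic, df, p_value,
                      effect_size = NULL, correction = "none",
                      extra = NULL) {
  structure(list(name = name, statistic_name = statistic_name,
                 statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), effect_size = effect_size,
                 correction = correction, extra = extra),
            class = "prt_htest")
}

#' @export
print.prt_htest <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4, trim = TRUE), collapse = ", ")
  cat(sprintf("%s: %s(%s) = %.4g, p = %.4g", x$name, x$statistic_name, dfs,
              x$statistic, x$p_value))
  if (!is.null(x$effect_size))
    cat(sprintf(", %s = %.4g", names(x$effect_size)[1], x$effect_size[[1]]))
  if (!identical(x$correction, "none"))
    cat(sprintf(" [%s-corrected]", x$correction))
  cat("\n")
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Estimates the allele frequency from the genotype counts, forms expected
#' counts n * (p^2, 2pq, q^2), and tests goodness of fit with a Pearson
#' chi-square on 1 degree of freedom (3 genotype classes minus 1 minus 1
#' estimated allele frequency).
#'
#' @param n_AA,n_AG,n_GG observed genotype counts.
#' @return a `prt_htest` with the chi-square statistic, df = 1, p-value, and
#'   the estimated risk-allele frequency in `extra`.
#' @export
hwe_chisq <- function(n_AA, n_AG, n_GG) {
  stopifnot(n_AA >= 0, n_AG >= 0, n_GG >= 0)
  n <- n_AA + n_AG + n_GG
  if (n <= 0) stop("total count must be positive", call. = FALSE)
  p <- (2 * n_AA + n_AG) / (2 * n)
  if (p == 0 || p == 1)
    stop("monomorphic sample: Hardy-Weinberg test undefined", call. = FALSE)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(n_AA, n_AG, n_GG) - expected)^2 / expected)
  new_htest("Hardy-Weinberg equilibrium", "chisq", chisq, df = 1,
            p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
            extra = list(allele_freq = p, expected = expected))
}

#' Pearson chi-square test of independence
#'
#' No continuity correction is applied (matching reproducible printed
#' contingency checks).
#'
#' @param tab a counts matrix with at least 2 rows and 2 columns.
#' @return a `prt_htest`.
#' @export
contingency_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: chi-square test undefined", call. = FALSE)
  # asymptotic Pearson test by design; small-expected-count warnings are
  # not informative for the simulated tables this runs on
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_htest("contingency chi-square", "chisq",
            ct$statistic, df = ct$parameter, p_value = ct$p.value)
}

#' One-way analysis of variance
#'
#' `oneway_anova` takes raw per-group values; `oneway_anova_summary`
#' reconstructs the same decomposition from group sizes, means and standard
#' deviations (SS_within = sum (n_g - 1) s_g^2), as needed to check a
#' published descriptive table.  Partial eta squared is
#' SS_between / (SS_between + SS_within).
#'
#' @param groups list of numeric vectors (one per group), or a single
#'   numeric vector if `g` gives group labels.
#' @param g optional group labels parallel to `groups`.
#' @return a `prt_htest` with the F statistic, (k-1, N-k) df, p-value and
#'   partial eta squared.
#' @export
oneway_anova <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  stopifnot(is.list(groups), length(groups) >= 2)
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  oneway_anova_summary(ns, vapply(groups, mean, numeric(1)),
                       vapply(groups, stats::sd, numeric(1)))
}

#' @rdname oneway_anova
#' @param ns,means,sds per-group sizes, means and standard deviations.
#' @export
oneway_anova_summary <- function(ns, means, sds) {
  stopifnot(length(ns) == length(means), length(means) == length(sds),
            length(ns) >= 2, all(ns >= 2), all(sds >= 0))
  N <- sum(ns)
  k <- length(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0 && ssb == 0)
    stop("degenerate input: no variance between or within groups",
         call. = FALSE)
  if (ssw == 0)
    stop("zero within-group variance: F undefined", call. = FALSE)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  new_htest("one-way ANOVA", "F", F, df = c(k - 1, N - k),
            p_value = stats::pf(F, k - 1, N - k, lower.tail = FALSE),
            effect_size = c(partial_eta_sq = ssb / (ssb + ssw)))
}

#' Genotype group coding
#'
#' Additive coding keeps the three genotype groups (AA, AG, GG, i.e.
#' risk-allele dose 2/1/0); dominant coding pools risk-allele carriers
#' (AA and AG) against GG.
#'
#' @param genotype character vector of "AA"/"AG"/"GG".
#' @param scheme `"additive"` or `"dominant"`.
#' @return a factor of group labels.
#' @export
genotype_coding <- function(genotype, scheme = c("additive", "dominant")) {
  scheme <- match.arg(scheme)
  stopifnot(all(genotype %in% c("AA", "AG", "GG")))
  if (scheme == "additive") factor(genotype, levels = c("AA", "AG", "GG"))
  else factor(ifelse(genotype == "GG", "GG", "AA/AG"),
              levels = c("AA/AG", "GG"))
}

#' Mixed repeated-measures ANOVA / ANCOVA
#'
#' Classical univariate repeated-measures decomposition for a complete
#' design with one between-subjects factor (e.g. genotype group) and one
#' within-subjects factor (task block): between-subjects stratum
#' (group; subjects-within-groups error) and within-subjects stratum
#' (block; block x group; block x subjects error), each effect with F, df,
#' p and partial eta squared (SS_effect / (SS_effect + SS_error of its
#' stratum)).  Groups may be unbalanced; every subject must contribute every
#' block (no imputation).  With a covariate, the between-subjects stratum is
#' covariate-adjusted (analysis of covariance on subject means, covariate
#' entered first); no sphericity correction is applied.
#'
#' @param data long-format data frame.
#' @param value,subject,group,block column names (strings) of the response,
#'   subject id, between-group factor and within factor.
#' @param covariate optional column name of a subject-level covariate
#'   (e.g. age).
#' @param sphericity `"none"` (default) or `"greenhouse-geisser"`: with the
#'   latter, the within-subjects F tests keep their statistics but their
#'   degrees of freedom (and hence p-values) are multiplied by the
#'   Greenhouse-Geisser epsilon estimated from the pooled within-group
#'   covariance of the repeated measures.
#' @return object of class `prt_anova`: list of `prt_htest` results named
#'   `between`, `within`, `interaction` (and `covariate` when adjusted).
#' @export
mixed_anova <- function(data, value = "criterion", subject = "participant_id",
                        group = "group", block = "block", covariate = NULL,
                        sphericity = c("none", "greenhouse-geisser")) {
  sphericity <- match.arg(sphericity)
  y <- as.numeric(data[[value]])
  s <- as.character(data[[subject]])
  g <- as.character(data[[group]])
  b <- as.character(data[[block]])
  if (anyNA(y)) stop("missing response values", call. = FALSE)
  blocks <- sort(unique(b))
  k <- length(blocks)
  tab <- table(s, b)
  if (any(tab != 1L))
    stop("design must be complete: every subject exactly once per block",
         call. = FALSE)
  subj <- unique(data.frame(s = s, g = g, stringsAsFactors = FALSE))
  if (any(table(subj$g) < 2))
    stop("each group needs at least 2 subjects", call. = FALSE)
  ng <- table(subj$g)
  G <- length(ng)
  N <- nrow(subj)

  grand <- mean(y)
  m_subj <- tapply(y, s, mean)                       # subject means
  g_of_subj <- subj$g[match(names(m_subj), subj$s)]
  m_group <- tapply(m_subj, g_of_subj, mean)         # group means of means
  m_block <- tapply(y, b, mean)                      # block means (all N)
  cell <- tapply(y, list(g, b), mean)                # group x block means

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- k * sum((m_subj - grand)^2)
  ss_group <- k * sum(ng * (m_group - grand)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_block <- N * sum((m_block - grand)^2)
  # block and group are orthogonal here (proportional cell frequencies:
  # every subject contributes every block), so weighted cell-mean formulas
  # give the unique decomposition
  ss_int <- 0
  for (gi in names(ng)) for (bi in blocks)
    ss_int <- ss_int + ng[[gi]] *
      (cell[gi, bi] - m_group[[gi]] - m_block[[bi]] + grand)^2
  ss_within <- ss_total - ss_between_subj
  ss_werr <- ss_within - ss_block - ss_int

  df_block <- k - 1
  df_int <- (k - 1) * (G - 1)
  df_werr <- (N - G) * (k - 1)

  ftest <- function(name, ss, df1, ss_err, df_err, eps = 1) {
    F <- (ss / df1) / (ss_err / df_err)
    new_htest(name, "F", F, df = c(df1 * eps, df_err * eps),
              p_value = stats::pf(F, df1 * eps, df_err * eps,
                                  lower.tail = FALSE),
              effect_size = c(partial_eta_sq = ss / (ss + ss_err)))
  }

  eps <- 1
  if (sphericity == "greenhouse-geisser") {
    # pooled within-group covariance of the subject x block matrix
    Y <- matrix(y[order(match(s, names(m_subj)), b)], nrow = N, ncol = k,
                byrow = TRUE)
    Y <- do.call(rbind, lapply(split(seq_len(N), g_of_subj), function(i)
      scale(Y[i, , drop = FALSE], scale = FALSE)))
    S <- crossprod(Y) / (N - G)
    A <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    eps <- sum(diag(A))^2 / ((k - 1) * sum(A^2))
  }

  out <- list()
  if (is.null(covariate)) {
    out$between <- ftest("between-subjects (group)", ss_group, G - 1,
                         ss_subj_err, N - G)
  } else {
    cv <- tapply(as.numeric(data[[covariate]]), s, mean)
    cv <- cv[names(m_subj)]
    if (stats::var(cv) == 0)
      stop("covariate has zero variance", call. = FALSE)
    gf <- factor(g_of_subj)
    fit0 <- stats::lm(m_subj ~ cv)
    fit1 <- stats::lm(m_subj ~ cv + gf)
    rss0 <- sum(stats::resid(fit0)^2)
    rss1 <- sum(stats::resid(fit1)^2)
    ss_cov <- k * (sum((m_subj - mean(m_subj))^2) - rss0)
    ss_group_adj <- k * (rss0 - rss1)
    ss_err_adj <- k * rss1
    df_err <- N - G - 1
    out$covariate <- ftest("between-subjects covariate", ss_cov, 1,
                           ss_err_adj, df_err)
    out$between <- ftest("between-subjects (group, covariate-adjusted)",
                         ss_group_adj, G - 1, ss_err_adj, df_err)
  }
  out$within <- ftest("within-subjects (block)", ss_block, df_block,
                      ss_werr, df_werr, eps)
  out$interaction <- ftest("block x group interaction", ss_int, df_int,
                           ss_werr, df_werr, eps)
  attr(out, "gg_epsilon") <- if (sphericity == "greenhouse-geisser") eps
    else NULL
  structure(out, class = "prt_anova")
}

#' @export
print.prt_anova <- function(x, ...) {
  cat("Mixed repeated-measures ANOVA\n")
  for (nm in names(x)) print(x[[nm]])
  invisible(x)
}

#' One-sample t-test
#'
#' Two-sided by default; tests whether the mean differs from `null_mean`
#' (e.g. whether a genotype group's response bias differs from 0 at a
#' block).
#'
#' @param values numeric vector, n >= 2.
#' @param null_mean hypothesised mean.
#' @return a `prt_htest` with t, df = n - 1, p and Cohen's d
#'   (mean difference / SD).
#' @export
one_sample_t <- function(values, null_mean = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance: t undefined",
                                   call. = FALSE)
  tt <- stats::t.test(values, mu = null_mean)
  new_htest("one-sample t", "t", tt$statistic, df = tt$parameter,
            p_value = tt$p.value,
            effect_size = c(
              cohens_d = (mean(values) - null_mean) / stats::sd(values)))
}

#' Independent-samples t-test and Cohen's d
#'
#' Pooled-variance (Student) t-test, two-sided.  `cohens_d` is the mean
#' difference (group 1 minus group 2) divided by the pooled standard
#' deviation.
#'
#' @param g1,g2 numeric vectors, each n >= 2.
#' @return `independent_t`: a `prt_htest` (with Cohen's d as effect size);
#'   `cohens_d`: a number.
#' @export
independent_t <- function(g1, g2) {
  stopifnot(length(g1) >= 2, length(g2) >= 2)
  d <- cohens_d(g1, g2)
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  new_htest("independent-samples t", "t", tt$statistic, df = tt$parameter,
            p_value = tt$p.value, effect_size = c(cohens_d = d))
}

#' @rdname independent_t
#' @export
cohens_d <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance: d undefined", call. = FALSE)
  (mean(g1) - mean(g2)) / sqrt(sp2)
}

#' All pairwise group contrasts with multiplicity correction
#'
#' Independent-samples t-tests for every pair of groups, with Bonferroni
#' correction (raw p multiplied by the number of comparisons, capped at 1).
#'
#' @param groups list of numeric vectors (named by group), or a numeric
#'   vector with labels in `g`.
#' @param g optional group labels.
#' @param method correction method (only `"bonferroni"`).
#' @return list of `prt_htest`, one per pair, named "A vs B".
#' @export
pairwise_corrected <- function(groups, g = NULL, method = "bonferroni") {
  method <- match.arg(method, "bonferroni")
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  stopifnot(is.list(groups), length(groups) >= 2)
  nms <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2, simplify = FALSE)
  m <- length(pairs)
  out <- lapply(pairs, function(ij) {
    res <- independent_t(groups[[ij[1]]], groups[[ij[2]]])
    res$name <- paste(nms[ij[1]], "vs", nms[ij[2]])
    res$p_value <- min(1, res$p_value * m)
    res$correction <- method
    res
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Two-sample power analysis for a standardized mean difference
#'
#' Noncentral-t method: with noncentrality delta = d / sqrt(1/n1 + 1/n2)
#' and df = n1 + n2 - 2, power is the probability that the test statistic
#' exceeds the central-t critical value.  A normal-approximation method is
#' also available.
#'
#' @param d standardized effect size (Cohen's d), >= 0.
#' @param n1,n2 group sizes.
#' @param alpha significance level.
#' @param tails `"one-sided"` or `"two-sided"`.
#' @param method `"noncentral-t"` or `"normal-approximation"`.
#' @return object of class `prt_power`: list with the inputs and `power`.
#' @export
power_two_sample <- function(d, n1, n2, alpha = 0.05,
                             tails = c("one-sided", "two-sided"),
                             method = c("noncentral-t",
                                        "normal-approximation")) {
  tails <- match.arg(tails)
  method <- match.arg(method)
  stopifnot(n1 >= 2, n2 >= 2, d >= 0, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  delta <- d / sqrt(1 / n1 + 1 / n2)
  if (method == "noncentral-t") {
    if (tails == "one-sided") {
      crit <- stats::qt(1 - alpha, df)
      power <- stats::pt(crit, df, ncp = delta, lower.tail = FALSE)
    } else {
      crit <- stats::qt(1 - alpha / 2, df)
      power <- stats::pt(crit, df, ncp = delta, lower.tail = FALSE) +
        stats::pt(-crit, df, ncp = delta)
    }
  } else {
    if (tails == "one-sided") {
      power <- stats::pnorm(delta - stats::qnorm(1 - alpha))
    } else {
      z <- stats::qnorm(1 - alpha / 2)
      power <- stats::pnorm(delta - z) + stats::pnorm(-delta - z)
    }
  }
  structure(list(d = d, n1 = n1, n2 = n2, alpha = alpha, tails = tails,
                 method = method, df = df, delta = delta,
                 power = unname(power)),
            class = "prt_power")
}

#' @export
print.prt_power <- function(x, ...) {
  cat(sprintf(
    "Two-sample power (%s, %s): d = %.3g, n = (%d, %d), alpha = %.3g -> power = %.3f\n",
    x$method, x$tails, x$d, x$n1, x$n2, x$alpha, x$power))
  invisible(x)
}

#' Pearson correlation test
#'
#' Used for age-score association checks (e.g. age vs block-1
#' discriminability).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return a `prt_htest` with t statistic, df = n - 2, p and r as effect
#'   size.
#' @export
age_association <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y)
  new_htest("Pearson correlation", "t", ct$statistic, df = ct$parameter,
            p_value = ct$p.value, effect_size = c(r = unname(ct$estimate)))
}
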