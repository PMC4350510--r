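test_that("Hardy-Weinberg chi-square matches closed-form expectations", {
  res <- hwe_chisq(25, 50, 25)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)

  # brute-force expected counts from the combined genotype counts
  res <- hwe_chisq(23, 62, 79)
  p <- 108 / 328
  exp_counts <- 164 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  expect_equal(res$statistic, sum((c(23, 62, 79) - exp_counts)^2 / exp_counts))
  expect_equal(res$statistic, 3.41, tolerance = 0.005)

  res <- hwe_chisq(0, 100, 0)  # maximal heterozygote excess
  expect_equal(res$statistic, 100)

  expect_error(hwe_chisq(0, 0, 50), "monomorphic")
})

test_that("contingency chi-square has no continuity correction", {
  expect_equal(contingency_chisq(matrix(10, 2, 2))$statistic, 0)
  # genotype-by-site brute force from per-site counts
  tab <- rbind(c(16, 50, 64), c(7, 12, 15))
  res <- contingency_chisq(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_equal(res$df, 2)
  expect_equal(res$statistic, 1.54, tolerance = 0.005)
  # combined gender table reproduces the printed p-value
  res <- contingency_chisq(rbind(c(10, 33, 29), c(13, 30, 50)))
  expect_equal(round(res$p_value, 3), 0.174)
  expect_error(contingency_chisq(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("one-way ANOVA agrees with aov and its summary-statistics twin", {
  set.seed(21)
  g <- rep(c("a", "b", "c"), times = c(8, 11, 9))
  y <- rnorm(28) + (g == "c") * 0.8
  res <- oneway_anova(y, g = g)
  ref <- anova(lm(y ~ g))
  expect_equal(res$statistic, ref[["F value"]][1])
  expect_equal(res$p_value, ref[["Pr(>F)"]][1])
  # summary-statistics route reproduces the raw-data result
  gs <- split(y, g)
  res2 <- oneway_anova_summary(lengths(gs), sapply(gs, mean), sapply(gs, sd))
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$effect_size[["partial_eta_sq"]],
               res$effect_size[["partial_eta_sq"]])

  # identical groups: no between-group variance
  same <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(oneway_anova(same)$statistic, 0)
  expect_equal(oneway_anova(same)$p_value, 1)
  expect_error(oneway_anova(list(c(1, 1), c(2, 2))), "zero within")

  # published age summary: combined-sample one-way ANOVA
  res <- oneway_anova_summary(c(23, 62, 79), c(22.70, 22.21, 22.23),
                              c(3.698, 4.315, 4.717))
  expect_equal(res$p_value, 0.90, tolerance = 0.015)
})

test_that("two-group one-way ANOVA is the square of the pooled t", {
  set.seed(4)
  g1 <- rnorm(12)
  g2 <- rnorm(15, 0.5)
  fa <- oneway_anova(list(g1, g2))
  tt <- independent_t(g1, g2)
  expect_equal(fa$statistic, tt$statistic^2)
  expect_equal(fa$p_value, tt$p_value)
})

test_that("mixed ANOVA reproduces the aov() decomposition (balanced toy)", {
  # 3 groups x 2 subjects x 3 blocks
  df <- expand.grid(participant_id = paste0("s", 1:6), block = 1:3)
  df$grp <- rep(c("AA", "AG", "GG"), each = 2)[match(df$participant_id,
                                                     paste0("s", 1:6))]
  df$criterion <- c(1, 2, 3, 4, 5, 6,
                    2, 2, 4, 5, 7, 6,
                    1, 3, 5, 4, 8, 9)
  res <- mixed_anova(df, value = "criterion", group = "grp")
  ora <- rm_anova_oracle(df)
  expect_equal(res$between$statistic, ora$F_group)
  expect_equal(res$within$statistic, ora$F_block)
  expect_equal(res$interaction$statistic, ora$F_int)
  # partial eta^2 from the oracle's sums of squares
  expect_equal(res$between$effect_size[["partial_eta_sq"]],
               ora$ss_group / (ora$ss_group + ora$ss_subj_err))
  expect_equal(res$interaction$effect_size[["partial_eta_sq"]],
               ora$ss_int / (ora$ss_int + ora$ss_werr))
  expect_equal(res$between$df, c(2, 3))
  expect_equal(res$within$df, c(2, 6))
})

test_that("mixed ANOVA handles unbalanced groups and a covariate like aov", {
  set.seed(77)
  ns <- c(AA = 5, AG = 9, GG = 12)
  subj <- paste0("s", seq_len(sum(ns)))
  grp <- rep(names(ns), ns)
  age <- round(rnorm(sum(ns), 22, 4))
  df <- expand.grid(participant_id = subj, block = 1:3,
                    stringsAsFactors = FALSE)
  df$grp <- grp[match(df$participant_id, subj)]
  df$age <- age[match(df$participant_id, subj)]
  df$criterion <- rnorm(nrow(df)) + 0.1 * (df$grp == "GG") * df$block

  res <- mixed_anova(df, value = "criterion", group = "grp")
  ora <- rm_anova_oracle(df)
  expect_equal(res$between$statistic, ora$F_group)
  expect_equal(res$within$statistic, ora$F_block)
  expect_equal(res$interaction$statistic, ora$F_int)

  resc <- mixed_anova(df, value = "criterion", group = "grp",
                      covariate = "age")
  orac <- rm_anova_oracle(df, covariate = "age")
  expect_equal(resc$between$statistic, orac$F_group)
  expect_equal(resc$between$df, c(2, sum(ns) - 4))

  df_bad <- df[-1, ]
  expect_error(mixed_anova(df_bad, value = "criterion", group = "grp"),
               "complete")
  df2 <- df[df$participant_id %in% c("s1", "s6", "s7", "s15", "s16"), ]
  expect_error(mixed_anova(df2, value = "criterion", group = "grp"),
               "at least 2 subjects")
})

test_that("mixed ANOVA between-group effect grows with injected separation", {
  set.seed(10)
  base <- expand.grid(participant_id = paste0("s", 1:30), block = 1:3,
                      stringsAsFactors = FALSE)
  base$grp <- rep(c("A", "B", "C"), each = 10)[match(base$participant_id,
                                                     paste0("s", 1:30))]
  noise <- rnorm(nrow(base))
  eta <- vapply(c(0, 0.5, 1.5), function(shift) {
    base$criterion <- noise + shift * (base$grp == "C")
    mixed_anova(base, value = "criterion",
                group = "grp")$between$effect_size[["partial_eta_sq"]]
  }, numeric(1))
  expect_true(all(diff(eta) > 0))
  expect_true(all(eta >= 0 & eta <= 1))
  # gross separation
  base$criterion <- noise + 30 * (base$grp == "C")
  expect_lt(mixed_anova(base, value = "criterion",
                        group = "grp")$between$p_value, 1e-6)
})

test_that("one-sample t matches hand arithmetic", {
  res <- one_sample_t(c(1, 2, 3))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)))
  expect_equal(res$df, 2)
  sym <- c(-2, -1, 0, 1, 2)
  expect_equal(one_sample_t(sym)$statistic, 0)
  expect_equal(one_sample_t(sym)$p_value, 1)
  expect_error(one_sample_t(rep(3, 5)), "zero variance")
})

test_that("independent t and Cohen's d match hand arithmetic", {
  expect_equal(cohens_d(c(0, 1, 2), c(2, 3, 4)), -2)
  res <- independent_t(c(0, 1, 2), c(2, 3, 4))
  expect_equal(res$effect_size[["cohens_d"]], -2)
  set.seed(2)
  a <- rnorm(20); b <- rnorm(25, 0.3)
  tt <- t.test(a, b, var.equal = TRUE)
  res <- independent_t(a, b)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("pairwise contrasts apply Bonferroni correctly", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3) + 1e-9, c = c(1, 2, 3) - 1e-9)
  res <- pairwise_corrected(same)
  expect_length(res, 3)
  expect_true(all(vapply(res, `[[`, numeric(1), "p_value") == 1))

  set.seed(14)
  groups <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  res <- pairwise_corrected(groups)
  for (nm in names(res)) {
    ids <- strsplit(nm, " vs ")[[1]]
    raw <- independent_t(groups[[ids[1]]], groups[[ids[2]]])$p_value
    expect_equal(res[[nm]]$p_value, min(1, raw * 3))
    expect_gte(res[[nm]]$p_value, raw)
  }
})

test_that("noncentral-t power reproduces the design power calculations", {
  expect_equal(round(power_two_sample(0.38, 85, 79)$power, 2), 0.78)
  expect_equal(round(power_two_sample(0.37, 85, 79)$power, 2), 0.76)
  expect_equal(power_two_sample(0, 40, 40)$power, 0.05, tolerance = 1e-10)

  # monotone in d, n and alpha
  p_d <- vapply(c(0.1, 0.3, 0.5, 0.8), function(d)
    power_two_sample(d, 50, 50)$power, numeric(1))
  expect_true(all(diff(p_d) > 0))
  p_n <- vapply(c(10, 30, 90), function(n)
    power_two_sample(0.4, n, n)$power, numeric(1))
  expect_true(all(diff(p_n) > 0))
  p_a <- vapply(c(0.01, 0.05, 0.2), function(a)
    power_two_sample(0.4, 30, 30, alpha = a)$power, numeric(1))
  expect_true(all(diff(p_a) > 0))

  # normal approximation close to noncentral t at large df
  for (d in c(0.2, 0.4)) {
    expect_equal(power_two_sample(d, 60, 60)$power,
                 power_two_sample(d, 60, 60,
                                  method = "normal-approximation")$power,
                 tolerance = 0.01)
  }
  # two-sided power is lower than one-sided at the same alpha
  expect_lt(power_two_sample(0.38, 85, 79, tails = "two-sided")$power,
            power_two_sample(0.38, 85, 79)$power)
})

test_that("correlation test matches hand covariance arithmetic", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 3, 2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- age_association(x, y)
  expect_equal(res$effect_size[["r"]], r_hand)
  expect_equal(age_association(1:5, 2 * (1:5) + 3)$effect_size[["r"]], 1)
  expect_error(age_association(rep(1, 4), 1:4), "zero variance")
})

test_that("genotype codings nest correctly", {
  g <- c("AA", "AG", "GG", "AG", "GG")
  add <- genotype_coding(g)
  dom <- genotype_coding(g, "dominant")
  expect_equal(levels(add), c("AA", "AG", "GG"))
  expect_equal(levels(dom), c("AA/AG", "GG"))
  expect_true(all((dom == "GG") == (add == "GG")))
  expect_error(genotype_coding(c("AA", "AT")))
})

test_that("Greenhouse-Geisser correction is bounded and conservative", {
  set.seed(55)
  subj <- paste0("s", 1:24)
  df <- expand.grid(participant_id = subj, block = 1:3,
                    stringsAsFactors = FALSE)
  df$grp <- rep(c("A", "B"), each = 12)[match(df$participant_id, subj)]
  df$criterion <- rnorm(nrow(df)) + 0.4 * df$block
  plain <- mixed_anova(df, value = "criterion", group = "grp")
  gg <- mixed_anova(df, value = "criterion", group = "grp",
                    sphericity = "greenhouse-geisser")
  eps <- attr(gg, "gg_epsilon")
  expect_gte(eps, 1 / 2)      # lower bound 1/(k-1) with k = 3 blocks
  expect_lte(eps, 1)
  # same F, shrunken df, never smaller p
  expect_equal(gg$within$statistic, plain$within$statistic)
  expect_equal(gg$within$df, plain$within$df * eps)
  # conservative where it matters (the correction can only lower p when
  # F < 1, i.e. where nothing is near significance)
  expect_gte(gg$within$p_value, plain$within$p_value)
  if (gg$interaction$statistic > 1)
    expect_gte(gg$interaction$p_value, plain$interaction$p_value)
  # between-subjects stratum untouched by sphericity
  expect_equal(gg$between$p_value, plain$between$p_value)

  # grossly non-spherical data push epsilon toward the lower bound
  df$criterion <- rnorm(nrow(df), sd = ifelse(df$block == 3, 25, 0.1))
  gg2 <- mixed_anova(df, value = "criterion", group = "grp",
                     sphericity = "greenhouse-geisser")
  expect_lt(attr(gg2, "gg_epsilon"), 0.6)
})
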