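# Independent oracles used across test files.

# Standard normal quantile by Acklam's rational approximation plus one
# Halley refinement against pnorm(); independent of qnorm().
qnorm_oracle <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  a <- c(-3.969683028665376e+01, 2.209460984245205e+02,
         -2.759285104469687e+02, 1.383577518672690e+02,
         -3.066479806614716e+01, 2.506628277459239e+00)
  b <- c(-5.447609879822406e+01, 1.615858368580409e+02,
         -1.556989798598866e+02, 6.680131188771972e+01,
         -1.328068155288572e+01)
  c_ <- c(-7.784894002430293e-03, -3.223964580411365e-01,
          -2.400758277161838e+00, -2.549732539343734e+00,
          4.374664141464968e+00, 2.938163982698783e+00)
  d <- c(7.784695709041462e-03, 3.224671290700398e-01,
         2.445134137142996e+00, 3.754408661907416e+00)
  p_low <- 0.02425
  x <- vapply(p, function(pp) {
    if (pp < p_low) {
      q <- sqrt(-2 * log(pp))
      (((((c_[1] * q + c_[2]) * q + c_[3]) * q + c_[4]) * q + c_[5]) * q +
          c_[6]) / ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
    } else if (pp <= 1 - p_low) {
      q <- pp - 0.5
      r <- q * q
      (((((a[1] * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) * r +
          a[6]) * q /
        (((((b[1] * r + b[2]) * r + b[3]) * r + b[4]) * r + b[5]) * r + 1)
    } else {
      q <- sqrt(-2 * log(1 - pp))
      -(((((c_[1] * q + c_[2]) * q + c_[3]) * q + c_[4]) * q + c_[5]) * q +
          c_[6]) / ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
    }
  }, numeric(1))
  # Halley refinement (uses the normal CDF, not the quantile function)
  e <- pnorm(x) - p
  u <- e * sqrt(2 * pi) * exp(x^2 / 2)
  x - u / (1 + x * u / 2)
}

# Repeated-measures ANOVA oracle via base aov() + Error(subject); returns
# the sums of squares and F statistics per effect.
rm_anova_oracle <- function(df, value = "criterion", covariate = NULL) {
  df$subjf <- factor(df$participant_id)
  df$grpf <- factor(df$grp)
  df$blkf <- factor(df$block)
  fml <- if (is.null(covariate))
    stats::as.formula(paste(value, "~ grpf * blkf + Error(subjf)"))
  else
    stats::as.formula(paste(value, "~", covariate,
                            "+ grpf * blkf + Error(subjf)"))
  fit <- stats::aov(fml, data = df)
  s <- summary(fit)
  btab <- s[["Error: subjf"]][[1]]
  wtab <- s[["Error: Within"]][[1]]
  rn <- function(tab) trimws(rownames(tab))
  list(
    ss_group = btab[rn(btab) == "grpf", "Sum Sq"],
    F_group = btab[rn(btab) == "grpf", "F value"],
    ss_cov = if (is.null(covariate)) NULL else
      btab[rn(btab) == covariate, "Sum Sq"],
    ss_subj_err = btab[rn(btab) == "Residuals", "Sum Sq"],
    ss_block = wtab[rn(wtab) == "blkf", "Sum Sq"],
    F_block = wtab[rn(wtab) == "blkf", "F value"],
    ss_int = wtab[rn(wtab) == "grpf:blkf", "Sum Sq"],
    F_int = wtab[rn(wtab) == "grpf:blkf", "F value"],
    ss_werr = wtab[rn(wtab) == "Residuals", "Sum Sq"]
  )
}

# Minimal hand-built schedule object for scripted sessions.
toy_schedule <- function(stimulus, scheduled_reward, rich_stimulus = "short",
                         reward_value = 0.05) {
  n <- length(stimulus)
  cfg <- schedule_config(n_blocks = 1L,
                         trials_per_block = if (n %% 2 == 0) n else n + 1,
                         rewards_per_block = sum(scheduled_reward),
                         rich_rewards_per_block =
                           sum(scheduled_reward & stimulus == rich_stimulus),
                         lean_rewards_per_block =
                           sum(scheduled_reward & stimulus != rich_stimulus),
                         rich_stimulus = rich_stimulus,
                         reward_value = reward_value)
  structure(list(config = cfg,
                 trials = data.frame(block = 1L, trial = seq_len(n),
                                     stimulus = stimulus,
                                     is_rich = stimulus == rich_stimulus,
                                     scheduled_reward = scheduled_reward,
                                     stringsAsFactors = FALSE)),
            class = "prt_schedule")
}

responder_random <- function(seed) {
  set.seed(seed)
  responder(function(plan)
    list(response = sample(c("short", "long"), 1L), rt_ms = 500))
}
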