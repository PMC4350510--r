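make_outcomes <- function(stimulus, response, block = 1L) {
  data.frame(block = block, trial = seq_along(stimulus),
             stimulus = stimulus, response = response,
             rt_ms = 500, valid = TRUE, stringsAsFactors = FALSE)
}

test_that("trial classification partitions valid trials", {
  perfect <- make_outcomes(rep(c("short", "long"), each = 50),
                           rep(c("short", "long"), each = 50))
  cts <- classify_trials(perfect, "short")
  expect_equal(cts, list(hits = 50L, misses = 0L, false_alarms = 0L,
                         correct_rejections = 50L))

  const <- make_outcomes(rep(c("short", "long"), each = 50), rep("short", 100))
  cts <- classify_trials(const, "short")
  expect_equal(cts$hits, 50L)
  expect_equal(cts$false_alarms, 50L)

  # 8-trial hand count: 2 misses, 2 false alarms
  hand <- make_outcomes(c("short", "short", "short", "short",
                          "long", "long", "long", "long"),
                        c("short", "short", "long", "long",
                          "long", "long", "short", "short"))
  cts <- classify_trials(hand, "short")
  expect_equal(cts, list(hits = 2L, misses = 2L, false_alarms = 2L,
                         correct_rejections = 2L))
  expect_equal(Reduce(`+`, cts), 8L)

  one_sided <- make_outcomes(rep("short", 10), rep("short", 10))
  expect_error(classify_trials(one_sided, "short"), "zero valid trials")
})

test_that("log-linear correction gives the stated rates and stays in (0,1)", {
  r <- edge_corrected_rates(50, 50, 0, 50)
  expect_equal(r$H, 50.5 / 51)
  expect_equal(r$F, 0.5 / 51)
  r <- edge_corrected_rates(25, 50, 25, 50)
  expect_equal(r$H, 0.5)
  expect_equal(r$F, 0.5)
  r <- edge_corrected_rates(0, 10, 0, 10)
  expect_equal(r$H, 0.5 / 11)
  expect_equal(r$F, 0.5 / 11)
  for (h in c(0, 3, 10)) {
    r <- edge_corrected_rates(h, 10, 10 - h, 10)
    expect_true(r$H > 0 && r$H < 1 && r$F > 0 && r$F < 1)
  }
})

test_that("d-prime and reported criterion match the quantile oracle to 1e-9", {
  m <- sdt_measures(0.9, 0.4)
  expect_equal(m$d_prime, 1.5349, tolerance = 1e-4)
  expect_equal(m$criterion, 0.5141, tolerance = 1e-4)

  grid <- expand.grid(H = seq(0.05, 0.95, length.out = 11),
                      F = seq(0.05, 0.95, length.out = 9))
  for (i in seq_len(nrow(grid))) {
    m <- sdt_measures(grid$H[i], grid$F[i])
    zo <- qnorm_oracle(c(grid$H[i], grid$F[i]))
    expect_equal(m$d_prime, zo[1] - zo[2], tolerance = 1e-9)
    expect_equal(m$criterion, 0.5 * (zo[1] + zo[2]), tolerance = 1e-9)
  }
})

test_that("SDT identities: H=F gives zero d-prime, symmetry gives zero criterion", {
  for (v in c(0.1, 0.5, 0.77)) {
    expect_identical(sdt_measures(v, v)$d_prime, 0)
    expect_equal(sdt_measures(v, 1 - v)$criterion, 0)
  }
  expect_equal(sdt_measures(0.8, 0.2)$criterion, 0)
  expect_error(sdt_measures(1, 0.5), "strictly inside")
})

test_that("scores depend only on per-block counts, not trial order", {
  set.seed(31)
  stim <- rep(c("short", "long"), 30)
  resp <- sample(c("short", "long"), 60, replace = TRUE)
  o1 <- make_outcomes(stim, resp)
  perm <- sample(60)
  o2 <- o1[perm, ]
  s1 <- score_participant(o1, signal_stimulus = "short")
  s2 <- score_participant(o2, signal_stimulus = "short")
  expect_equal(s1$blocks, s2$blocks)
})

test_that("bias toward the rich response yields positive reported criterion", {
  stim <- rep(c("short", "long"), 30)
  # 90% rich ("short") responses irrespective of the stimulus
  biased <- ifelse(seq_along(stim) %% 10 == 0, "long", "short")
  s <- score_participant(make_outcomes(stim, biased),
                         signal_stimulus = "short")
  expect_gt(s$blocks$criterion, 0)
  anti <- ifelse(seq_along(stim) %% 10 == 0, "short", "long")
  s <- score_participant(make_outcomes(stim, anti),
                         signal_stimulus = "short")
  expect_lt(s$blocks$criterion, 0)
})

test_that("a hand-worked multi-block session scores exactly", {
  blocks <- list(
    list(hits = 8, fa = 4),   # 10 rich, 10 lean trials per block
    list(hits = 9, fa = 3),
    list(hits = 9, fa = 2))
  outs <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    k <- blocks[[b]]
    stim <- rep(c("short", "long"), each = 10)
    resp <- c(rep("short", k$hits), rep("long", 10 - k$hits),
              rep("short", k$fa), rep("long", 10 - k$fa))
    make_outcomes(stim, resp, block = b)
  }))
  # two invalid trials that must be ignored (they would change block 1)
  extra <- make_outcomes(c("short", "long"), c("long", "short"), block = 1L)
  extra$rt_ms <- c(100, 3200)
  extra$valid <- FALSE
  sc <- score_participant(rbind(outs, extra), signal_stimulus = "short")
  H <- (c(8, 9, 9) + 0.5) / 11
  F <- (c(4, 3, 2) + 0.5) / 11
  expect_equal(sc$blocks$d_prime, qnorm(H) - qnorm(F))
  expect_equal(sc$blocks$criterion, 0.5 * (qnorm(H) + qnorm(F)))
  expect_equal(sc$mean_criterion, mean(0.5 * (qnorm(H) + qnorm(F))))
  expect_equal(sc$delta_response_bias,
               0.5 * (qnorm(H[3]) + qnorm(F[3])) -
                 0.5 * (qnorm(H[1]) + qnorm(F[1])))
  expect_equal(sc$blocks$n_valid, rep(20L, 3))
})

test_that("perfect and chance performers hit the correction-imposed bounds", {
  perfect <- make_outcomes(rep(c("short", "long"), each = 50),
                           rep(c("short", "long"), each = 50))
  s <- score_participant(perfect, signal_stimulus = "short")
  expect_equal(s$blocks$d_prime, qnorm(50.5 / 51) - qnorm(0.5 / 51))
  expect_equal(s$blocks$criterion, 0)
  half <- make_outcomes(rep(c("short", "long"), 10),
                        rep(c("short", "long"), each = 10))
  s <- score_participant(half, signal_stimulus = "short")
  expect_equal(s$blocks$d_prime, 0)
})
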