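#' Classify trials into signal-detection outcome cells
#'
#' The signal category is the rich (more frequently reinforced) stimulus: a
#' hit is a rich-stimulus trial answered with the rich response and a false
#' alarm a lean-stimulus trial answered with the rich response, so that the
#' derived criterion measures bias toward the reinforced category.
#'
#' @param outcomes data frame of (valid) trial outcomes with `stimulus` and
#'   `response` columns.
#' @param signal_stimulus the stimulus treated as signal, `"short"` or
#'   `"long"` (normally the rich stimulus).
#' @return list with counts `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`; the four cells partition the trials.
#' @export
classify_trials <- function(outcomes, signal_stimulus) {
  stopifnot(is.data.frame(outcomes),
            signal_stimulus %in% c("short", "long"))
  is_sig <- outcomes$stimulus == signal_stimulus
  if (!any(is_sig) || all(is_sig))
    stop("cannot score a block with zero valid trials of either stimulus",
         call. = FALSE)
  said_sig <- outcomes$response == signal_stimulus
  list(hits = sum(is_sig & said_sig),
       misses = sum(is_sig & !said_sig),
       false_alarms = sum(!is_sig & said_sig),
       correct_rejections = sum(!is_sig & !said_sig))
}

#' Log-linear edge correction for hit and false-alarm rates
#'
#' The z-transform is undefined at rates of exactly 0 or 1, so rates are
#' computed with the log-linear correction, adding 0.5 to each count and 1 to
#' each trial total: H = (hits + 0.5) / (n_signal + 1).  The correction is
#' applied uniformly to every block (not only at the edges) so the estimator
#' stays continuous, and guarantees rates strictly inside (0, 1).
#'
#' @param hits,false_alarms outcome counts.
#' @param n_signal,n_noise valid signal- and noise-trial counts.
#' @return list with corrected rates `H` and `F`.
#' @export
edge_corrected_rates <- function(hits, n_signal, false_alarms, n_noise) {
  stopifnot(hits >= 0, false_alarms >= 0, hits <= n_signal,
            false_alarms <= n_noise, n_signal > 0, n_noise > 0)
  list(H = (hits + 0.5) / (n_signal + 1),
       F = (false_alarms + 0.5) / (n_noise + 1))
}

#' Discriminability and reported criterion
#'
#' Computes d' = z(H) - z(F) and the response-bias criterion, reported with
#' its sign reversed relative to the conventional c = -0.5 * (z(H) + z(F)):
#' `criterion = +0.5 * (z(H) + z(F))`, so that positive values represent a
#' stronger propensity to give the rich (signal) response.
#'
#' @param H,F hit and false-alarm rates, strictly inside (0, 1) (see
#'   [edge_corrected_rates()]).
#' @return list with `d_prime` and `criterion` (sign-reversed bias).
#' @export
sdt_measures <- function(H, F) {
  if (any(H <= 0 | H >= 1 | F <= 0 | F >= 1))
    stop("rates must lie strictly inside (0, 1); apply an edge correction",
         call. = FALSE)
  zH <- stats::qnorm(H)
  zF <- stats::qnorm(F)
  list(d_prime = zH - zF, criterion = 0.5 * (zH + zF))
}

score_block <- function(outcomes, signal_stimulus) {
  cts <- classify_trials(outcomes, signal_stimulus)
  n_sig <- cts$hits + cts$misses
  n_noise <- cts$false_alarms + cts$correct_rejections
  rates <- edge_corrected_rates(cts$hits, n_sig, cts$false_alarms, n_noise)
  m <- sdt_measures(rates$H, rates$F)
  data.frame(n_valid = nrow(outcomes), n_rich_trials = n_sig,
             n_lean_trials = n_noise, hits = cts$hits,
             false_alarms = cts$false_alarms, hit_rate = rates$H,
             fa_rate = rates$F, d_prime = m$d_prime, criterion = m$criterion)
}

#' Score a session: per-block signal detection and response-bias change
#'
#' Filters invalid trials, classifies each block against the rich stimulus,
#' applies the edge correction, and computes per-block d' and sign-reversed
#' criterion, the across-block means, and the development of response bias
#' over the task, `delta_response_bias` = criterion(last block) -
#' criterion(first block).
#'
#' @param session a `prt_session`, or a trial-outcome data frame including a
#'   `valid` column.
#' @param signal_stimulus stimulus treated as signal; defaults to the
#'   session's rich stimulus.
#' @return object of class `prt_scores`: list with `blocks` (one row per
#'   block: `block`, `n_valid`, counts, rates, `d_prime`, `criterion`),
#'   `mean_criterion`, `mean_d_prime`, `delta_response_bias`.
#' @export
score_participant <- function(session, signal_stimulus = NULL) {
  if (inherits(session, "prt_session")) {
    signal_stimulus <- signal_stimulus %||% session$config$rich_stimulus
    outcomes <- session$outcomes
  } else {
    outcomes <- session
    if (is.null(signal_stimulus))
      stop("signal_stimulus must be given when scoring a raw outcome table",
           call. = FALSE)
  }
  valid <- filter_trials(outcomes)
  blocks <- sort(unique(outcomes$block))
  per_block <- do.call(rbind, lapply(blocks, function(b) {
    cbind(data.frame(block = b),
          score_block(valid[valid$block == b, , drop = FALSE],
                      signal_stimulus))
  }))
  rownames(per_block) <- NULL
  out <- list(blocks = per_block,
              mean_criterion = mean(per_block$criterion),
              mean_d_prime = mean(per_block$d_prime),
              delta_response_bias =
                per_block$criterion[nrow(per_block)] - per_block$criterion[1])
  class(out) <- "prt_scores"
  out
}

#' @export
print.prt_scores <- function(x, ...) {
  cat("Signal-detection scores by block\n")
  print(x$blocks[, c("block", "n_valid", "hit_rate", "fa_rate", "d_prime",
                     "criterion")], digits = 4, row.names = FALSE)
  cat(sprintf("mean d' %.4f; mean criterion %.4f; delta response bias %.4f\n",
              x$mean_d_prime, x$mean_criterion, x$delta_response_bias))
  invisible(x)
}

#' Score many sessions into long and participant-level tables
#'
#' @param sessions named list of `prt_session` objects (names = participant
#'   ids).
#' @return list with `blocks` (participant x block rows: `participant_id`,
#'   `block`, `n_valid`, `hits`, `false_alarms`, `H`, `F`, `d_prime`,
#'   `criterion`) and `participants` (`participant_id`, `mean_criterion`,
#'   `mean_d_prime`, `delta_response_bias`, `earnings`, `included`).
#' @export
score_cohort_sessions <- function(sessions) {
  stopifnot(is.list(sessions), !is.null(names(sessions)))
  blocks <- list(); parts <- list()
  for (id in names(sessions)) {
    sc <- score_participant(sessions[[id]])
    b <- sc$blocks
    blocks[[id]] <- data.frame(participant_id = id, block = b$block,
                               n_valid = b$n_valid, hits = b$hits,
                               false_alarms = b$false_alarms,
                               H = b$hit_rate, F = b$fa_rate,
                               d_prime = b$d_prime, criterion = b$criterion,
                               stringsAsFactors = FALSE)
    parts[[id]] <- data.frame(participant_id = id,
                              mean_criterion = sc$mean_criterion,
                              mean_d_prime = sc$mean_d_prime,
                              delta_response_bias = sc$delta_response_bias,
                              earnings = sessions[[id]]$earnings,
                              included = sessions[[id]]$included,
                              stringsAsFactors = FALSE)
  }
  out <- list(blocks = do.call(rbind, blocks),
              participants = do.call(rbind, parts))
  rownames(out$blocks) <- rownames(out$participants) <- NULL
  out
}

#' Write or read the per-block scores table
#'
#' @param scores the `blocks` table from [score_cohort_sessions()].
#' @param path file path.
#' @return `read_scores_csv` returns the data frame.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
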