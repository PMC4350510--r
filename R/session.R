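#' Responder contract
#'
#' A responder maps each planned trial to a response and a reaction time, and
#' may update internal state when told whether the trial was rewarded.  It is
#' a list of class `prt_responder` with functions
#' `respond(plan)` returning `list(response = "short"|"long", rt_ms =
#' <milliseconds>)`, and optionally `feedback(response, rewarded)` called
#' after every trial (reward feedback is only ever delivered on correct
#' trials; `rewarded = FALSE` covers both no-feedback correct trials and all
#' incorrect trials).
#'
#' @param respond function of one argument (a one-row trial plan as a list
#'   with `block`, `trial`, `stimulus`, `is_rich`, `scheduled_reward`).
#' @param feedback optional function of `(response, rewarded)`.
#' @return an object of class `prt_responder`.
#' @export
responder <- function(respond, feedback = NULL) {
  stopifnot(is.function(respond), is.null(feedback) || is.function(feedback))
  structure(list(respond = respond, feedback = feedback),
            class = "prt_responder")
}

#' Built-in responders
#'
#' `responder_perfect()` always reports the true stimulus;
#' `responder_always_wrong()` always reports the other stimulus;
#' `responder_constant()` always gives the same response regardless of the
#' stimulus; `responder_scripted()` replays fixed response/RT sequences (used
#' for hand-traceable sessions).
#'
#' @param rt_ms reaction time attached to every response, in milliseconds.
#' @param response for `responder_constant`, the fixed response label.
#' @param responses,rts for `responder_scripted`, vectors consumed one trial
#'   at a time.
#' @return a [responder()].
#' @export
responder_perfect <- function(rt_ms = 500) {
  responder(function(plan) list(response = plan$stimulus, rt_ms = rt_ms))
}

#' @rdname responder_perfect
#' @export
responder_always_wrong <- function(rt_ms = 500) {
  responder(function(plan) {
    list(response = if (plan$stimulus == "short") "long" else "short",
         rt_ms = rt_ms)
  })
}

#' @rdname responder_perfect
#' @export
responder_constant <- function(response = "short", rt_ms = 500) {
  force(response)
  responder(function(plan) list(response = response, rt_ms = rt_ms))
}

#' @rdname responder_perfect
#' @export
responder_scripted <- function(responses, rts = rep(500, length(responses))) {
  stopifnot(length(responses) == length(rts))
  i <- 0L
  responder(function(plan) {
    i <<- i + 1L
    if (i > length(responses)) stop("scripted responder exhausted")
    list(response = responses[i], rt_ms = rts[i])
  })
}

#' Run a session of the probabilistic reward task
#'
#' Plays a schedule against a responder, applying the reward rules: feedback
#' is only ever given on correct trials; a trial delivers at most one reward;
#' a scheduled reward on a correct trial is delivered immediately; a
#' scheduled reward on an incorrect trial is postponed and delivered on a
#' later unreinforced correct trial of the same stimulus (scheduled rewards
#' take precedence over pending ones, and pending rewards carry across block
#' boundaries).  Earnings accumulate at `reward_value` per delivered reward.
#'
#' @param schedule a [generate_schedule()] result.
#' @param responder a [responder()].
#' @param inclusion_threshold minimum earnings (GBP) for the session to be
#'   flagged as included in analysis.
#' @return an object of class `prt_session`: list with `outcomes` (one row
#'   per trial: plan columns plus `response`, `correct`, `rt_ms`, `rewarded`,
#'   `reward_postponed`, `valid`), `earnings` (GBP),
#'   `pending_rewards_remaining` (per-stimulus counts of postponed rewards
#'   never delivered), `included`, and `config`.
#' @export
run_session <- function(schedule, responder, inclusion_threshold = 5.00) {
  stopifnot(inherits(schedule, "prt_schedule"),
            inherits(responder, "prt_responder"))
  trials <- schedule$trials
  n <- nrow(trials)
  response <- character(n)
  rt_ms <- numeric(n)
  correct <- logical(n)
  rewarded <- logical(n)
  postponed <- logical(n)
  pending <- c(short = 0L, long = 0L)
  for (i in seq_len(n)) {
    plan <- list(block = trials$block[i], trial = trials$trial[i],
                 stimulus = trials$stimulus[i], is_rich = trials$is_rich[i],
                 scheduled_reward = trials$scheduled_reward[i])
    ans <- responder$respond(plan)
    if (!is.list(ans) || is.null(ans$response) ||
        !ans$response %in% c("short", "long"))
      stop("responder contract violation: response must be \"short\" or ",
           "\"long\"", call. = FALSE)
    response[i] <- ans$response
    rt_ms[i] <- as.numeric(ans$rt_ms %||% NA_real_)
    correct[i] <- response[i] == plan$stimulus
    if (correct[i]) {
      if (plan$scheduled_reward) {
        rewarded[i] <- TRUE
      } else if (pending[[plan$stimulus]] > 0L) {
        rewarded[i] <- TRUE
        pending[[plan$stimulus]] <- pending[[plan$stimulus]] - 1L
      }
    } else if (plan$scheduled_reward) {
      pending[[plan$stimulus]] <- pending[[plan$stimulus]] + 1L
      postponed[i] <- TRUE
    }
    if (!is.null(responder$feedback))
      responder$feedback(response[i], rewarded[i])
  }
  outcomes <- cbind(trials,
                    data.frame(response = response, correct = correct,
                               rt_ms = rt_ms, rewarded = rewarded,
                               reward_postponed = postponed,
                               valid = rt_ms >= 200 & rt_ms <= 3000))
  earnings <- sum(rewarded) * schedule$config$reward_value
  out <- list(outcomes = outcomes,
              earnings = earnings,
              pending_rewards_remaining = pending,
              included = earnings >= inclusion_threshold,
              config = schedule$config)
  class(out) <- "prt_session"
  out
}

#' @export
print.prt_session <- function(x, ...) {
  cat("Probabilistic reward task session\n")
  cat(sprintf("  %d trials, %d rewarded; earnings GBP %.2f (%s)\n",
              nrow(x$outcomes), sum(x$outcomes$rewarded), x$earnings,
              if (x$included) "included" else "excluded"))
  cat(sprintf("  accuracy %.1f%%; valid trials %d; pending rewards undelivered: %d\n",
              100 * mean(x$outcomes$correct), sum(x$outcomes$valid),
              sum(x$pending_rewards_remaining)))
  invisible(x)
}

#' Remove trials with implausible reaction times
#'
#' Trials faster than 200 ms or slower than 3000 ms are removed before
#' scoring; exactly 200 ms and 3000 ms are retained (the cut is on strictly
#' faster/slower trials).  Order is preserved.
#'
#' @param outcomes a trial-outcome data frame (or a `prt_session`, whose
#'   outcomes are used).
#' @param min_rt,max_rt retention bounds in milliseconds, inclusive.
#' @return the retained rows, in the original order.
#' @export
filter_trials <- function(outcomes, min_rt = 200, max_rt = 3000) {
  if (inherits(outcomes, "prt_session")) outcomes <- outcomes$outcomes
  stopifnot(is.data.frame(outcomes), "rt_ms" %in% names(outcomes))
  if (nrow(outcomes) == 0L) return(outcomes)
  if (any(outcomes$rt_ms < 0, na.rm = TRUE))
    stop("reaction times must be nonnegative", call. = FALSE)
  keep <- !is.na(outcomes$rt_ms) &
    outcomes$rt_ms >= min_rt & outcomes$rt_ms <= max_rt
  outcomes[keep, , drop = FALSE]
}

#' Apply the earnings-based exclusion rule
#'
#' Participants who earn less than the threshold (GBP 5 by default, against a
#' GBP 6 maximum bonus) are excluded from analysis.
#'
#' @param sessions a list of `prt_session` objects (optionally named by
#'   participant id), or a numeric vector of earnings.
#' @param threshold minimum earnings (GBP) required for inclusion.
#' @return a list with `included` (the retained subset, same type as the
#'   input) and `report`, a data frame with `id`, `earnings`, `included`.
#' @export
apply_earnings_exclusion <- function(sessions, threshold = 5.00) {
  if (is.numeric(sessions)) {
    earnings <- sessions
    ids <- names(sessions) %||% as.character(seq_along(sessions))
  } else {
    stopifnot(is.list(sessions),
              all(vapply(sessions, inherits, logical(1), "prt_session")))
    earnings <- vapply(sessions, `[[`, numeric(1), "earnings")
    ids <- names(sessions) %||% as.character(seq_along(sessions))
  }
  keep <- earnings >= threshold
  report <- data.frame(id = ids, earnings = earnings, included = keep,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(included = sessions[keep], report = report)
}

#' Write or read a multi-participant trial log
#'
#' CSV with one row per trial and columns `participant_id`, `block`, `trial`,
#' `stimulus`, `is_rich`, `scheduled_reward`, `response`, `correct`, `rt_ms`,
#' `rewarded`, `valid`.
#'
#' @param sessions named list of `prt_session` objects; names are participant
#'   ids.
#' @param path file path.
#' @return `read_trial_log` returns the data frame.
#' @export
write_trial_log <- function(sessions, path) {
  stopifnot(is.list(sessions), !is.null(names(sessions)))
  cols <- c("block", "trial", "stimulus", "is_rich", "scheduled_reward",
            "response", "correct", "rt_ms", "rewarded", "valid")
  rows <- lapply(names(sessions), function(id) {
    cbind(data.frame(participant_id = id, stringsAsFactors = FALSE),
          sessions[[id]]$outcomes[, cols])
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "block", "trial", "stimulus", "is_rich",
              "scheduled_reward", "response", "correct", "rt_ms", "rewarded",
              "valid")
  if (!all(needed %in% names(df)))
    stop("trial log must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  for (cl in c("is_rich", "scheduled_reward", "correct", "rewarded", "valid"))
    df[[cl]] <- as.logical(df[[cl]])
  df
}
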