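#' Parameters of the drifting-criterion signal-detection learner
#'
#' The synthetic participant is a signal-detection observer with a decision
#' threshold that drifts in response to reward.  On each trial it draws a
#' percept from a unit-variance Gaussian centred at +s/2 (long) or -s/2
#' (short), where s = `perceptual_sensitivity` is the observer's true d',
#' and reports "long" iff the percept exceeds its current internal
#' threshold.  Whenever a response is rewarded the threshold moves by
#' `reward_learning_rate` toward that response category, so asymmetric
#' reinforcement produces a response bias without any change in
#' discriminability -- the dissociation the task is designed to measure.
#' Reaction times are lognormal, with small probabilities of an anticipatory
#' fast guess (< 200 ms) or an attentional lapse (> 3000 ms) that exercise
#' the trial-validity filter.
#'
#' @param perceptual_sensitivity true discriminability in d' units (> 0).
#' @param reward_learning_rate threshold shift per delivered reward, in z
#'   units of the percept axis.
#' @param criterion_start starting internal threshold (z units; 0 =
#'   unbiased).
#' @param criterion_decay proportional decay of the threshold toward
#'   `criterion_start` per trial (0 = no forgetting).
#' @param rt_log_mean,rt_log_sd lognormal reaction-time parameters
#'   (`meanlog`/`sdlog` of milliseconds).
#' @param fast_guess_rate probability a trial's RT is replaced by an
#'   anticipatory guess in [50, 200) ms.
#' @param lapse_rate probability a trial's RT is replaced by a lapse in
#'   (3000, 4500] ms.
#' @return an object of class `prt_agent_params`.
#' @export
agent_params <- function(perceptual_sensitivity = 1.0,
                         reward_learning_rate = 0.02,
                         criterion_start = 0,
                         criterion_decay = 0,
                         rt_log_mean = log(600),
                         rt_log_sd = 0.35,
                         fast_guess_rate = 0.02,
                         lapse_rate = 0.02) {
  stopifnot(perceptual_sensitivity > 0,
            criterion_decay >= 0, criterion_decay <= 1,
            fast_guess_rate >= 0, fast_guess_rate <= 1,
            lapse_rate >= 0, lapse_rate <= 1,
            fast_guess_rate + lapse_rate <= 1)
  structure(list(perceptual_sensitivity = perceptual_sensitivity,
                 reward_learning_rate = reward_learning_rate,
                 criterion_start = criterion_start,
                 criterion_decay = criterion_decay,
                 rt_log_mean = rt_log_mean, rt_log_sd = rt_log_sd,
                 fast_guess_rate = fast_guess_rate, lapse_rate = lapse_rate),
            class = "prt_agent_params")
}

#' Create mutable agent state
#'
#' @param params an [agent_params()].
#' @return an environment of class `prt_agent` holding the parameters and
#'   the current internal threshold.
#' @export
agent_state <- function(params = agent_params()) {
  stopifnot(inherits(params, "prt_agent_params"))
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$criterion <- params$criterion_start
  class(st) <- "prt_agent"
  st
}

#' One trial of the learning agent
#'
#' `agent_respond` draws a percept, compares it to the current threshold and
#' returns the response with a sampled reaction time (uses the current RNG
#' stream).  `agent_feedback` applies the reward-driven threshold update:
#' decay toward the starting point, then a shift of `reward_learning_rate`
#' toward the rewarded response category (downward for a rewarded "long",
#' upward for a rewarded "short").
#'
#' @param state an [agent_state()].
#' @param plan one-row trial plan (list with at least `stimulus`).
#' @param response,rewarded the trial's response and whether it was
#'   rewarded.
#' @return `agent_respond`: `list(response, rt_ms)`.
#' @export
agent_respond <- function(state, plan) {
  p <- state$params
  mu <- if (plan$stimulus == "long") p$perceptual_sensitivity / 2 else
    -p$perceptual_sensitivity / 2
  percept <- mu + stats::rnorm(1L)
  response <- if (percept > state$criterion) "long" else "short"
  rt <- stats::rlnorm(1L, p$rt_log_mean, p$rt_log_sd)
  u <- stats::runif(1L)
  if (u < p$fast_guess_rate) {
    rt <- stats::runif(1L, 50, 199)
  } else if (u < p$fast_guess_rate + p$lapse_rate) {
    rt <- stats::runif(1L, 3001, 4500)
  }
  list(response = response, rt_ms = rt)
}

#' @rdname agent_respond
#' @export
agent_feedback <- function(state, response, rewarded) {
  p <- state$params
  if (p$criterion_decay > 0)
    state$criterion <- p$criterion_start +
      (state$criterion - p$criterion_start) * (1 - p$criterion_decay)
  if (isTRUE(rewarded)) {
    shift <- if (response == "long") -p$reward_learning_rate else
      p$reward_learning_rate
    state$criterion <- state$criterion + shift
  }
  invisible(state)
}

#' Wrap the learning agent as a session responder
#'
#' @param params an [agent_params()].
#' @param seed optional integer seed; when given, the agent consumes its own
#'   reproducible random stream and the caller's RNG state is untouched.
#' @return a [responder()] suitable for [run_session()].
#' @export
responder_agent <- function(params = agent_params(), seed = NULL) {
  st <- agent_state(params)
  rng <- NULL
  if (!is.null(seed)) {
    # private RNG stream: keep the agent reproducible regardless of what
    # else draws random numbers between trials
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed %% 2147483647))
    rng <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }
  with_rng <- function(f) {
    if (is.null(rng)) return(f())
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", rng, envir = globalenv())
    out <- f()
    rng <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  responder(
    respond = function(plan) with_rng(function() agent_respond(st, plan)),
    feedback = function(response, rewarded)
      agent_feedback(st, response, rewarded)
  )
}
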