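#' Task/session configuration for the probabilistic reward task
#'
#' Defines the design constants of a session: three blocks of 100
#' line-discrimination trials in which the two stimuli ("short" and "long"
#' mouth) appear equally often in pseudo-random order, with 40 scheduled
#' rewards per block distributed asymmetrically -- 30 on the more frequently
#' reinforced ("rich") stimulus and 10 on the other ("lean") -- under
#' run-length caps: no more than `max_stimulus_run` successive trials of the
#' same stimulus and no more than `max_reward_run` consecutive scheduled
#' rewards.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block; must be even so that the two
#'   stimuli can appear exactly equally often.
#' @param rewards_per_block total scheduled rewards per block.
#' @param rich_rewards_per_block scheduled rewards on the rich stimulus.
#' @param lean_rewards_per_block scheduled rewards on the lean stimulus.
#' @param max_stimulus_run longest permitted run of identical stimuli.
#' @param max_reward_run longest permitted run of consecutively scheduled
#'   rewards.
#' @param rich_stimulus which stimulus is rich, `"short"` or `"long"`
#'   (counterbalanced across participants by the cohort tools).
#' @param reward_value monetary value of one reward, in GBP (5 pence).
#' @param rng_seed integer seed for schedule generation.
#' @return an object of class `prt_schedule_config`.
#' @seealso [generate_schedule()]
#' @export
schedule_config <- function(n_blocks = 3L,
                            trials_per_block = 100L,
                            rewards_per_block = 40L,
                            rich_rewards_per_block = 30L,
                            lean_rewards_per_block = 10L,
                            max_stimulus_run = 4L,
                            max_reward_run = 3L,
                            rich_stimulus = c("short", "long"),
                            reward_value = 0.05,
                            rng_seed = 1L) {
  rich_stimulus <- match.arg(rich_stimulus)
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    rewards_per_block = as.integer(rewards_per_block),
    rich_rewards_per_block = as.integer(rich_rewards_per_block),
    lean_rewards_per_block = as.integer(lean_rewards_per_block),
    max_stimulus_run = as.integer(max_stimulus_run),
    max_reward_run = as.integer(max_reward_run),
    rich_stimulus = rich_stimulus,
    reward_value = as.numeric(reward_value),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "prt_schedule_config"
  validate_schedule_config(cfg)
  cfg
}

validate_schedule_config <- function(cfg) {
  with(cfg, {
    if (n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
    if (trials_per_block < 2L || trials_per_block %% 2L != 0L)
      stop("trials_per_block must be even and >= 2 (equal stimulus frequency)",
           call. = FALSE)
    if (rich_rewards_per_block + lean_rewards_per_block != rewards_per_block)
      stop("rich_rewards_per_block + lean_rewards_per_block must equal ",
           "rewards_per_block", call. = FALSE)
    if (rewards_per_block > trials_per_block)
      stop("rewards_per_block cannot exceed trials_per_block", call. = FALSE)
    half <- trials_per_block %/% 2L
    if (rich_rewards_per_block > half || lean_rewards_per_block > half)
      stop("per-stimulus reward counts cannot exceed trials of that stimulus ",
           "per block (", half, ")", call. = FALSE)
    if (max_stimulus_run < 1L || max_reward_run < 1L)
      stop("run-length caps must be >= 1", call. = FALSE)
    if (half > max_stimulus_run * (half + 1L))
      stop("stimulus run cap unsatisfiable for this block length",
           call. = FALSE)
    n_unrewarded <- trials_per_block - rewards_per_block
    if (rewards_per_block > max_reward_run * (n_unrewarded + 1L))
      stop("reward run cap unsatisfiable: ", rewards_per_block,
           " rewards cannot be placed among ", trials_per_block,
           " trials without a run longer than ", max_reward_run,
           call. = FALSE)
    if (reward_value < 0) stop("reward_value must be nonnegative",
                               call. = FALSE)
  })
  invisible(cfg)
}

# Rejection-free constrained shuffle of a two-symbol sequence with a run cap.
# At each position a symbol is drawn uniformly among those whose placement
# leaves a completable remainder.  For two symbols the exact completability
# condition is a gap count: with `a` of A left, `b` of B left and a current
# run of A of length L, the A's fit iff a <= r*(b+1) - L and the B's iff
# b <= r*(a+1).
constrained_stimulus_order <- function(n_each, max_run) {
  syms <- c("short", "long")
  counts <- c(short = n_each, long = n_each)
  out <- character(2L * n_each)
  run_sym <- ""
  run_len <- 0L
  feasible <- function(cnt, rs, rl) {
    lead <- function(s) if (rs == s) rl else 0L
    cnt[["short"]] <= max_run * (cnt[["long"]] + 1L) - lead("short") &&
      cnt[["long"]] <= max_run * (cnt[["short"]] + 1L) - lead("long")
  }
  for (i in seq_along(out)) {
    cand <- syms[vapply(syms, function(s) {
      if (counts[[s]] == 0L) return(FALSE)
      if (s == run_sym && run_len >= max_run) return(FALSE)
      cnt <- counts
      cnt[[s]] <- cnt[[s]] - 1L
      feasible(cnt, if (s == run_sym) s else s,
               if (s == run_sym) run_len + 1L else 1L)
    }, logical(1))]
    if (length(cand) == 0L)
      stop("internal error: stimulus order construction reached a dead end")
    s <- if (length(cand) == 1L) cand else sample(cand, 1L)
    out[i] <- s
    counts[[s]] <- counts[[s]] - 1L
    if (s == run_sym) run_len <- run_len + 1L else { run_sym <- s; run_len <- 1L }
  }
  out
}

# Sample scheduled-reward positions (per-stimulus counts) and re-draw until
# no run of consecutive rewarded trials exceeds the cap.  Bounded retries:
# an unsatisfiable combination raises a configuration error rather than
# looping forever.
place_rewards <- function(stimulus, is_rich, n_rich_rw, n_lean_rw, max_run,
                          max_tries = 10000L) {
  rich_idx <- which(is_rich)
  lean_idx <- which(!is_rich)
  if (n_rich_rw > length(rich_idx) || n_lean_rw > length(lean_idx))
    stop("reward counts exceed available trials of that stimulus",
         call. = FALSE)
  for (try in seq_len(max_tries)) {
    rw <- logical(length(stimulus))
    rw[sample(rich_idx, n_rich_rw)] <- TRUE
    rw[sample(lean_idx, n_lean_rw)] <- TRUE
    if (longest_run(rw) <= max_run) return(rw)
  }
  stop("could not place ", n_rich_rw + n_lean_rw, " scheduled rewards with ",
       "run cap ", max_run, " in ", max_tries, " attempts; ",
       "configuration likely unsatisfiable", call. = FALSE)
}

#' Generate a constrained pseudo-random reinforcement schedule
#'
#' Builds the full planned session: per block, a stimulus order in which both
#' stimuli appear exactly equally often with no run of more than
#' `max_stimulus_run` identical stimuli, and scheduled-reward flags placing
#' `rich_rewards_per_block` rewards on rich-stimulus trials and
#' `lean_rewards_per_block` on lean-stimulus trials with no more than
#' `max_reward_run` consecutively rewarded trials.  Blocks are generated
#' independently; the run caps are enforced within each block.  Identical
#' configurations (including seed) yield identical schedules.
#'
#' @param config a [schedule_config()].
#' @return an object of class `prt_schedule`: a list with elements `config`
#'   and `trials`, the latter a data frame with one row per planned trial and
#'   columns `block`, `trial`, `stimulus`, `is_rich`, `scheduled_reward`.
#' @examples
#' sched <- generate_schedule(schedule_config(rng_seed = 42))
#' table(sched$trials$block, sched$trials$stimulus)
#' @export
generate_schedule <- function(config = schedule_config()) {
  stopifnot(inherits(config, "prt_schedule_config"))
  validate_schedule_config(config)
  half <- config$trials_per_block %/% 2L
  blocks <- with_seed(config$rng_seed, lapply(seq_len(config$n_blocks),
    function(b) {
      stim <- constrained_stimulus_order(half, config$max_stimulus_run)
      is_rich <- stim == config$rich_stimulus
      rw <- place_rewards(stim, is_rich,
                          config$rich_rewards_per_block,
                          config$lean_rewards_per_block,
                          config$max_reward_run)
      data.frame(block = b, trial = seq_along(stim), stimulus = stim,
                 is_rich = is_rich, scheduled_reward = rw,
                 stringsAsFactors = FALSE)
    }))
  sched <- list(config = config, trials = do.call(rbind, blocks))
  rownames(sched$trials) <- NULL
  class(sched) <- "prt_schedule"
  sched
}

#' @export
print.prt_schedule <- function(x, ...) {
  cfg <- x$config
  cat("Probabilistic reward task schedule\n")
  cat(sprintf("  %d block(s) x %d trials; rich stimulus: %s\n",
              cfg$n_blocks, cfg$trials_per_block, cfg$rich_stimulus))
  cat(sprintf("  scheduled rewards/block: %d (%d rich + %d lean) at GBP %.2f each\n",
              cfg$rewards_per_block, cfg$rich_rewards_per_block,
              cfg$lean_rewards_per_block, cfg$reward_value))
  cat(sprintf("  run caps: stimulus <= %d, reward <= %d; seed %d\n",
              cfg$max_stimulus_run, cfg$max_reward_run, cfg$rng_seed))
  invisible(x)
}

#' @export
as.data.frame.prt_schedule <- function(x, ...) x$trials

#' Write or read a schedule as CSV for audit
#'
#' One row per planned trial with columns `block`, `trial`, `stimulus`,
#' `is_rich`, `scheduled_reward`.
#'
#' @param schedule a `prt_schedule`.
#' @param path file path.
#' @return `read_schedule_csv` returns the trial-plan data frame.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "prt_schedule"))
  utils::write.csv(schedule$trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("block", "trial", "stimulus", "is_rich", "scheduled_reward")
  if (!all(needed %in% names(df)))
    stop("schedule CSV must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  df$is_rich <- as.logical(df$is_rich)
  df$scheduled_reward <- as.logical(df$scheduled_reward)
  df
}
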