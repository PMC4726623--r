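#' Adaptive reward-threshold state
#'
#' The salience threshold starts at 4.5. After each trial the 0/1 reward
#' indicator is appended to a 10-trial history window; whenever at least
#' `criterion_count` (3, i.e. 30%) of the last 10 trials were rewarded, the
#' threshold increases by `increment` (0.1) and the history is reset to
#' zeros. The threshold is therefore monotone non-decreasing:
#' theta = 4.5 + 0.1 * (number of criterion events so far).
#'
#' @param init Initial threshold (default 4.5).
#' @param increment Threshold increment (default 0.1).
#' @param history_len Reward-history window length (default 10).
#' @param criterion_count Rewards within the window needed to trigger an
#'   increment (default 3).
#' @return A list of class `threshold_state`.
#' @export
threshold_state <- function(init = 4.5, increment = 0.1, history_len = 10L,
                            criterion_count = 3L) {
  structure(list(theta = init, history = rep(0L, history_len),
                 increment = increment,
                 criterion_count = as.integer(criterion_count),
                 n_increments = 0L),
            class = "threshold_state")
}

#' Evaluate one trial against the reward threshold
#'
#' Reward is the strict inequality `S > theta` (a score exactly equal to the
#' threshold is not rewarded). The history is updated first, the criterion
#' tested, and on success the threshold incremented and the history reset,
#' so the next increment requires three new rewards.
#'
#' @param S Salience score of the trial's vocalization.
#' @param state A `threshold_state`.
#' @param trial_index Optional index recorded in the event.
#' @return List with `event` (fields `trial_index`, `r`, `S`,
#'   `theta_at_eval`) and the updated `state`.
#' @export
evaluate_trial <- function(S, state, trial_index = NA_integer_) {
  r <- as.integer(S > state$theta)
  event <- list(trial_index = trial_index, r = r, S = S,
                theta_at_eval = state$theta)
  state$history <- c(state$history[-1], r)
  if (sum(state$history) >= state$criterion_count) {
    state$theta <- state$theta + state$increment
    state$history[] <- 0L
    state$n_increments <- state$n_increments + 1L
  }
  list(event = event, state = state)
}

#' Yoked-control reward replayer
#'
#' Builds a reward source that delivers rewards at a fixed list of trial
#' indices (taken from a reference run in which rewards were salience-driven)
#' regardless of the yoked run's own salience. Salience is still computed and
#' logged for analysis.
#'
#' @param reward_trials Sorted integer trial indices at which to reward.
#' @param n_trials Run length; indices beyond it are an error.
#' @return A function `f(trial_index)` returning 0/1.
#' @export
yoked_replayer <- function(reward_trials, n_trials = Inf) {
  reward_trials <- as.integer(reward_trials)
  if (is.unsorted(reward_trials)) stop("reward trial indices must be sorted")
  if (length(reward_trials) &&
      (min(reward_trials) < 1 || max(reward_trials) > n_trials))
    stop("reward trial index out of range")
  set <- reward_trials
  function(trial_index) as.integer(trial_index %in% set)
}

#' Write / read a per-trial reward log
#'
#' The CSV columns (trial_index, S, theta, r) are both the run log format
#' and the input format for yoked replay.
#'
#' @param records Data frame with at least columns `trial_index`, `S`,
#'   `theta`, `r`.
#' @param path CSV path.
#' @return `path` invisibly (write) / the data frame (read).
#' @export
write_reward_log <- function(records, path) {
  utils::write.csv(records[, c("trial_index", "S", "theta", "r")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_reward_log
#' @export
read_reward_log <- function(path) {
  utils::read.csv(path)
}

#' Reward trial indices of a reference log
#'
#' @param log A reward-log data frame or CSV path.
#' @return Sorted integer trial indices with `r == 1`.
#' @export
rewarded_trials <- function(log) {
  if (is.character(log)) log <- read_reward_log(log)
  sort(log$trial_index[log$r == 1])
}
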