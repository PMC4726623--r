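#' Run configuration
#'
#' @param seed Master seed. Topology/reservoir weights, initial plastic
#'   weights, and the noise stream use fixed offsets of this seed, so the
#'   topology is reproducible independently of run length.
#' @param n_trials Number of 1-s trials (default 7200, i.e. 2 simulated
#'   hours; scaled runs simply lower this).
#' @param n_motor Motor-pool size in \{50, 100, 200\} (default 200); the
#'   output-neuron count is matched to it.
#' @param m Muscle scaling constant (default 2).
#' @param n_reservoir,n_inhibitory,fanout Reservoir geometry.
#' @param backend `"surrogate"` synthesizes audio internally;
#'   `"praat-script-export"` writes a synthesis script per sampled trial
#'   instead of audio (requires `output_dir`; salience/syllable fields are NA).
#' @param yoked_rewards `NULL` for salience-driven (adaptive-threshold)
#'   rewards, or an integer vector / reward-log CSV path of trial indices to
#'   replay (yoked control).
#' @param snapshot_every Trials between weight-matrix snapshots kept on the
#'   run object (`NULL`: only initial and final).
#' @param wav_sample_every Trials between saved example WAVs when
#'   `output_dir` is set (default 300 trials = 5 simulated minutes).
#' @param count_syllables Count syllable nuclei per trial (default `TRUE`).
#' @param output_dir Optional directory for the CSV log, config sidecar,
#'   snapshots, and sampled WAVs.
#' @param noise_amp Input-noise half-width in pA (default 6.5).
#' @param check_invariants Track weight-matrix invariants (nonnegativity,
#'   cap, post-normalization mean) at every update boundary.
#' @param plasticity A `plasticity_params`.
#' @param synth A `synth_config`.
#' @param nuclei A `nuclei_params`.
#' @param threshold A `threshold_state` to start from.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_trials = 7200L, n_motor = 200L, m = 2,
                       n_reservoir = 1000L, n_inhibitory = 200L,
                       fanout = 100L,
                       backend = c("surrogate", "praat-script-export"),
                       yoked_rewards = NULL, snapshot_every = NULL,
                       wav_sample_every = 300L, count_syllables = TRUE,
                       output_dir = NULL, noise_amp = 6.5,
                       check_invariants = FALSE,
                       plasticity = plasticity_params(),
                       synth = synth_config(),
                       nuclei = nuclei_params(),
                       threshold = threshold_state()) {
  backend <- match.arg(backend)
  stopifnot(n_trials >= 1, n_motor %% 2 == 0)
  if (is.character(yoked_rewards)) yoked_rewards <- rewarded_trials(yoked_rewards)
  structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                 n_motor = as.integer(n_motor), m = m,
                 n_reservoir = as.integer(n_reservoir),
                 n_inhibitory = as.integer(n_inhibitory),
                 fanout = as.integer(fanout), backend = backend,
                 yoked_rewards = yoked_rewards,
                 snapshot_every = snapshot_every,
                 wav_sample_every = wav_sample_every,
                 count_syllables = isTRUE(count_syllables),
                 output_dir = output_dir, noise_amp = noise_amp,
                 check_invariants = isTRUE(check_invariants),
                 plasticity = plasticity, synth = synth, nuclei = nuclei,
                 threshold = threshold),
            class = "run_config")
}

# Offsets separating the named random substreams derived from the master
# seed (kept well below .Machine$integer.max for 32-bit seeds).
SEED_OFFSET_WEIGHTS <- 1000003L
SEED_OFFSET_NOISE <- 2000003L

#' Initialize a simulation bundle
#'
#' Builds topology, plasticity state, membrane state and threshold state from
#' a config, and seeds the noise stream. The bundle is an environment so that
#' [run_trial()] can advance it in place.
#'
#' @param config A `run_config`.
#' @return An environment of class `babble_sim`.
#' @export
init_simulation <- function(config) {
  sim <- new.env(parent = emptyenv())
  sim$config <- config
  sim$topology <- build_network(
    seed = config$seed, n_reservoir = config$n_reservoir,
    n_inhibitory = config$n_inhibitory, n_output = config$n_motor,
    n_motor = config$n_motor, fanout = config$fanout)
  sim$plast <- init_plasticity(sim$topology,
                               seed = config$seed + SEED_OFFSET_WEIGHTS)
  sim$state <- init_network_state(sim$topology)
  sim$threshold <- config$threshold
  sim$reward_next <- FALSE
  sim$trial <- 0L
  sim$yoked <- if (!is.null(config$yoked_rewards))
    yoked_replayer(config$yoked_rewards, config$n_trials) else NULL
  sim$weights_initial <- sim$plast$s
  sim$invariants <- list(min_s = Inf, max_s_postcap = -Inf, max_meandev = 0,
                         n_norms = 0L)
  set.seed(config$seed + SEED_OFFSET_NOISE)   # noise stream for the run
  class(sim) <- c("babble_sim", class(sim))
  sim
}

#' Run one trial
#'
#' Simulates 1000 ms of network activity with per-ms plasticity bookkeeping
#' (delivering the previous trial's reward as a dopamine bump at the first
#' ms), smooths the motor rasters into the 900-ms muscle series, synthesizes
#' the 0.9-s vocalization, scores its salience, evaluates the reward
#' (adaptive threshold or yoked replay), and schedules the dopamine bump for
#' the next trial.
#'
#' @param sim A `babble_sim` environment from [init_simulation()]; advanced
#'   in place.
#' @return The trial record as a one-row data frame (also appended inside
#'   `sim`): trial_index, S, r, theta, syllable_count, muscle_mean,
#'   muscle_sd, dopamine_at_trial_end.
#' @export
run_trial <- function(sim) {
  config <- sim$config
  topo <- sim$topology
  sim$trial <- sim$trial + 1L
  t_start <- sim$state$t_ms + 1L

  res <- sim_trial_cpp(
    topo$targets, topo$tweights,
    topo$a, topo$b, topo$c, topo$d_reset,
    rep(topo$motor_params$a, topo$n_motor),
    rep(topo$motor_params$b, topo$n_motor),
    rep(topo$motor_params$c, topo$n_motor),
    rep(topo$motor_params$d_reset, topo$n_motor),
    topo$output_ids, length(topo$agonist_ids),
    sim$plast$s, sim$plast$e, sim$plast$c, sim$plast$d,
    sim$state$v_res, sim$state$u_res, sim$state$fired_res,
    sim$state$v_mot, sim$state$u_mot, sim$state$fired_mot,
    t_start, sim$reward_next, config$noise_amp,
    unclass(config$plasticity), 1000L, config$check_invariants)

  sim$plast$s <- res$s
  sim$plast$e <- res$e
  sim$plast$c <- res$ctrace
  sim$plast$d <- res$dopamine
  sim$state$v_res <- res$v_res; sim$state$u_res <- res$u_res
  sim$state$fired_res <- res$fired_res
  sim$state$v_mot <- res$v_mot; sim$state$u_mot <- res$u_mot
  sim$state$fired_mot <- res$fired_mot
  sim$state$t_ms <- res$t_end
  if (config$check_invariants) {
    inv <- res$invariants
    sim$invariants$min_s <- min(sim$invariants$min_s, inv$min_s)
    sim$invariants$max_s_postcap <- max(sim$invariants$max_s_postcap,
                                        inv$max_s_postcap)
    sim$invariants$max_meandev <- max(sim$invariants$max_meandev,
                                      inv$max_meandev)
    sim$invariants$n_norms <- sim$invariants$n_norms + inv$n_norms
  }

  ag <- smooth_spikes(res$agonist_raster, 100L)
  ant <- smooth_spikes(res$antagonist_raster, 100L)
  muscle <- net_muscle(ag, ant, config$m, trial_index = sim$trial)
  ms <- muscle_stats(muscle)

  if (config$backend == "surrogate") {
    wave <- synthesize_surrogate(muscle, config$synth)
    S <- salience_score(wave)
    syl <- if (config$count_syllables)
      count_nuclei(wave, config$nuclei) else NA_integer_
  } else {
    wave <- NULL
    S <- NA_real_
    syl <- NA_integer_
    if (!is.null(config$output_dir)) {
      export_praat_script(muscle, config$synth,
                          file.path(config$output_dir,
                                    sprintf("trial%06d.praat", sim$trial)))
    }
  }

  if (!is.null(sim$yoked)) {
    r <- sim$yoked(sim$trial)
    theta <- NA_real_
  } else if (is.na(S)) {
    # script-export backend: no audio, so no salience-driven reward
    r <- 0L
    theta <- NA_real_
  } else {
    ev <- evaluate_trial(S, sim$threshold, trial_index = sim$trial)
    sim$threshold <- ev$state
    r <- ev$event$r
    theta <- ev$event$theta_at_eval
  }
  sim$reward_next <- r == 1L
  sim$last_wave <- wave
  sim$last_muscle <- muscle

  data.frame(trial_index = sim$trial, S = S, r = r, theta = theta,
             syllable_count = syl, muscle_mean = ms[["mean"]],
             muscle_sd = ms[["sd"]], dopamine_at_trial_end = sim$plast$d)
}

#' Run a full simulation
#'
#' Loops [run_trial()] for `n_trials`, collecting one record per trial plus
#' initial/final (and optionally periodic) weight snapshots. With an
#' `output_dir`, also writes the per-trial CSV log, a JSON sidecar of the
#' resolved configuration, initial/final weight snapshot CSVs, and example
#' WAVs at `wav_sample_every`-trial intervals.
#'
#' @param config A `run_config`.
#' @return An object of class `babble_run`: list with `config`, `records`
#'   (data frame), `weights_initial`, `weights_final`, `snapshots`,
#'   `agonist_ids`, `antagonist_ids`, `invariants`, `reward_trials`.
#' @export
run_simulation <- function(config) {
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  sim <- init_simulation(config)
  records <- vector("list", config$n_trials)
  snapshots <- list()
  for (k in seq_len(config$n_trials)) {
    rec <- run_trial(sim)
    records[[k]] <- rec
    if (!is.null(config$snapshot_every) &&
        k %% config$snapshot_every == 0) {
      snapshots[[as.character(k)]] <- sim$plast$s
    }
    if (!is.null(out_dir) && config$backend == "surrogate" &&
        (k == 1L || k %% config$wav_sample_every == 0)) {
      write_wav(sim$last_wave,
                file.path(out_dir, sprintf("trial%06d.wav", k)))
    }
  }
  records <- do.call(rbind, records)
  run <- structure(list(
    config = config, records = records,
    weights_initial = sim$weights_initial, weights_final = sim$plast$s,
    snapshots = snapshots,
    agonist_ids = sim$topology$agonist_ids,
    antagonist_ids = sim$topology$antagonist_ids,
    invariants = sim$invariants,
    reward_trials = records$trial_index[records$r == 1]
  ), class = "babble_run")
  if (!is.null(out_dir)) {
    utils::write.csv(records, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    write_reward_log(records, file.path(out_dir, "rewards.csv"))
    write_weights(sim$weights_initial,
                  file.path(out_dir, "weights_initial.csv"))
    write_weights(sim$plast$s, file.path(out_dir, "weights_final.csv"))
    cfg <- config
    cfg$plasticity <- unclass(cfg$plasticity)
    cfg$synth <- NULL; cfg$nuclei <- NULL; cfg$threshold <- NULL
    jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.babble_run <- function(x, ...) {
  se <- try(start_end_summary(x$records), silent = TRUE)
  cat("<babble_run> ", nrow(x$records), " trials, ",
      length(x$reward_trials), " rewards\n", sep = "")
  if (!inherits(se, "try-error"))
    cat(sprintf("  salience: first-60 mean %.2f, last-60 mean %.2f\n",
                se[["start"]], se[["end"]]))
  invisible(x)
}

#' Serialize a plastic weight matrix
#'
#' Column-ordered CSV (rows = output neurons, columns = motor neurons).
#'
#' @param s Weight matrix.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(s, path) {
  utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  invisible(path)
}

#' Parameter sweep over motor-pool size and muscle scaling
#'
#' Runs every (n_motor, m) combination of the grid for each seed and
#' summarizes start (mean salience over the first 60 vocalizations) versus
#' end (last 60) per combination, with a paired t-test across seeds.
#'
#' @param grid Data frame with columns `n_motor` and `m`. The full study
#'   design uses the 13 combinations spanning n_motor in \{50, 100, 200\}
#'   and m in 2..8; see [sweep_grid()].
#' @param seeds Integer vector of seeds (one run per seed per combination).
#' @param n_trials Trials per run.
#' @param ... Further arguments passed to [run_config()].
#' @return A list with `summary` (one row per combination) and `runs`
#'   (nested list of `babble_run`s).
#' @export
run_sweep <- function(grid, seeds = 1:5, n_trials = 7200L, ...) {
  stopifnot(all(c("n_motor", "m") %in% names(grid)))
  runs <- list()
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    starts <- ends <- numeric(length(seeds))
    cell_runs <- list()
    for (j in seq_along(seeds)) {
      cfg <- run_config(seed = seeds[j], n_trials = n_trials,
                        n_motor = grid$n_motor[i], m = grid$m[i], ...)
      run <- run_simulation(cfg)
      se <- start_end_summary(run$records)
      starts[j] <- se[["start"]]
      ends[j] <- se[["end"]]
      cell_runs[[j]] <- run
    }
    key <- sprintf("n%d_m%g", grid$n_motor[i], grid$m[i])
    runs[[key]] <- cell_runs
    p <- if (length(seeds) > 1)
      stats::t.test(ends, starts, paired = TRUE,
                    alternative = "greater")$p.value else NA_real_
    rows[[i]] <- data.frame(
      n_motor = grid$n_motor[i], m = grid$m[i],
      start_mean = mean(starts), start_sd = stats::sd(starts),
      end_mean = mean(ends), end_sd = stats::sd(ends),
      p_paired_onesided = p)
  }
  list(summary = do.call(rbind, rows), runs = runs)
}

#' The 13-combination sweep grid
#'
#' @return Data frame of the 13 (n_motor, m) combinations of the full study
#'   design.
#' @export
sweep_grid <- function() {
  rbind(
    expand.grid(n_motor = c(50L, 100L, 200L), m = c(4, 5, 6)),
    data.frame(n_motor = 50L, m = c(7, 8)),
    data.frame(n_motor = 200L, m = c(2, 3))
  )
}
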