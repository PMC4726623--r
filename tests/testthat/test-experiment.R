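test_that("identical seed and config reproduce the run bit-for-bit", {
  cfg <- tiny_config(seed = 11, n_trials = 3)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$weights_final, r2$weights_final)
})

test_that("zero noise leaves the network silent and the output deterministic", {
  cfg <- tiny_config(seed = 3, n_trials = 2, noise_amp = 0,
                     count_syllables = FALSE)
  run <- run_simulation(cfg)
  expect_true(all(run$records$muscle_mean == 0))
  expect_true(all(run$records$muscle_sd == 0))
  expect_equal(run$records$S[1], run$records$S[2])
  run2 <- run_simulation(cfg)
  expect_identical(run$records$S, run2$records$S)
})

test_that("an empty yoked reward list keeps dopamine at zero", {
  cfg <- tiny_config(seed = 5, n_trials = 3, yoked_rewards = integer(0),
                     count_syllables = FALSE)
  run <- run_simulation(cfg)
  expect_true(all(run$records$dopamine_at_trial_end == 0))
  expect_true(all(run$records$r == 0))
  # without dopamine the weights change only via normalization
  expect_equal(mean(run$weights_final), 1, tolerance = 1e-9)
})

test_that("a yoked run consumes exactly its reference run's reward trials", {
  cfg <- tiny_config(seed = 21, n_trials = 12, count_syllables = FALSE,
                     threshold = threshold_state(init = 0.001))
  ref <- run_simulation(cfg)
  expect_gt(length(ref$reward_trials), 0)

  ycfg <- tiny_config(seed = 22, n_trials = 12, count_syllables = FALSE,
                      yoked_rewards = ref$reward_trials)
  yoked <- run_simulation(ycfg)
  expect_equal(which(yoked$records$r == 1), ref$reward_trials)
  expect_equal(length(yoked$reward_trials), length(ref$reward_trials))
  # replayed schedule, different spike dynamics
  expect_false(identical(yoked$records$S, ref$records$S))
})

test_that("the reservoir weights never change during a run", {
  cfg <- tiny_config(seed = 2, n_trials = 3, count_syllables = FALSE)
  sim <- init_simulation(cfg)
  before <- sim$topology$tweights
  for (k in 1:3) run_trial(sim)
  expect_identical(sim$topology$tweights, before)
})

test_that("run directories contain the log, config, snapshots, and audio", {
  out <- file.path(tempdir(), "babble-run-test")
  on.exit(unlink(out, recursive = TRUE))
  cfg <- tiny_config(seed = 6, n_trials = 10, output_dir = out,
                     wav_sample_every = 5, snapshot_every = 5,
                     count_syllables = FALSE)
  run <- run_simulation(cfg)
  expect_equal(nrow(run$records), 10)
  expect_true(file.exists(file.path(out, "trials.csv")))
  expect_true(file.exists(file.path(out, "config.json")))
  expect_true(file.exists(file.path(out, "weights_initial.csv")))
  expect_true(file.exists(file.path(out, "weights_final.csv")))
  expect_true(file.exists(file.path(out, "trial000005.wav")))
  expect_length(run$snapshots, 2)
  log <- utils::read.csv(file.path(out, "trials.csv"))
  expect_equal(nrow(log), 10)
  w <- as.matrix(utils::read.csv(file.path(out, "weights_final.csv")))
  expect_equal(unname(w), unname(run$weights_final), tolerance = 1e-12)
})

test_that("script-export backend writes synthesis scripts instead of audio", {
  out <- file.path(tempdir(), "babble-praat-test")
  on.exit(unlink(out, recursive = TRUE))
  cfg <- tiny_config(seed = 6, n_trials = 2, output_dir = out,
                     backend = "praat-script-export")
  run <- run_simulation(cfg)
  expect_true(file.exists(file.path(out, "trial000001.praat")))
  expect_true(all(is.na(run$records$S)))
  script <- readLines(file.path(out, "trial000001.praat"))
  expect_true(any(grepl("Interarytenoid", script)))
})

test_that("a single-cell sweep summarizes start and end salience", {
  grid <- data.frame(n_motor = 20L, m = 2)
  sw <- run_sweep(grid, seeds = c(1, 2), n_trials = 130,
                  n_reservoir = 100, n_inhibitory = 20, fanout = 10,
                  count_syllables = FALSE)
  expect_equal(nrow(sw$summary), 1)
  run <- sw$runs[["n20_m2"]][[1]]
  se <- start_end_summary(run$records)
  # independent recomputation from the records
  expect_equal(se[["start"]], mean(run$records$S[1:60]))
  expect_equal(se[["end"]], mean(run$records$S[71:130]))
  expect_equal(sw$summary$start_mean,
               mean(c(mean(sw$runs[["n20_m2"]][[1]]$records$S[1:60]),
                      mean(sw$runs[["n20_m2"]][[2]]$records$S[1:60]))))
})

test_that("the full sweep grid holds the 13 design combinations", {
  g <- sweep_grid()
  expect_equal(nrow(g), 13)
  expect_true(all(g$n_motor %in% c(50, 100, 200)))
  expect_equal(sum(g$n_motor == 200), 5)   # m = 2..6
  expect_equal(sum(g$n_motor == 50), 5)    # m = 4..8
})
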