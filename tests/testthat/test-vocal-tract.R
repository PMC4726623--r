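test_that("aperture trajectory maps activation to closure with clamping", {
  cfg <- synth_config()
  zero <- make_muscle_series("constant", value = 0)
  expect_equal(aperture_trajectory(zero, cfg), rep(0.5, 900))
  closed <- make_muscle_series("constant", value = 0.9)
  expect_equal(aperture_trajectory(closed, cfg), rep(0, 900))
  # sinusoid exceeding rest_aperture on known intervals touches 0 there
  x <- 0.5 + 0.3 * sin(2 * pi * 3 * (0:899) / 900)
  ap <- aperture_trajectory(x, cfg)
  expect_true(all(ap[x >= 0.5] == pmax(0.5 - x[x >= 0.5], 0)))
  expect_identical(which(ap == 0), which(x >= 0.5))
})

test_that("surrogate output is 0.9 s at 22050 Hz and deterministic", {
  m <- make_muscle_series("sine", amplitude = 0.2, periods = 3)
  w1 <- synthesize_surrogate(m)
  w2 <- synthesize_surrogate(m)
  expect_length(w1, 19845)
  expect_identical(as.numeric(w1), as.numeric(w2))
  expect_true(all(abs(w1) <= 1))
  expect_true(all(is.finite(w1)))
})

test_that("full closure silences the surrogate", {
  closed <- make_muscle_series("constant", value = 1)
  w <- synthesize_surrogate(closed)
  expect_lt(sqrt(mean(w^2)), 1e-6)
})

test_that("more closure means less sound for constant sub-closure muscle", {
  rms <- function(v) sqrt(mean(synthesize_surrogate(
    make_muscle_series("constant", value = v))^2))
  expect_gt(rms(0.1), rms(0.3))
  expect_gt(rms(0.3), rms(0.45))
})

test_that("closure episodes produce alternating bursts the counter sees", {
  m <- make_closure_series(3)
  w <- synthesize_surrogate(m)
  expect_equal(count_nuclei(w), 3)
  # amplitude alternation only when the aperture crosses closure
  open <- make_closure_series(0)
  w_open <- synthesize_surrogate(open)
  env_zero_runs <- function(w) {
    # count silent gaps longer than 20 ms
    env <- abs(w) > 1e-8
    r <- rle(env[2206:19845])   # skip the pre-voicing onset
    sum(!r$values & r$lengths > 0.02 * 22050)
  }
  expect_equal(env_zero_runs(w), 3)
  expect_equal(env_zero_runs(w_open), 0)
})

test_that("exported synthesis script carries the fixed articulatory settings", {
  zero <- make_muscle_series("constant", value = 0)
  script <- export_praat_script(zero)
  expect_true(any(grepl("Create Speaker... speaker Female", script,
                        fixed = TRUE)))
  expect_true(any(grepl("0.500000 Interarytenoid", script, fixed = TRUE)))
  expect_true(any(grepl("0.400000 Hyoglossus", script, fixed = TRUE)))
  lungs <- grep("Lungs$", script, value = TRUE)
  expect_equal(lungs, c("Set target... 0.000000 0.100000 Lungs",
                        "Set target... 0.020000 0.100000 Lungs",
                        "Set target... 0.050000 0.000000 Lungs",
                        "Set target... 0.900000 0.000000 Lungs"))
  mas <- grep("Masseter$", script, value = TRUE)
  orb <- grep("OrbicularisOris$", script, value = TRUE)
  expect_length(mas, 900)
  expect_identical(sub("Masseter$", "", mas), sub("OrbicularisOris$", "", orb))
  expect_true(all(grepl(" 0.000000 ", mas, fixed = TRUE)))

  # byte-stable across calls and via file
  path1 <- tempfile(fileext = ".praat")
  path2 <- tempfile(fileext = ".praat")
  m <- make_muscle_series("sine", amplitude = 0.3, periods = 2)
  export_praat_script(m, path = path1)
  export_praat_script(m, path = path2)
  expect_identical(readBin(path1, "raw", file.size(path1)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("WAV files round-trip through the PCM writer and reader", {
  m <- make_closure_series(2)
  w <- synthesize_surrogate(m)
  path <- tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(attr(back, "sample_rate"), 22050)
  expect_length(back, length(w))
  expect_lt(max(abs(as.numeric(back) - as.numeric(w))), 1 / 32767 + 1e-9)
})
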