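test_that("noise-free single-beat trace spans exactly the amplitude", {
  spec <- transient_sim_spec(pacing_frequencies = 1, min_stimulations = 1,
                             min_duration_s = 0, amplitude = 0.5,
                             noise_sd = 0)
  g <- gen_transient_trace(spec)
  x <- get_channel(g$recording, "fura_ratio")
  expect_equal(max(x) - min(x), 0.5, tolerance = 1e-3)
  expect_equal(min(x), spec$diastolic_level)
})

test_that("the pacing ladder satisfies the 24-stimulation / 12-second rule", {
  spec <- transient_sim_spec()
  g <- gen_transient_trace(spec)
  tr <- g$truth
  for (f in spec$pacing_frequencies) {
    tf <- tr$stimulus_time[abs(tr$frequency - f) < 1e-9]
    n <- length(tf)
    duration <- n / f
    expect_true(n >= 24 || duration >= 12,
                info = sprintf("interval at %g Hz: %d stimuli, %.1f s",
                               f, n, duration))
  }
  # seven intervals, increasing rates
  expect_equal(length(unique(tr$frequency)), 7L)
})

test_that("generators are deterministic under a fixed seed", {
  spec <- transient_sim_spec(noise_sd = 0.02, missed_beat_prob = 0.1,
                             seed = 99)
  g1 <- gen_transient_trace(spec)
  g2 <- gen_transient_trace(spec)
  expect_identical(g1$recording$channels, g2$recording$channels)
  expect_identical(g1$truth, g2$truth)
  # and the global RNG state is untouched
  set.seed(123); before <- .Random.seed
  gen_transient_trace(spec)
  expect_identical(before, .Random.seed)
})

test_that("overlapping beats are rejected with a diagnostic", {
  spec <- transient_sim_spec(pacing_frequencies = c(1, 8),
                             decay_tau = 0.2)
  expect_error(gen_transient_trace(spec), "overlap")
})

test_that("sarcomere traces deflect downward and validate shortening", {
  spec <- transient_sim_spec(pacing_frequencies = 1, min_stimulations = 2,
                             min_duration_s = 0, noise_sd = 0)
  g <- gen_sarcomere_trace(spec, resting_sl = 1.8, shortening = 0.1)
  sl <- get_channel(g$recording, "sarcomere_length")
  expect_equal(max(sl), 1.8)
  expect_equal(min(sl), 1.7, tolerance = 1e-3)
  expect_error(gen_sarcomere_trace(spec, 1.8, 1.9), "below resting_sl")
})

test_that("all-missed-beat traces are flat at the resting level", {
  spec <- transient_sim_spec(pacing_frequencies = c(1, 2),
                             missed_beat_prob = 1, noise_sd = 0)
  g <- gen_sarcomere_trace(spec, 1.8, 0.1)
  expect_true(all(get_channel(g$recording, "sarcomere_length") == 1.8))
  expect_true(all(!g$truth$captured))
})

test_that("striation profiles have the requested spatial period", {
  p <- gen_striation_profile(sl = 1.8, pixel_size = 0.05, length = 40,
                             noise_sd = 0)
  n <- length(p)
  pw <- Mod(stats::fft(p - mean(p)))^2
  freqs <- (seq_len(floor(n / 2) - 1)) / (n * 0.05)
  peak_f <- freqs[which.max(pw[2:floor(n / 2)])]
  expect_equal(1 / peak_f, 1.8, tolerance = 0.05)
  expect_error(gen_striation_profile(1.8, 0.05, length = 0), "positive")
  # 1.7 vs 1.9 profiles separate in the right direction
  e17 <- estimate_sarcomere_length(
    gen_striation_profile(1.7, 0.05, 40, 0.05, seed = 5), 0.05)
  e19 <- estimate_sarcomere_length(
    gen_striation_profile(1.9, 0.05, 40, 0.05, seed = 5), 0.05)
  expect_lt(e17, e19)
})
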