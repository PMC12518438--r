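make_rec <- function(spec = transient_sim_spec(pacing_frequencies = c(0.5, 1),
                                               noise_sd = 0)) {
  gen_transient_trace(spec)
}

test_that("stimulus detection recovers generated times and the ladder", {
  g <- make_rec(transient_sim_spec(pacing_frequencies = 1,
                                   min_stimulations = 12,
                                   min_duration_s = 0, noise_sd = 0))
  tr <- detect_stimuli(g$recording)
  expect_equal(length(tr$stimulus_times), 12L)
  expect_true(all(abs(tr$stimulus_times - g$truth$stimulus_time) <=
                    1 / g$recording$sampling_rate + 1e-9))

  full <- gen_transient_trace(transient_sim_spec())
  tr7 <- detect_stimuli(full$recording)
  expect_equal(nrow(tr7$intervals), 7L)
  expect_equal(tr7$intervals$frequency,
               c(0.5, 1, 1.5, 2, 2.5, 3, 4), tolerance = 0.05)
})

test_that("a flat stimulus channel yields an empty train with a warning", {
  rec <- ts_recording(seq(0, 1, 1 / 1000),
                      list(fura_ratio = rep(1, 1001),
                           stimulus = rep(0, 1001)))
  expect_warning(tr <- detect_stimuli(rec), "no stimulation events")
  expect_equal(length(tr$stimulus_times), 0L)
})

test_that("median+mean filter matches the brute-force reference", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(60:400, 1)
    x <- rnorm(n) + sin(seq_len(n) / 17)
    expect_equal(filter_signal(x), naive_filter(x), tolerance = 1e-12)
  }
  # constant signals pass through unchanged
  expect_equal(filter_signal(rep(2.5, 100)), rep(2.5, 100))
  # an isolated spike on a flat baseline is removed entirely
  x <- rep(1, 100); x[50] <- 10
  expect_equal(filter_signal(x), rep(1, 100))
  expect_error(filter_signal(rnorm(15)), "shorter")
})

test_that("noise estimation matches the window-by-window oracle", {
  spec <- transient_sim_spec(pacing_frequencies = c(0.5, 1),
                             noise_sd = 0.03, seed = 5)
  g <- gen_transient_trace(spec)
  x <- filter_signal(get_channel(g$recording, "fura_ratio"))
  x <- x - min(x)
  tr <- detect_stimuli(g$recording)
  est <- estimate_noise(x, g$recording$time, tr)
  expect_equal(est$a_noise,
               naive_noise(x, g$recording$time, tr$stimulus_times),
               tolerance = 1e-12)
  # zero signal -> zero noise amplitude
  z <- numeric(length(x))
  expect_equal(estimate_noise(z, g$recording$time, tr)$a_noise, 0)
  # a window sitting at a constant level above offset reports that level
  x2 <- z; x2[g$recording$time < tr$stimulus_times[2]] <- 0.07
  expect_equal(estimate_noise(x2, g$recording$time, tr)$a_noise, 0.07)
})

test_that("noise estimation refuses fast-pacing-only recordings", {
  g <- gen_transient_trace(transient_sim_spec(pacing_frequencies = c(2, 4)))
  x <- filter_signal(get_channel(g$recording, "fura_ratio"))
  tr <- detect_stimuli(g$recording)
  expect_error(estimate_noise(x - min(x), g$recording$time, tr),
               "supply a_noise")
  # but the pipeline runs when a_noise is supplied via config
  res <- analyze_recording(g$recording, "fura_ratio", "up",
                           beat_config(a_noise = 0.01))
  expect_true(all(res$beats$captured))
})

test_that("noise-free beats recover the analytic metrics", {
  g <- make_rec()
  res <- analyze_recording(g$recording, "fura_ratio", "up")
  cap <- res$beats[res$beats$captured, ]
  expect_equal(nrow(cap), nrow(g$truth))
  expect_equal(mean(cap$amplitude), 0.5, tolerance = 0.01)
  cr <- g$truth[1, ]
  expect_lt(abs(mean(cap$ttp90) - cr$ttp90), 0.001 + 0.02 * cr$ttp90)
  expect_lt(abs(mean(cap$ttbl90) - cr$ttbl90), 0.001 + 0.02 * cr$ttbl90)
})

test_that("capture requires a peak at least twice the noise amplitude", {
  # constructed trace: one beat of height 1.9 * a_noise must not capture,
  # one of height 2.1 * a_noise must
  fs <- 1000
  time <- seq(0, 6, 1 / fs)
  stim <- c(2, 4)
  stim_ch <- numeric(length(time))
  stim_ch[round(stim * fs) + 1] <- 5
  a_noise <- 0.05
  x <- rep(0, length(time))
  shape <- myoequiv:::pulse_shape(seq(0, 1, 1 / fs), 0.035, 0.045)
  i1 <- round(2 * fs) + 1
  x[i1:(i1 + length(shape) - 1)] <- 1.9 * a_noise * shape
  i2 <- round(4 * fs) + 1
  x[i2:(i2 + length(shape) - 1)] <- 2.1 * a_noise * shape
  rec <- ts_recording(time, list(sig = x, stimulus = stim_ch))
  tr <- detect_stimuli(rec)
  beats <- analyze_beats(filter_signal(x), time, tr, a_noise)
  expect_false(beats$captured[1])
  expect_true(beats$captured[2])
})

test_that("transient duration is exactly the sum of its two phases", {
  spec <- transient_sim_spec(noise_sd = 0.025, missed_beat_prob = 0.1,
                             seed = 3)
  g <- gen_transient_trace(spec)
  res <- analyze_recording(g$recording, "fura_ratio", "up")
  cap <- res$beats[res$beats$captured & !res$beats$truncated_decay, ]
  expect_equal(cap$catd90, cap$ttp90 + cap$ttbl90)
})

test_that("interval summaries average the last six captured beats", {
  beats <- data.frame(stimulus_time = 1:24, interval = 1L, frequency = 1,
                      captured = TRUE, diastolic_level = 0,
                      amplitude = 1:24, ttp90 = 0.02, ttbl90 = 0.1,
                      catd90 = 0.12, truncated_decay = FALSE)
  s <- summarize_interval(beats, 1)
  expect_equal(s$amplitude, mean(19:24))
  expect_equal(s$n_beats_used, 6L)
  # identical beats: the summary equals the single-beat metrics
  beats$amplitude <- 0.5
  expect_equal(summarize_interval(beats, 1)$amplitude, 0.5)
  # only three captured -> n_beats_used records it
  beats$captured <- rep(c(FALSE, TRUE), c(21, 3))
  expect_equal(summarize_interval(beats, 1)$n_beats_used, 3L)
  # none captured -> flagged
  beats$captured <- FALSE
  expect_false(summarize_interval(beats, 1)$captured)
})

test_that("the pipeline is translation-invariant and scale-equivariant", {
  spec <- transient_sim_spec(pacing_frequencies = c(0.5, 1),
                             noise_sd = 0.02, seed = 8)
  g <- gen_transient_trace(spec)
  base <- analyze_recording(g$recording, "fura_ratio", "up")

  shifted <- g$recording
  shifted$channels$fura_ratio <- shifted$channels$fura_ratio + 3
  res_s <- analyze_recording(shifted, "fura_ratio", "up")
  expect_equal(res_s$beats$diastolic_level,
               base$beats$diastolic_level + 3, tolerance = 1e-9)
  expect_equal(res_s$beats$amplitude, base$beats$amplitude,
               tolerance = 1e-9)
  expect_equal(res_s$beats$ttp90, base$beats$ttp90, tolerance = 1e-9)

  scaled <- g$recording
  scaled$channels$fura_ratio <- scaled$channels$fura_ratio * 4
  res_m <- analyze_recording(scaled, "fura_ratio", "up")
  expect_equal(res_m$a_noise, base$a_noise * 4, tolerance = 1e-9)
  expect_equal(res_m$beats$amplitude, base$beats$amplitude * 4,
               tolerance = 1e-9)
  expect_equal(res_m$beats$captured, base$beats$captured)
})

test_that("sarcomere length estimation is accurate and guarded", {
  p <- gen_striation_profile(1.8, 0.05, 40, noise_sd = 0)
  expect_equal(estimate_sarcomere_length(p, 0.05), 1.8, tolerance = 0.02)
  set.seed(9)
  expect_warning(out <- estimate_sarcomere_length(rnorm(800), 0.05),
                 "background")
  expect_true(is.na(out))
})
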