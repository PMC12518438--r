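#' Specification for a paced-transient simulation
#'
#' Defaults reproduce the study's pacing protocol: an ascending frequency
#' ladder of 0.5, 1, 1.5, 2, 2.5, 3 and 4 Hz where every interval contains at
#' least 24 stimulations or lasts at least 12 s, whichever is reached first.
#' The transient template is a peak-normalized sigmoidal-rise pulse
#' \deqn{s(t) = (1 - e^{-t/\tau_r})^2\, e^{-t/\tau_d} / s(t^*)}
#' with analytic peak time
#' \eqn{t^* = \tau_r \log((\tau_r + 2\tau_d)/\tau_r)}; the squared
#' exponential gives the S-shaped upstroke foot of real transients, so the
#' 10%-of-amplitude landmark lies several samples after the stimulus.
#'
#' @param pacing_frequencies Hz, positive and increasing.
#' @param min_stimulations,min_duration_s Interval rule: each interval holds
#'   `min_stimulations` stimuli or spans `min_duration_s` seconds, whichever
#'   needs fewer stimuli.
#' @param diastolic_level Baseline signal level (Fura ratio units).
#' @param amplitude Transient amplitude above the diastolic level.
#' @param rise_tau,decay_tau Rise and decay time constants in seconds.
#' @param noise_sd Additive Gaussian noise SD in signal units.
#' @param missed_beat_prob Probability that a stimulus fails to elicit a beat.
#' @param sampling_rate Hz.
#' @param seed RNG seed (explicit; no global state is consumed).
#' @return A `transient_sim_spec` list.
#' @export
transient_sim_spec <- function(pacing_frequencies = c(0.5, 1, 1.5, 2, 2.5, 3, 4),
                               min_stimulations = 24,
                               min_duration_s = 12,
                               diastolic_level = 1.0,
                               amplitude = 0.5,
                               rise_tau = 0.035,
                               decay_tau = 0.045,
                               noise_sd = 0,
                               missed_beat_prob = 0,
                               sampling_rate = 1000,
                               seed = 1L) {
  f <- as.numeric(pacing_frequencies)
  abort_if(any(f <= 0), "pacing frequencies must be positive")
  abort_if(any(diff(f) <= 0) && length(f) > 1,
           "pacing frequencies must be increasing")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  abort_if(missed_beat_prob < 0 || missed_beat_prob > 1,
           "missed_beat_prob must be in [0, 1]")
  abort_if(rise_tau <= 0 || decay_tau <= 0, "time constants must be positive")
  structure(list(pacing_frequencies = f,
                 min_stimulations = min_stimulations,
                 min_duration_s = min_duration_s,
                 diastolic_level = diastolic_level,
                 amplitude = amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 noise_sd = noise_sd,
                 missed_beat_prob = missed_beat_prob,
                 sampling_rate = sampling_rate,
                 seed = seed),
            class = "transient_sim_spec")
}

# Peak-normalized transient template and its analytic landmarks. The rise
# is a squared exponential (sigmoidal foot, like the latency-then-upstroke
# of real transients) and the decay a single exponential; the peak time is
# closed-form.
pulse_shape <- function(t, rise_tau, decay_tau) {
  tp <- pulse_peak_time(rise_tau, decay_tau)
  peak <- (1 - exp(-tp / rise_tau))^2 * exp(-tp / decay_tau)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (1 - exp(-t[pos] / rise_tau))^2 *
    exp(-t[pos] / decay_tau) / peak
  out
}

pulse_peak_time <- function(rise_tau, decay_tau) {
  rise_tau * log((rise_tau + 2 * decay_tau) / rise_tau)
}

# Times where the template crosses `level` (fraction of peak) on the rise and
# on the decay; used for ground-truth TTP90/TTBL90.
pulse_crossings <- function(rise_tau, decay_tau, level = 0.1) {
  tp <- pulse_peak_time(rise_tau, decay_tau)
  f <- function(t) pulse_shape(t, rise_tau, decay_tau) - level
  up <- stats::uniroot(f, c(tp * 1e-9, tp), tol = 1e-12)$root
  # decay crossing lies beyond the peak; bracket by expanding upper bound
  hi <- tp * 2
  while (f(hi) > 0) hi <- hi * 2
  down <- stats::uniroot(f, c(tp, hi), tol = 1e-12)$root
  list(t_up = up, t_peak = tp, t_down = down,
       ttp90 = tp - up, ttbl90 = down - tp)
}

# Stimulus times for the frequency ladder; each interval holds
# min(min_stimulations, ceiling(min_duration_s * f)) stimuli.
ladder_stimulus_times <- function(spec, lead_in_s = 1) {
  fs_all <- spec$pacing_frequencies
  t0 <- lead_in_s
  times <- numeric(0); freqs <- numeric(0)
  for (k in seq_along(fs_all)) {
    f <- fs_all[k]
    n <- if (spec$min_duration_s <= 0) {
      spec$min_stimulations
    } else if (spec$min_stimulations <= 0) {
      ceiling(spec$min_duration_s * f)
    } else {
      min(spec$min_stimulations, ceiling(spec$min_duration_s * f))
    }
    n <- max(1, n)
    st <- t0 + (seq_len(n) - 1) / f
    times <- c(times, st)
    freqs <- c(freqs, rep(f, n))
    # next interval starts one *new* period after the last stimulus, so the
    # period sequence changes exactly at the first stimulus of the new rate
    t0 <- st[n] + if (k < length(fs_all)) 1 / fs_all[k + 1] else 1 / f
  }
  data.frame(stimulus_time = times, frequency = freqs)
}

render_stimulus_channel <- function(time, stim_times, sampling_rate,
                                    amplitude_v = 5) {
  ch <- numeric(length(time))
  idx <- round((stim_times - time[1]) * sampling_rate) + 1
  idx <- idx[idx >= 1 & idx <= length(time)]
  ch[idx] <- amplitude_v
  idx2 <- idx + 1
  ch[idx2[idx2 <= length(time)]] <- amplitude_v
  ch
}

# Shared machinery for calcium and sarcomere traces. `direction` +1 renders
# upward transients from the baseline, -1 downward deflections.
simulate_paced_trace <- function(spec, baseline, amplitude, direction,
                                 signal_name) {
  abort_if(amplitude <= 0, "amplitude must be positive")
  cr <- pulse_crossings(spec$rise_tau, spec$decay_tau)
  stim <- ladder_stimulus_times(spec)
  min_period <- 1 / max(spec$pacing_frequencies)
  resid <- pulse_shape(min_period, spec$rise_tau, spec$decay_tau)
  abort_if(resid > 0.03,
           paste0("beats overlap: %.0f%% of the transient remains at the ",
                  "shortest stimulation period (%.0f ms); shorten decay_tau ",
                  "or lower the maximum pacing frequency"),
           100 * resid, 1000 * min_period)

  fs <- spec$sampling_rate
  t_end <- stim$stimulus_time[nrow(stim)] + max(2, 14 * spec$decay_tau)
  time <- seq(0, t_end, by = 1 / fs)
  n <- length(time)

  with_seed(spec$seed, {
    missed <- stats::runif(nrow(stim)) < spec$missed_beat_prob
    signal <- rep(baseline, n)
    support <- min(14 * spec$decay_tau, Inf)
    for (i in seq_len(nrow(stim))) {
      if (missed[i]) next
      t0 <- stim$stimulus_time[i]
      i0 <- max(1L, ceiling((t0 - time[1]) * fs) + 1L)
      i1 <- min(n, floor((t0 + support - time[1]) * fs) + 1L)
      sl <- i0:i1
      signal[sl] <- signal[sl] +
        direction * amplitude * pulse_shape(time[sl] - t0,
                                            spec$rise_tau, spec$decay_tau)
    }
    if (spec$noise_sd > 0) signal <- signal + stats::rnorm(n, 0, spec$noise_sd)

    truth <- data.frame(stimulus_time = stim$stimulus_time,
                        frequency = stim$frequency,
                        captured = !missed,
                        diastolic_level = baseline,
                        amplitude = ifelse(missed, 0, amplitude),
                        ttp90 = ifelse(missed, NA_real_, cr$ttp90),
                        ttbl90 = ifelse(missed, NA_real_, cr$ttbl90))
    truth$catd90 <- truth$ttp90 + truth$ttbl90

    ch <- stats::setNames(
      list(signal, render_stimulus_channel(time, stim$stimulus_time, fs)),
      c(signal_name, "stimulus"))
    list(recording = ts_recording(time, ch, fs), truth = truth)
  })
}

#' Generate a paced Fura-2 ratio trace with ground truth
#'
#' Renders the frequency ladder with the difference-of-exponentials transient
#' template on a diastolic baseline, plus a stimulus channel of short
#' rectangular impulses at the exact pacing times. Beats are dropped with
#' `missed_beat_prob` (the stimulus impulse remains). The returned truth table
#' lists, per stimulus, whether it was captured and the analytic amplitude,
#' TTP90, TTBL90 and CATD90 of the rendered transient.
#'
#' @param spec A [transient_sim_spec()].
#' @return List with `recording` (a [ts_recording()] with channels
#'   `fura_ratio` and `stimulus`) and `truth` (per-beat data frame).
#' @export
gen_transient_trace <- function(spec) {
  stopifnot(inherits(spec, "transient_sim_spec"))
  simulate_paced_trace(spec, spec$diastolic_level, spec$amplitude,
                       direction = +1, signal_name = "fura_ratio")
}

#' Generate a paced sarcomere-length trace with ground truth
#'
#' As [gen_transient_trace()] but contractions are downward deflections from
#' the resting sarcomere length.
#'
#' @param spec A [transient_sim_spec()]; its `diastolic_level`/`amplitude`
#'   are ignored in favour of `resting_sl`/`shortening`.
#' @param resting_sl Resting sarcomere length, um.
#' @param shortening Maximum shortening, um; must be smaller than
#'   `resting_sl`.
#' @return List with `recording` (channels `sarcomere_length`, `stimulus`)
#'   and `truth`.
#' @export
gen_sarcomere_trace <- function(spec, resting_sl = 1.8, shortening = 0.1) {
  stopifnot(inherits(spec, "transient_sim_spec"))
  abort_if(shortening >= resting_sl,
           "shortening (%.3g um) must be below resting_sl (%.3g um)",
           shortening, resting_sl)
  abort_if(shortening <= 0, "shortening must be positive")
  simulate_paced_trace(spec, resting_sl, shortening,
                       direction = -1, signal_name = "sarcomere_length")
}

#' Generate a brightfield striation intensity profile
#'
#' A sinusoid with spatial period equal to the sarcomere length plus optional
#' white noise, emulating the cross-striation pattern used for Fourier
#' sarcomere-length estimation.
#'
#' @param sl Sarcomere length (spatial period), um.
#' @param pixel_size um per pixel.
#' @param length Profile length, um; must cover at least two periods.
#' @param noise_sd Gaussian noise SD (profile amplitude is 1).
#' @param seed RNG seed.
#' @return Numeric intensity profile.
#' @export
gen_striation_profile <- function(sl, pixel_size = 0.05, length = 40,
                                  noise_sd = 0, seed = 1L) {
  abort_if(length <= 0, "profile length must be positive")
  abort_if(sl <= 0, "sarcomere length must be positive")
  abort_if(length < 2 * sl, "profile must cover at least two periods")
  x <- seq(0, length, by = pixel_size)
  with_seed(seed, {
    p <- sin(2 * pi * x / sl)
    if (noise_sd > 0) p <- p + stats::rnorm(base::length(x), 0, noise_sd)
    p
  })
}
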