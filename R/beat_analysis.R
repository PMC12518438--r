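#' Detect stimulation times and pacing intervals from the stimulus channel
#'
#' Peak detection on the voltage channel: rising edges above half the channel
#' maximum mark stimulation times. Consecutive stimuli are segmented into
#' pacing intervals wherever the inter-stimulus period changes by more than
#' 10%, and each interval's frequency is inferred as the reciprocal median
#' period.
#'
#' @param rec A [ts_recording()] containing a `stimulus` channel.
#' @param channel Name of the stimulus channel.
#' @param min_amplitude_v Absolute floor for the detection threshold, so a
#'   flat near-zero channel yields an empty train rather than noise edges.
#' @return A `stimulus_train`: list with `stimulus_times` (s), `interval`
#'   (interval id per stimulus) and `intervals` (data frame: `interval`,
#'   `frequency`, `start`, `end`, `n_stimuli`).
#' @export
detect_stimuli <- function(rec, channel = "stimulus", min_amplitude_v = 0.5) {
  stopifnot(inherits(rec, "ts_recording"))
  v <- get_channel(rec, channel)
  thr <- max(max(v) / 2, min_amplitude_v)
  above <- v >= thr
  edges <- which(above & !c(FALSE, above[-length(above)]))
  if (length(edges) == 0L) {
    warning("no stimulation events detected; returning empty train")
    return(structure(list(stimulus_times = numeric(0),
                          interval = integer(0),
                          intervals = data.frame(interval = integer(0),
                                                 frequency = numeric(0),
                                                 start = numeric(0),
                                                 end = numeric(0),
                                                 n_stimuli = integer(0))),
                     class = "stimulus_train"))
  }
  times <- rec$time[edges]

  interval <- integer(length(times))
  interval[1] <- 1L
  if (length(times) > 1L) {
    p <- diff(times)
    cur <- 1L
    interval[2] <- 1L
    if (length(times) > 2L) {
      for (j in 2:length(p)) {
        if (abs(p[j] - p[j - 1]) > 0.10 * p[j - 1]) cur <- cur + 1L
        interval[j + 1] <- cur
      }
    }
  }
  ids <- sort(unique(interval))
  iv <- do.call(rbind, lapply(ids, function(k) {
    tk <- times[interval == k]
    freq <- if (length(tk) > 1) 1 / stats::median(diff(tk)) else NA_real_
    data.frame(interval = k, frequency = freq,
               start = tk[1], end = tk[length(tk)],
               n_stimuli = length(tk))
  }))
  structure(list(stimulus_times = times, interval = interval,
                 intervals = iv),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> %d stimuli in %d intervals\n",
              length(x$stimulus_times), nrow(x$intervals)))
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' Moving median then moving mean filter
#'
#' The raw signal is smoothed with a moving median filter of radius
#' `median_radius` (window `2r + 1` samples) followed by a moving mean filter
#' of radius `mean_radius`, in that order. At the edges the median uses
#' symmetric shrinking odd windows and the mean uses windows clipped to the
#' signal, so output length equals input length.
#'
#' @param signal Numeric vector, longer than the median window.
#' @param median_radius,mean_radius Half-window sizes in samples.
#' @return Filtered vector of the same length.
#' @export
filter_signal <- function(signal, median_radius = 10, mean_radius = 5) {
  n <- length(signal)
  k <- 2 * median_radius + 1
  abort_if(n <= k, "signal (%d samples) shorter than median window (%d)",
           n, k)
  med <- as.numeric(stats::runmed(signal, k, endrule = "keep"))
  # edges: medians of symmetric shrinking windows
  for (i in seq_len(median_radius)) {
    med[i] <- stats::median(signal[1:(2 * i - 1)])
    med[n - i + 1] <- stats::median(signal[(n - 2 * i + 2):n])
  }
  w <- 2 * mean_radius + 1
  cs <- cumsum(c(0, med))
  lo <- pmax(seq_len(n) - mean_radius, 1L)
  hi <- pmin(seq_len(n) + mean_radius, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Estimate the noise amplitude from pre-stimulus windows
#'
#' The noise amplitude `A_noise` is the maximum of the offset-subtracted
#' filtered signal over all windows of `window_s` seconds preceding a
#' stimulus, restricted to pacing intervals at frequencies at or below
#' `max_frequency` (slow pacing, where the transient has fully decayed before
#' the next stimulus). The capture gate downstream is `2 * a_noise`.
#'
#' @param filtered Offset-subtracted filtered signal (global minimum already
#'   removed).
#' @param time Sample times, s.
#' @param train A `stimulus_train` from [detect_stimuli()].
#' @param window_s Pre-stimulus window length, s.
#' @param max_frequency Highest pacing frequency eligible for noise
#'   estimation, Hz (a 5% tolerance is applied to the inferred frequency).
#' @param guard_s Gap between window end and the stimulus, s; defaults to
#'   the filter half-width so the smoothed upstroke cannot bleed into the
#'   window.
#' @return List of class `noise_estimate`: `a_noise`, `window`,
#'   `frequencies_used`.
#' @export
estimate_noise <- function(filtered, time, train, window_s = 0.2,
                           max_frequency = 1.0, guard_s = 0.016) {
  stopifnot(inherits(train, "stimulus_train"))
  ok_iv <- train$intervals$interval[
    !is.na(train$intervals$frequency) &
      train$intervals$frequency <= max_frequency * 1.05]
  abort_if(length(ok_iv) == 0L,
           paste0("no pacing interval at <= %.3g Hz: supply a_noise ",
                  "explicitly via the analysis config"), max_frequency)
  use <- train$interval %in% ok_iv
  stim <- train$stimulus_times[use]
  vals <- numeric(0)
  for (t0 in stim) {
    sel <- time >= t0 - window_s - guard_s & time < t0 - guard_s
    if (any(sel)) vals <- c(vals, max(filtered[sel]))
  }
  abort_if(length(vals) == 0L, "no samples in any pre-stimulus window")
  structure(list(a_noise = max(vals), window = window_s,
                 frequencies_used = train$intervals$frequency[
                   train$intervals$interval %in% ok_iv]),
            class = "noise_estimate")
}

# Linear-interpolated crossing time of `level` between samples j-1 and j.
.cross_time <- function(time, x, j, level, rising) {
  if (j <= 1L) return(time[j])
  x0 <- x[j - 1]; x1 <- x[j]
  if (x1 == x0) return(time[j])
  frac <- (level - x0) / (x1 - x0)
  frac <- min(max(frac, 0), 1)
  time[j - 1] + frac * (time[j] - time[j - 1])
}

# Gaussian smoothing used only to PLACE landmark fit windows; landmark
# values come from local polynomial fits of the pipeline-filtered signal.
.coarse_smooth <- function(x, sd_samples = 6) {
  r <- ceiling(3 * sd_samples)
  k <- stats::dnorm(-r:r, sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
}

# Least-squares quartic around the coarse peak: vertex time from the
# derivative root nearest the centre; the peak value is corrected for the
# final boxcar (mean-filter) stage, which adds var(u) * c2 to a local
# polynomial (u uniform over the boxcar support).
.refine_peak <- function(xw, centre, half = 16L, boxcar_var = 10) {
  ii <- max(1L, centre - half):min(length(xw), centre + half)
  if (length(ii) < 7L) return(list(offset = 0, value = xw[centre]))
  u <- ii - centre
  X <- cbind(1, u, u^2, u^3, u^4)
  cf <- stats::lm.fit(X, xw[ii])$coefficients
  if (any(is.na(cf))) return(list(offset = 0, value = xw[centre]))
  rts <- tryCatch(polyroot(cf[-1] * 1:4), error = function(e) complex(0))
  rr <- Re(rts[abs(Im(rts)) < 1e-6])
  off <- if (length(rr)) rr[which.min(abs(rr))] else 0
  if (!is.finite(off) || abs(off) > half) {
    return(list(offset = 0, value = xw[centre]))
  }
  val <- sum(cf * off^(0:4)) - cf[3] * boxcar_var
  list(offset = off, value = val)
}

# Level crossing from a de-blurred local quadratic around the coarse
# crossing index. Returns the fractional sample offset or NA.
.refine_crossing <- function(xw, centre, level, half = 6L, boxcar_var = 10) {
  ii <- max(1L, centre - half):min(length(xw), centre + half)
  if (length(ii) < 4L) return(NA_real_)
  u <- ii - centre
  cf <- stats::lm.fit(cbind(1, u, u^2), xw[ii])$coefficients
  if (any(is.na(cf))) return(NA_real_)
  cf[1] <- cf[1] - cf[3] * boxcar_var
  rts <- tryCatch(polyroot(c(cf[1] - level, cf[2], cf[3])),
                  error = function(e) complex(0))
  rr <- Re(rts[abs(Im(rts)) < 1e-6])
  if (!length(rr)) return(NA_real_)
  off <- rr[which.min(abs(rr))]
  if (abs(off) > 2 * half) NA_real_ else off
}

#' Per-beat capture classification and kinetic metrics
#'
#' For each stimulus the search window runs to the next stimulus (or one
#' median period past the last). A beat is captured when the window's peak
#' rises at least `capture_factor * a_noise` above the beat's diastolic level
#' (the mean of a short pre-stimulus window ending one filter half-width
#' before the stimulus, falling back to the value at the stimulus; a mean is
#' used because a window minimum is biased low under noise, which inflates
#' the decay-crossing times). For captured beats: amplitude = peak -
#' diastolic; TTP90 = time from the 10%-of-amplitude crossing on the upstroke
#' to the peak; TTBL90 = peak to the 10% crossing on the decay; CATD90 =
#' TTP90 + TTBL90 by definition. A peak whose decay is truncated by the
#' window edge stays captured but has `ttbl90 = NA` and
#' `truncated_decay = TRUE`.
#'
#' @param filtered Offset-subtracted filtered signal.
#' @param time Sample times, s.
#' @param train A `stimulus_train`.
#' @param noise A `noise_estimate` from [estimate_noise()], or a bare number.
#' @param capture_factor Peak-height gate in units of `a_noise`.
#' @param diastolic_window_s Pre-stimulus window for the diastolic level, s.
#' @param guard_s Gap between the diastolic window and the stimulus, s.
#' @param mean_radius Radius (samples) of the mean-filter stage the signal
#'   went through; its known boxcar response is deconvolved analytically in
#'   the local polynomial landmark fits.
#' @return Data frame, one row per stimulus: `stimulus_time`, `interval`,
#'   `frequency`, `captured`, `diastolic_level`, `amplitude`, `ttp90`,
#'   `ttbl90`, `catd90`, `truncated_decay`.
#' @export
analyze_beats <- function(filtered, time, train, noise, capture_factor = 2,
                          diastolic_window_s = 0.02, guard_s = 0.006,
                          mean_radius = 5) {
  stopifnot(inherits(train, "stimulus_train"))
  a_noise <- if (inherits(noise, "noise_estimate")) noise$a_noise else noise
  abort_if(!is.numeric(a_noise) || a_noise < 0, "a_noise must be >= 0")
  stim <- train$stimulus_times
  ns <- length(stim)
  if (ns == 0L) {
    return(data.frame(stimulus_time = numeric(0), interval = integer(0),
                      frequency = numeric(0), captured = logical(0),
                      diastolic_level = numeric(0), amplitude = numeric(0),
                      ttp90 = numeric(0), ttbl90 = numeric(0),
                      catd90 = numeric(0), truncated_decay = logical(0)))
  }
  period <- if (ns > 1) stats::median(diff(stim)) else
    diastolic_window_s * 5
  ends <- c(stim[-1], stim[ns] + period)
  freq <- train$intervals$frequency[match(train$interval,
                                          train$intervals$interval)]
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    w <- which(time >= stim[i] & time < ends[i])
    pre <- which(time >= stim[i] - diastolic_window_s - guard_s &
                   time < stim[i] - guard_s)
    diast <- if (length(pre)) mean(filtered[pre]) else
      filtered[which.min(abs(time - stim[i]))]
    row <- data.frame(stimulus_time = stim[i], interval = train$interval[i],
                      frequency = freq[i], captured = FALSE,
                      diastolic_level = diast, amplitude = NA_real_,
                      ttp90 = NA_real_, ttbl90 = NA_real_, catd90 = NA_real_,
                      truncated_decay = FALSE)
    if (length(w) >= 3L) {
      xw <- filtered[w]; tw <- time[w]
      dt <- tw[2] - tw[1]
      # coarse smoothed copy places the landmark fit windows; all landmark
      # values come from local polynomial fits of the filtered signal
      bv <- mean_radius * (mean_radius + 1) / 3
      z <- .coarse_smooth(xw)
      cpk <- which.max(z)           # ties break toward the earliest sample
      pf <- .refine_peak(xw, cpk, boxcar_var = bv)
      t_pk <- tw[cpk] + pf$offset * dt
      v_pk <- pf$value
      amp <- v_pk - diast
      if (amp >= capture_factor * a_noise && amp > 1e-12) {
        row$captured <- TRUE
        row$amplitude <- amp
        level <- diast + 0.1 * amp
        # upstroke crossing: centre a local quadratic at the coarse
        # curve's last sample below the level (the centring only places
        # the fit window; the regression supplies the crossing)
        below <- which(z[seq_len(cpk)] < level)
        ju <- if (length(below)) below[length(below)] else 1L
        off <- .refine_crossing(xw, ju, level, boxcar_var = bv)
        t_up <- if (is.na(off)) tw[ju] else tw[ju] + off * dt
        row$ttp90 <- t_pk - t_up
        post <- which(z <= level & seq_along(z) > cpk)
        if (length(post)) {
          jd <- post[1]
          off <- .refine_crossing(xw, jd, level, half = 8L, boxcar_var = bv)
          t_down <- if (is.na(off)) tw[jd] else tw[jd] + off * dt
          row$ttbl90 <- t_down - t_pk
          row$catd90 <- row$ttp90 + row$ttbl90
        } else {
          row$truncated_decay <- TRUE
        }
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Average the last captured beats of a pacing interval
#'
#' Representative per-frequency values are the means over the last
#' `n_summary` captured beats of the interval (fewer if fewer were captured,
#' with the count recorded).
#'
#' @param beats Data frame from [analyze_beats()] (one interval's rows).
#' @param frequency Nominal pacing frequency, Hz.
#' @param n_summary Number of trailing captured beats to average.
#' @return One-row data frame: `pacing_frequency`, `captured`,
#'   `n_beats_used`, and means of `diastolic_level`, `amplitude`, `ttp90`,
#'   `ttbl90`, `catd90`.
#' @export
summarize_interval <- function(beats, frequency, n_summary = 6) {
  cap <- beats[beats$captured, , drop = FALSE]
  if (nrow(cap) == 0L) {
    return(data.frame(pacing_frequency = frequency, captured = FALSE,
                      n_beats_used = 0L, diastolic_level = NA_real_,
                      amplitude = NA_real_, ttp90 = NA_real_,
                      ttbl90 = NA_real_, catd90 = NA_real_))
  }
  use <- cap[max(1L, nrow(cap) - n_summary + 1L):nrow(cap), , drop = FALSE]
  data.frame(pacing_frequency = frequency, captured = TRUE,
             n_beats_used = nrow(use),
             diastolic_level = mean(use$diastolic_level),
             amplitude = mean(use$amplitude),
             ttp90 = mean(use$ttp90),
             ttbl90 = mean(use$ttbl90),
             catd90 = mean(use$catd90))
}

#' Default beat-analysis configuration
#'
#' Defaults follow the study protocol: median radius 10 and mean radius 5
#' samples, capture gate `2 * A_noise`, 200 ms pre-stimulus windows, noise
#' estimation at pacing frequencies at or below 1 Hz, six-beat summaries.
#'
#' @param ... Overrides for any default.
#' @return Named list of parameters.
#' @export
beat_config <- function(...) {
  cfg <- list(median_radius = 10, mean_radius = 5, capture_factor = 2,
              n_summary = 6, noise_window_s = 0.2, noise_max_frequency = 1.0,
              diastolic_window_s = 0.02, guard_s = NULL, a_noise = NULL)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  abort_if(length(unknown) > 0, "unknown config entries: %s",
           paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

#' Full stimulus-locked analysis of one recording channel
#'
#' Pipeline (in this order): moving median + mean filtering, orientation
#' (downward contraction channels are negated so beats point up), global
#' offset (minimum) subtraction, noise-amplitude estimation from slow-pacing
#' pre-stimulus windows, per-beat capture and kinetics, and per-frequency
#' six-beat summaries. Diastolic levels are reported on the original signal
#' scale.
#'
#' @param rec A [ts_recording()].
#' @param channel Signal channel to analyze.
#' @param direction `"up"` for Ca transients, `"down"` for sarcomere
#'   shortening.
#' @param config From [beat_config()]; set `a_noise` there to skip
#'   estimation (required when no slow-pacing interval exists).
#' @return List of class `beat_analysis`: `train`, `a_noise`, `offset`,
#'   `beats`, `summary`.
#' @export
analyze_recording <- function(rec, channel = "fura_ratio",
                              direction = c("up", "down"),
                              config = beat_config()) {
  direction <- match.arg(direction)
  raw <- get_channel(rec, channel)
  x <- filter_signal(raw, config$median_radius, config$mean_radius)
  if (direction == "down") x <- -x
  offset <- min(x)
  x <- x - offset
  train <- detect_stimuli(rec)
  # the noise window must not see the smoothed upstroke at all (median +
  # mean half-width); the diastolic window only needs the mean half-width
  guard_noise <- config$guard_s %||%
    ((config$median_radius + config$mean_radius + 1) / rec$sampling_rate)
  guard_diast <- config$guard_s %||%
    ((config$mean_radius + 1) / rec$sampling_rate)
  noise <- if (!is.null(config$a_noise)) {
    structure(list(a_noise = config$a_noise, window = NA_real_,
                   frequencies_used = numeric(0)), class = "noise_estimate")
  } else {
    estimate_noise(x, rec$time, train, config$noise_window_s,
                   config$noise_max_frequency, guard_noise)
  }
  beats <- analyze_beats(x, rec$time, train, noise, config$capture_factor,
                         config$diastolic_window_s, guard_diast,
                         config$mean_radius)
  # diastolic back on the original signal scale
  beats$diastolic_level <- if (direction == "up") {
    beats$diastolic_level + offset
  } else {
    -(beats$diastolic_level + offset)
  }
  summary <- do.call(rbind, lapply(train$intervals$interval, function(k) {
    summarize_interval(beats[beats$interval == k, , drop = FALSE],
                       train$intervals$frequency[train$intervals$interval == k],
                       config$n_summary)
  }))
  structure(list(train = train, a_noise = noise$a_noise, offset = offset,
                 beats = beats, summary = summary),
            class = "beat_analysis")
}

#' @export
print.beat_analysis <- function(x, ...) {
  cat(sprintf("<beat_analysis> %d beats (%d captured), a_noise = %.4g\n",
              nrow(x$beats), sum(x$beats$captured), x$a_noise))
  print(x$summary)
  invisible(x)
}

#' Sarcomere length from a striation intensity profile
#'
#' Fourier analysis of the brightfield striation pattern: the profile is
#' Hann-windowed, the power spectrum searched for its dominant peak within a
#' physiological period band, and the peak frequency refined by local
#' parabolic interpolation before inversion to a length.
#'
#' @param profile Intensity profile along the cell axis.
#' @param pixel_size um per pixel.
#' @param band Period search band in um (default 1.4-2.4).
#' @param min_peak_frac Required share of total non-DC power in the peak
#'   bin; below it (as for structureless noise) the estimate is undefined.
#' @return Sarcomere length in um, or `NA` with a warning when no credible
#'   in-band peak exists.
#' @export
estimate_sarcomere_length <- function(profile, pixel_size, band = c(1.4, 2.4),
                                      min_peak_frac = 0.05) {
  n <- length(profile)
  abort_if(n < 8L, "profile too short for spectral analysis")
  abort_if(pixel_size <= 0, "pixel_size must be positive")
  x <- profile - mean(profile)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  p <- Mod(stats::fft(x * w))^2
  half <- 2:floor(n / 2)
  freqs <- (half - 1) / (n * pixel_size)
  inband <- which(freqs >= 1 / band[2] & freqs <= 1 / band[1])
  if (length(inband) < 1L) {
    warning("period band contains no spectral bins at this profile length")
    return(NA_real_)
  }
  pw <- p[half]
  k <- inband[which.max(pw[inband])]
  if (pw[k] < min_peak_frac * sum(pw)) {
    warning("no striation peak above spectral background in the 1.4-2.4 um band")
    return(NA_real_)
  }
  # parabolic sub-bin refinement
  delta <- 0
  if (k > 1 && k < length(pw)) {
    a <- pw[k - 1]; b <- pw[k]; c <- pw[k + 1]
    den <- a - 2 * b + c
    if (den < 0) delta <- 0.5 * (a - c) / den
  }
  f_hat <- (k + delta) / (n * pixel_size)
  1 / f_hat
}
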