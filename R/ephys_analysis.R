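#' Action-potential metrics from a paced current-clamp trace
#'
#' Analyzes one paced beat (the 30th by default, after pacing to steady
#' state). The resting membrane potential is the mean of the pre-upstroke
#' plateau, dV/dt_max the maximum discrete derivative on the upstroke,
#' overshoot the peak above 0 mV, and APDs run from the upstroke threshold
#' crossing (10% of dV/dt_max) to the given repolarization fraction between
#' peak and RMP (interpolated), plus the first downward 0 mV crossing.
#'
#' @param trace A [ts_recording()] with channels `membrane_potential` and
#'   `stimulus`.
#' @param beat_index Beat used for analysis (default 30).
#' @param rmp_window_s Pre-stimulus window for the RMP, s.
#' @param dvdt_threshold_frac Upstroke threshold as a fraction of
#'   dV/dt_max.
#' @return One-row data frame: `rmp`, `dvdt_max` (mV/ms), `overshoot`,
#'   `apd20`, `apd50`, `apd90`, `apd_0mv` (ms).
#' @export
measure_ap <- function(trace, beat_index = 30, rmp_window_s = 0.02,
                       dvdt_threshold_frac = 0.1) {
  stopifnot(inherits(trace, "ts_recording"))
  v <- get_channel(trace, "membrane_potential")
  train <- detect_stimuli(trace)
  nb <- length(train$stimulus_times)
  abort_if(nb < beat_index,
           paste0("only %d paced beats present but beat %d requested ",
                  "(the 30th AP is used for analysis by default)"),
           nb, beat_index)
  t0 <- train$stimulus_times[beat_index]
  t1 <- if (beat_index < nb) train$stimulus_times[beat_index + 1] else
    t0 + stats::median(diff(train$stimulus_times))
  w <- which(trace$time >= t0 & trace$time < t1)
  tw <- trace$time[w]; vw <- v[w]
  pre <- which(trace$time >= t0 - rmp_window_s & trace$time < t0)
  rmp <- if (length(pre)) mean(v[pre]) else vw[1]

  pk <- which.max(vw)
  dt_ms <- 1000 / trace$sampling_rate
  dv <- diff(vw[seq_len(pk)]) / dt_ms
  abort_if(length(dv) == 0 || max(dv) <= 1,
           "no upstroke found in the analyzed beat")
  dvdt_max <- max(dv)
  thr_i <- which(dv >= dvdt_threshold_frac * dvdt_max)[1] + 1L
  t_start <- tw[thr_i]
  peak <- vw[pk]

  apd_to_level <- function(level) {
    post <- which(vw <= level & seq_along(vw) > pk)
    if (!length(post)) return(NA_real_)
    j <- post[1]
    1000 * (.cross_time(tw, vw, j, level, rising = FALSE) - t_start)
  }
  data.frame(rmp = rmp, dvdt_max = dvdt_max, overshoot = peak,
             apd20 = apd_to_level(peak - 0.20 * (peak - rmp)),
             apd50 = apd_to_level(peak - 0.50 * (peak - rmp)),
             apd90 = apd_to_level(peak - 0.90 * (peak - rmp)),
             apd_0mv = apd_to_level(0))
}

# Pulse-window samples of one sweep, from its protocol row.
.pulse_window <- function(sweep, start_s, end_s) {
  which(sweep$time_s >= start_s & sweep$time_s < end_s)
}

.end_window_mean <- function(sweep, start_s, end_s, end_fraction) {
  w0 <- end_s - end_fraction * (end_s - start_s)
  idx <- which(sweep$time_s >= w0 & sweep$time_s < end_s)
  abort_if(length(idx) == 0, "empty end-of-pulse window")
  mean(sweep$signal[idx])
}

#' Transient outward current: peak minus end-of-pulse, per sweep
#'
#' I_to is the difference between the current peak within the pulse and the
#' remaining current at the end of the pulse (mean over the terminal window,
#' by default the last 5% of the pulse), normalized to cell capacitance.
#'
#' @param sweeps A [sweep_set()] whose protocol provides `pulse_start_s` /
#'   `pulse_end_s`.
#' @param end_fraction Terminal window as a fraction of the pulse.
#' @return Data frame: `v_pip_mv`, `peak_pA`, `end_pA`, `ito_pA`,
#'   `ito_density_pA_pF`.
#' @export
extract_ito <- function(sweeps, end_fraction = 0.05) {
  stopifnot(inherits(sweeps, "sweep_set"))
  out <- NULL
  for (i in seq_along(sweeps$sweeps)) {
    sw <- sweeps$sweeps[[i]]
    pr <- sweeps$protocol[i, ]
    idx <- .pulse_window(sw, pr$pulse_start_s, pr$pulse_end_s)
    abort_if(length(idx) == 0, "empty pulse window in sweep %d", i)
    peak <- max(sw$signal[idx])
    endm <- .end_window_mean(sw, pr$pulse_start_s, pr$pulse_end_s,
                             end_fraction)
    out <- rbind(out, data.frame(v_pip_mv = pr$v_pip_mv, peak_pA = peak,
                                 end_pA = endm, ito_pA = peak - endm))
  }
  out$ito_density_pA_pF <- out$ito_pA / sweeps$capacitance_pF
  out
}

#' Delayed-rectifier current: end-of-pulse mean density, per sweep
#'
#' @inheritParams extract_ito
#' @return Data frame: `v_pip_mv`, `end_pA`, `ik_density_pA_pF`.
#' @export
extract_ik <- function(sweeps, end_fraction = 0.05) {
  stopifnot(inherits(sweeps, "sweep_set"))
  out <- NULL
  for (i in seq_along(sweeps$sweeps)) {
    sw <- sweeps$sweeps[[i]]
    pr <- sweeps$protocol[i, ]
    endm <- .end_window_mean(sw, pr$pulse_start_s, pr$pulse_end_s,
                             end_fraction)
    out <- rbind(out, data.frame(v_pip_mv = pr$v_pip_mv, end_pA = endm))
  }
  out$ik_density_pA_pF <- out$end_pA / sweeps$capacitance_pF
  out
}

#' Ba-sensitive inward rectifier: control minus blocked difference density
#'
#' End-of-pulse current of the control sweeps minus that of the Ba-blocked
#' sweeps at matched commanded potentials; inward differences are negative.
#'
#' @param control,blocked [sweep_set()] pairs with identical protocols.
#' @param end_fraction Terminal window fraction.
#' @return Data frame: `v_pip_mv`, `ik1_pA`, `ik1_density_pA_pF`.
#' @export
extract_ik1 <- function(control, blocked, end_fraction = 0.05) {
  stopifnot(inherits(control, "sweep_set"), inherits(blocked, "sweep_set"))
  abort_if(!isTRUE(all.equal(control$protocol$v_pip_mv,
                             blocked$protocol$v_pip_mv)),
           "control and blocked protocols do not match")
  a <- extract_ik(control, end_fraction)
  b <- extract_ik(blocked, end_fraction)
  data.frame(v_pip_mv = a$v_pip_mv, ik1_pA = a$end_pA - b$end_pA,
             ik1_density_pA_pF = (a$end_pA - b$end_pA) /
               control$capacitance_pF)
}

#' Recovery-from-inactivation ratios from a two-pulse sweep set
#'
#' I_to of the second pulse normalized to I_to of the first, per
#' repolarization interval. The per-pulse transient amplitude is measured
#' as (onset-window mean) minus (end-of-pulse mean): with identical decay
#' kinetics in both pulses, any onset-window underestimate of the true
#' peak is a common factor that cancels exactly in the ratio, whereas a
#' raw per-sample maximum would carry extreme-value noise into it.
#'
#' @param sweeps A `"recovery"` [sweep_set()] (protocol columns
#'   `interval_s`, `pulse_start_s`, `pulse_end_s`, `pulse2_start_s`,
#'   `pulse2_end_s`).
#' @param end_fraction Terminal window fraction.
#' @param peak_window_s Onset averaging window, s.
#' @return Data frame: `interval_s`, `ratio`.
#' @export
extract_recovery <- function(sweeps, end_fraction = 0.05,
                             peak_window_s = 0.01) {
  stopifnot(inherits(sweeps, "sweep_set"))
  abort_if(!all(c("interval_s", "pulse2_start_s") %in%
                  names(sweeps$protocol)),
           "sweep set does not carry a two-pulse recovery protocol")
  amp_of <- function(sw, start_s, end_s) {
    onset <- which(sw$time_s >= start_s &
                     sw$time_s < start_s + peak_window_s)
    abort_if(length(onset) == 0, "empty onset window")
    mean(sw$signal[onset]) -
      .end_window_mean(sw, start_s, end_s, end_fraction)
  }
  out <- NULL
  for (i in seq_along(sweeps$sweeps)) {
    sw <- sweeps$sweeps[[i]]
    pr <- sweeps$protocol[i, ]
    ito1 <- amp_of(sw, pr$pulse_start_s, pr$pulse_end_s)
    ito2 <- amp_of(sw, pr$pulse2_start_s, pr$pulse2_end_s)
    out <- rbind(out, data.frame(interval_s = pr$interval_s,
                                 ratio = ito2 / ito1))
  }
  out
}

#' Boltzmann fit of normalized activation or availability data
#'
#' Least-squares fit of `y = 1 / (1 + exp(s (V50 - V) / k))` with `s = +1`
#' for activation (rising with voltage) and `s = -1` for inactivation
#' (falling). The slope `k` is reported positive with the direction flag.
#'
#' @param v Test or conditioning potentials, mV.
#' @param y Normalized conductance or availability.
#' @param direction `"activation"` or `"inactivation"`.
#' @return List of class `boltzmann_fit`: `v50`, `slope`, `direction`,
#'   `residual` (RSS), `fitted`.
#' @export
fit_boltzmann <- function(v, y, direction = c("activation", "inactivation")) {
  direction <- match.arg(direction)
  abort_if(length(v) < 4, "need at least 4 points spanning the transition")
  abort_if(diff(range(y)) < 0.2,
           "no transition in the data (y nearly constant); cannot fit")
  s <- if (direction == "activation") 1 else -1
  df <- data.frame(v = v, y = y)
  start <- list(v50 = v[which.min(abs(y - 0.5))], k = 5)
  fit <- try(minpack.lm::nlsLM(
    y ~ 1 / (1 + exp(s * (v50 - v) / k)), data = df, start = start,
    lower = c(v50 = min(v) - 100, k = 0.1),
    upper = c(v50 = max(v) + 100, k = 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  abort_if(inherits(fit, "try-error"),
           "Boltzmann fit did not converge: %s", as.character(fit))
  cf <- stats::coef(fit)
  structure(list(v50 = unname(cf["v50"]), slope = unname(cf["k"]),
                 direction = direction,
                 residual = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit)),
            class = "boltzmann_fit")
}

# Log-spaced two-component grid with linear amplitudes (variable
# projection); returns the best starting values.
.biexp_grid <- function(t, y, with_offset = TRUE) {
  span <- diff(range(t))
  dt <- min(diff(sort(unique(t))))
  taus <- exp(seq(log(max(dt, span / 500)), log(span * 2), length.out = 14))
  best <- NULL
  for (i in seq_along(taus)) for (j in seq_along(taus)) {
    if (taus[j] < 3 * taus[i]) next
    e1 <- exp(-t / taus[i]); e2 <- exp(-t / taus[j])
    X <- if (with_offset) cbind(e1, e2, 1) else cbind(e1, e2)
    cf <- try(qr.coef(qr(X), y), silent = TRUE)
    if (inherits(cf, "try-error") || any(is.na(cf))) next
    rss <- sum((y - X %*% cf)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, tau1 = taus[i], tau2 = taus[j],
                   a1 = unname(cf[1]), a2 = unname(cf[2]),
                   c = if (with_offset) unname(cf[3]) else 0)
    }
  }
  abort_if(is.null(best), "could not initialize the two-component fit")
  best
}

#' Bi-exponential fit of a decaying current
#'
#' Least-squares fit of `I(t) = A_f exp(-t/tau_f) + A_s exp(-t/tau_s) + C`,
#' initialized by a log-spaced time-constant grid search with linearly
#' solved amplitudes. Components are ordered so `tau_fast < tau_slow`;
#' fractional contributions `c1 + c2 = 1` by construction. A warning is
#' issued when the fitted constants are separated by less than a factor 2.
#'
#' @param t Time since the decay start (any consistent unit; outputs follow
#'   it).
#' @param current Current samples.
#' @return List of class `biexp_fit`: `tau_fast`, `tau_slow`, `amp_fast`,
#'   `amp_slow`, `c1`, `c2`, `offset`, `residual`.
#' @export
fit_biexponential <- function(t, current) {
  abort_if(length(t) < 6, "need at least 6 samples")
  g <- .biexp_grid(t, current, with_offset = TRUE)
  df <- data.frame(t = t, y = current)
  fit <- try(minpack.lm::nlsLM(
    y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2) + cc, data = df,
    start = list(a1 = g$a1, a2 = g$a2, tau1 = g$tau1, tau2 = g$tau2,
                 cc = g$c),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    cf <- c(a1 = g$a1, a2 = g$a2, tau1 = g$tau1, tau2 = g$tau2, cc = g$c)
    rss <- g$rss
  } else {
    cf <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
  }
  ord <- order(c(cf["tau1"], cf["tau2"]))
  taus <- unname(c(cf["tau1"], cf["tau2"])[ord])
  amps <- unname(c(cf["a1"], cf["a2"])[ord])
  if (taus[2] / taus[1] < 2) {
    warning("time constants differ by less than a factor 2; ",
            "components are poorly separable")
  }
  structure(list(tau_fast = taus[1], tau_slow = taus[2],
                 amp_fast = amps[1], amp_slow = amps[2],
                 c1 = amps[1] / (amps[1] + amps[2]),
                 c2 = amps[2] / (amps[1] + amps[2]),
                 offset = unname(cf["cc"]), residual = rss),
            class = "biexp_fit")
}

#' Bi-phasic association fit of recovery from inactivation
#'
#' Least-squares fit of `y(t) = 1 - a exp(-t/K_fast) - b exp(-t/K_slow)`
#' with non-negative `a`, `b`; `y(0) = 1 - a - b` and `y` tends to 1 by
#' construction. Initialized by grid search with linearly solved amplitudes.
#'
#' @param interval Repolarization intervals (unit carried to the `K`s).
#' @param ratio Second-pulse to first-pulse current ratios.
#' @return List of class `recovery_fit`: `k_fast`, `k_slow`, `frac_fast`,
#'   `frac_slow`, `a`, `b`, `residual`.
#' @export
fit_recovery <- function(interval, ratio) {
  abort_if(length(interval) < 5, "need at least 5 recovery intervals")
  g <- .biexp_grid(interval, 1 - ratio, with_offset = FALSE)
  df <- data.frame(t = interval, y = ratio)
  fit <- try(minpack.lm::nlsLM(
    y ~ 1 - a * exp(-t / kf) - b * exp(-t / ks), data = df,
    start = list(a = max(g$a1, 0), b = max(g$a2, 1e-6),
                 kf = g$tau1, ks = g$tau2),
    lower = c(a = 0, b = 0, kf = 1e-8, ks = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  abort_if(inherits(fit, "try-error"),
           "recovery fit did not converge")
  cf <- stats::coef(fit)
  ord <- order(c(cf["kf"], cf["ks"]))
  ks <- unname(c(cf["kf"], cf["ks"])[ord])
  ab <- unname(c(cf["a"], cf["b"])[ord])
  structure(list(k_fast = ks[1], k_slow = ks[2],
                 frac_fast = ab[1] / (ab[1] + ab[2]),
                 frac_slow = ab[2] / (ab[1] + ab[2]),
                 a = ab[1], b = ab[2],
                 residual = sum(stats::resid(fit)^2)),
            class = "recovery_fit")
}

#' Fit the bi-exponential decay of the largest-depolarization sweep
#'
#' Convenience wrapper: takes the sweep at the given commanded potential,
#' restricts to the decay (from the in-pulse peak to the pulse end) and
#' fits [fit_biexponential()].
#'
#' @param sweeps An I-V [sweep_set()].
#' @param v_pip_mv Commanded potential of the sweep to fit (default +60).
#' @return A `biexp_fit`.
#' @export
fit_ito_decay <- function(sweeps, v_pip_mv = 60) {
  stopifnot(inherits(sweeps, "sweep_set"))
  i <- which(sweeps$protocol$v_pip_mv == v_pip_mv)[1]
  abort_if(is.na(i), "no sweep at %g mV", v_pip_mv)
  sw <- sweeps$sweeps[[i]]
  pr <- sweeps$protocol[i, ]
  idx <- .pulse_window(sw, pr$pulse_start_s, pr$pulse_end_s)
  pk <- idx[which.max(sw$signal[idx])]
  sel <- idx[idx >= pk]
  fit_biexponential(sw$time_s[sel] - sw$time_s[pk], sw$signal[sel])
}
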