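#' Specification for voltage-clamp sweep simulation
#'
#' Defaults are anchored to the study's measured constants so simulated cells
#' look like real ventricular myocytes: bi-exponential transient-outward
#' inactivation with tau_fast 48.7 ms / tau_slow 322 ms and a 55.2% fast
#' contribution, steady-state inactivation with half-potential -34 mV,
#' bi-phasic recovery with K_fast 50.5 ms / K_slow 1319 ms, and end-of-pulse
#' delayed-rectifier and Ba-sensitive inward-rectifier densities near 19 and
#' -6 pA/pF.
#'
#' @param holding_potential mV.
#' @param step_potentials mV; protocol-specific defaults are used when
#'   `NULL` (I-V: +60 to -80 mV in -20 mV steps; inward rectifier: -120 to
#'   +40 mV in 10 mV steps; inactivation conditioning: -80 to +10 mV).
#' @param step_duration s (600 ms pulses).
#' @param ito_params List: `amp_fast`, `amp_slow` (pA at full activation),
#'   `tau_fast`, `tau_slow` (s), `steady_current` (pA, end-of-pulse
#'   delayed-rectifier component at full activation).
#' @param act_params Activation Boltzmann `v50`, `slope` (mV).
#' @param inact_params Steady-state inactivation Boltzmann `v50`, `slope`.
#' @param recovery_params List: `k_fast`, `k_slow` (s), `frac_fast`
#'   (fractions sum to 1), `n_intervals`, `first_interval` (s; interval grid
#'   grows by factor 1.5).
#' @param ik1_params List: `g` (pA/mV), `e_k` (mV), rectification `v_half`,
#'   `slope` (mV), leak conductance `g_leak` (pA/mV).
#' @param capacitance pF.
#' @param noise_sd pA.
#' @param sampling_rate Hz.
#' @param pulse_start_s Pre-pulse baseline length within each sweep, s.
#' @param seed RNG seed.
#' @return An `ephys_sim_spec` list.
#' @export
ephys_sim_spec <- function(holding_potential = -90,
                           step_potentials = NULL,
                           step_duration = 0.6,
                           ito_params = list(amp_fast = 0.552 * 7955,
                                             amp_slow = 0.448 * 7955,
                                             tau_fast = 0.0487,
                                             tau_slow = 0.322,
                                             steady_current = 2716),
                           act_params = list(v50 = 5, slope = 12),
                           inact_params = list(v50 = -34, slope = 5),
                           recovery_params = list(k_fast = 0.0505,
                                                  k_slow = 1.319,
                                                  frac_fast = 0.75,
                                                  n_intervals = 16,
                                                  first_interval = 0.01),
                           ik1_params = list(g = 30, e_k = -85,
                                             v_half = -60, slope = 20,
                                             g_leak = 2),
                           capacitance = 172.6,
                           noise_sd = 0,
                           sampling_rate = 5000,
                           pulse_start_s = 0.05,
                           seed = 1L) {
  abort_if(ito_params$tau_fast >= ito_params$tau_slow,
           "tau_fast must be smaller than tau_slow")
  abort_if(recovery_params$frac_fast < 0 || recovery_params$frac_fast > 1,
           "frac_fast must be in [0, 1] (fractions sum to 1)")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(holding_potential = holding_potential,
                 step_potentials = step_potentials,
                 step_duration = step_duration,
                 ito_params = ito_params, act_params = act_params,
                 inact_params = inact_params,
                 recovery_params = recovery_params,
                 ik1_params = ik1_params,
                 capacitance = capacitance, noise_sd = noise_sd,
                 sampling_rate = sampling_rate,
                 pulse_start_s = pulse_start_s, seed = seed),
            class = "ephys_sim_spec")
}

boltzmann_act <- function(v, v50, slope) 1 / (1 + exp((v50 - v) / slope))
boltzmann_inact <- function(v, v50, slope) 1 / (1 + exp((v - v50) / slope))

# Decaying outward current during a pulse, t measured from pulse onset (s).
.ito_current <- function(t, gate, p) {
  gate * (p$amp_fast * exp(-t / p$tau_fast) +
            p$amp_slow * exp(-t / p$tau_slow) + p$steady_current)
}

.make_sweep <- function(time, signal) data.frame(time_s = time, signal = signal)

#' Generate voltage-clamp sweep families with ground truth
#'
#' Four protocols:
#' * `"iv"`: 600 ms steps from the holding potential; current is the
#'   bi-exponential transient-outward decay plus a steady component, scaled
#'   by the activation Boltzmann at each potential.
#' * `"inactivation"`: two-pulse availability protocol; the test-pulse
#'   current is scaled by the inactivation Boltzmann of the conditioning
#'   potential.
#' * `"recovery"`: paired pulses separated by repolarization intervals that
#'   grow stepwise by a factor of 1.5; the second pulse is scaled by the
#'   bi-phasic recovery curve.
#' * `"ik1"`: paired control/blocked sweep sets; the control carries a
#'   Ba-sensitive inward-rectifier component on top of a linear leak, the
#'   blocked sweeps carry the leak only.
#'
#' @param spec An [ephys_sim_spec()].
#' @param protocol One of `"iv"`, `"inactivation"`, `"recovery"`, `"ik1"`.
#' @return For `"ik1"`: list `control`, `blocked` (both [sweep_set()]),
#'   `truth`. Otherwise: list `sweeps` ([sweep_set()]), `truth` (data frame
#'   plus model constants).
#' @export
gen_vclamp_sweeps <- function(spec,
                              protocol = c("iv", "inactivation",
                                           "recovery", "ik1")) {
  stopifnot(inherits(spec, "ephys_sim_spec"))
  protocol <- match.arg(protocol)
  fs <- spec$sampling_rate
  t_pre <- spec$pulse_start_s
  dur <- spec$step_duration
  p <- spec$ito_params

  with_seed(spec$seed, {
    add_noise <- function(x) {
      if (spec$noise_sd > 0) x + stats::rnorm(length(x), 0, spec$noise_sd)
      else x
    }

    if (protocol == "iv") {
      pots <- spec$step_potentials %||% seq(60, -80, by = -20)
      time <- seq(0, t_pre + dur, by = 1 / fs)
      in_pulse <- time >= t_pre
      sweeps <- list(); truth <- NULL
      for (v in pots) {
        gate <- boltzmann_act(v, spec$act_params$v50, spec$act_params$slope)
        sig <- numeric(length(time))
        sig[in_pulse] <- .ito_current(time[in_pulse] - t_pre, gate, p)
        sweeps[[length(sweeps) + 1]] <- .make_sweep(time, add_noise(sig))
        # analytic peak (pulse onset) and end-window mean of the model
        w0 <- dur * 0.95
        endmean <- gate * (p$amp_fast * p$tau_fast *
                             (exp(-w0 / p$tau_fast) - exp(-dur / p$tau_fast)) +
                           p$amp_slow * p$tau_slow *
                             (exp(-w0 / p$tau_slow) - exp(-dur / p$tau_slow))) /
          (dur - w0) + gate * p$steady_current
        truth <- rbind(truth, data.frame(
          v_pip_mv = v, gate = gate,
          peak_pA = gate * (p$amp_fast + p$amp_slow + p$steady_current),
          end_mean_pA = endmean))
      }
      truth$ito_density_pA_pF <- (truth$peak_pA - truth$end_mean_pA) /
        spec$capacitance
      truth$ik_density_pA_pF <- truth$end_mean_pA / spec$capacitance
      prot <- data.frame(v_pip_mv = pots, pulse_start_s = t_pre,
                         pulse_end_s = t_pre + dur)
      return(list(sweeps = sweep_set(sweeps, prot, "iv", spec$capacitance),
                  truth = truth))
    }

    if (protocol == "inactivation") {
      pots <- spec$step_potentials %||% seq(-80, 10, by = 10)
      time <- seq(0, t_pre + dur, by = 1 / fs)
      in_pulse <- time >= t_pre
      gate60 <- boltzmann_act(60, spec$act_params$v50, spec$act_params$slope)
      avail <- boltzmann_inact(pots, spec$inact_params$v50,
                               spec$inact_params$slope)
      sweeps <- lapply(avail, function(a) {
        sig <- numeric(length(time))
        sig[in_pulse] <- a * .ito_current(time[in_pulse] - t_pre, gate60, p)
        .make_sweep(time, add_noise(sig))
      })
      prot <- data.frame(v_pip_mv = pots, pulse_start_s = t_pre,
                         pulse_end_s = t_pre + dur)
      return(list(sweeps = sweep_set(sweeps, prot, "inactivation",
                                     spec$capacitance),
                  truth = data.frame(v_conditioning_mv = pots,
                                     availability = avail,
                                     v50 = spec$inact_params$v50,
                                     slope = spec$inact_params$slope)))
    }

    if (protocol == "recovery") {
      rp <- spec$recovery_params
      intervals <- rp$first_interval * 1.5^(seq_len(rp$n_intervals) - 1)
      gate60 <- boltzmann_act(60, spec$act_params$v50, spec$act_params$slope)
      sweeps <- list(); prot <- NULL
      frac <- 1 - rp$frac_fast * exp(-intervals / rp$k_fast) -
        (1 - rp$frac_fast) * exp(-intervals / rp$k_slow)
      for (i in seq_along(intervals)) {
        gap <- intervals[i]
        t_end <- t_pre + dur + gap + dur + 0.05
        time <- seq(0, t_end, by = 1 / fs)
        sig <- numeric(length(time))
        p1 <- time >= t_pre & time < t_pre + dur
        p2s <- t_pre + dur + gap
        p2 <- time >= p2s & time < p2s + dur
        sig[p1] <- .ito_current(time[p1] - t_pre, gate60, p)
        sig[p2] <- frac[i] * .ito_current(time[p2] - p2s, gate60, p) +
          (1 - frac[i]) * gate60 * p$steady_current
        sweeps[[i]] <- .make_sweep(time, add_noise(sig))
        prot <- rbind(prot, data.frame(v_pip_mv = 60, interval_s = gap,
                                       pulse_start_s = t_pre,
                                       pulse_end_s = t_pre + dur,
                                       pulse2_start_s = p2s,
                                       pulse2_end_s = p2s + dur))
      }
      return(list(sweeps = sweep_set(sweeps, prot, "recovery",
                                     spec$capacitance),
                  truth = data.frame(interval_s = intervals, ratio = frac,
                                     k_fast = rp$k_fast, k_slow = rp$k_slow,
                                     frac_fast = rp$frac_fast)))
    }

    # ik1: paired control / Ba-blocked sweep sets
    kp <- spec$ik1_params
    pots <- spec$step_potentials %||% seq(-120, 40, by = 10)
    time <- seq(0, t_pre + dur, by = 1 / fs)
    in_pulse <- time >= t_pre
    ba_current <- kp$g * (pots - kp$e_k) /
      (1 + exp((pots - kp$v_half) / kp$slope))
    leak <- kp$g_leak * (pots - 0)
    mk <- function(level_per_pot) {
      lapply(level_per_pot, function(lv) {
        sig <- numeric(length(time))
        sig[in_pulse] <- lv
        .make_sweep(time, add_noise(sig))
      })
    }
    prot <- data.frame(v_pip_mv = pots, pulse_start_s = t_pre,
                       pulse_end_s = t_pre + dur)
    list(control = sweep_set(mk(leak + ba_current), prot, "ik1",
                             spec$capacitance),
         blocked = sweep_set(mk(leak), prot, "ik1", spec$capacitance),
         truth = data.frame(v_pip_mv = pots, ba_current_pA = ba_current,
                            ik1_density_pA_pF = ba_current /
                              spec$capacitance))
  })
}

#' Generate a paced action-potential trace with ground truth
#'
#' Template per beat: resting potential, a linear upstroke of `rise_ms`
#' milliseconds to the overshoot peak, and a single-exponential
#' repolarization whose time constant is set from the requested APD50. All
#' AP durations therefore have closed forms that the truth table reports.
#'
#' @param rmp Resting membrane potential, mV.
#' @param overshoot Peak potential above 0 mV, mV.
#' @param apd50 Action-potential duration at 50% repolarization, ms.
#' @param n_beats Number of paced beats.
#' @param pacing Hz.
#' @param noise_sd mV.
#' @param rise_ms Upstroke duration, ms.
#' @param sampling_rate Hz.
#' @param seed RNG seed.
#' @return List: `recording` (channels `membrane_potential`, `stimulus`) and
#'   `truth` (rmp, dvdt_max mV/ms, overshoot, apd20/50/90/apd_0mv ms,
#'   stimulus times).
#' @export
gen_ap_trace <- function(rmp = -85, overshoot = 30, apd50 = 25,
                         n_beats = 30, pacing = 1, noise_sd = 0,
                         rise_ms = 1, sampling_rate = 20000, seed = 1L) {
  abort_if(n_beats < 1, "need at least one beat")
  abort_if(overshoot < 0, "overshoot is defined as the peak above 0 mV")
  if (n_beats < 30) {
    warning("fewer than 30 beats: the default 30th-beat analysis rule ",
            "cannot be applied to this trace")
  }
  d <- rise_ms / 1000
  tau <- (apd50 / 1000 - d) / log(2)
  abort_if(tau <= 0, "apd50 must exceed the upstroke duration")
  peak <- overshoot
  stim_times <- 0.5 + (seq_len(n_beats) - 1) / pacing
  t_end <- stim_times[n_beats] + 1 / pacing
  time <- seq(0, t_end, by = 1 / sampling_rate)
  v <- rep(rmp, length(time))
  for (t0 in stim_times) {
    up <- time >= t0 & time < t0 + d
    v[up] <- rmp + (peak - rmp) * (time[up] - t0) / d
    rep_sel <- time >= t0 + d & time < t0 + 1 / pacing
    v[rep_sel] <- rmp + (peak - rmp) * exp(-(time[rep_sel] - t0 - d) / tau)
  }
  rec <- with_seed(seed, {
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    ts_recording(time, list(
      membrane_potential = v,
      stimulus = render_stimulus_channel(time, stim_times, sampling_rate)),
      sampling_rate)
  })
  apd <- function(x) 1000 * (d + tau * log(100 / (100 - x)))
  truth <- list(rmp = rmp, overshoot = overshoot,
                dvdt_max = (peak - rmp) / rise_ms,
                apd20 = apd(20), apd50 = apd(50), apd90 = apd(90),
                apd_0mv = 1000 * (d + tau * log((peak - rmp) / (0 - rmp))),
                stimulus_times = stim_times)
  list(recording = rec, truth = truth)
}
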