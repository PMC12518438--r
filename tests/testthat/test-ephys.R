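test_that("action-potential metrics hit the template truth", {
  ap <- gen_ap_trace(rmp = -85, overshoot = 30, apd50 = 25, n_beats = 30)
  m <- measure_ap(ap$recording)
  dt_ms <- 1000 / ap$recording$sampling_rate
  expect_equal(m$rmp, ap$truth$rmp, tolerance = 1e-6)
  expect_equal(m$dvdt_max, ap$truth$dvdt_max, tolerance = 0.01)
  expect_equal(m$overshoot, ap$truth$overshoot, tolerance = 0.01)
  for (f in c("apd20", "apd50", "apd90", "apd_0mv")) {
    expect_lt(abs(m[[f]] - ap$truth[[f]]), dt_ms + 1e-9)
  }
  expect_true(m$apd20 <= m$apd50 && m$apd50 <= m$apd90)
})

test_that("the 30th-beat rule is enforced and degenerate traces rejected", {
  expect_warning(ap <- gen_ap_trace(n_beats = 10), "30")
  expect_error(measure_ap(ap$recording), "30th")
  m10 <- measure_ap(ap$recording, beat_index = 5)
  expect_equal(m10$rmp, -85, tolerance = 1e-6)
  # constant trace has no upstroke
  time <- seq(0, 2, 1 / 5000)
  stim <- numeric(length(time)); stim[c(1000, 6000)] <- 5
  flat <- ts_recording(time, list(membrane_potential = rep(-80, length(time)),
                                  stimulus = stim))
  expect_error(measure_ap(flat, beat_index = 1), "upstroke")
})

test_that("peak-minus-end extraction matches the analytic decay", {
  es <- ephys_sim_spec(noise_sd = 0)
  iv <- gen_vclamp_sweeps(es, "iv")
  ito <- extract_ito(iv$sweeps)
  expect_equal(ito$ito_density_pA_pF, iv$truth$ito_density_pA_pF,
               tolerance = 0.01)
  ik <- extract_ik(iv$sweeps)
  expect_equal(ik$ik_density_pA_pF, iv$truth$ik_density_pA_pF,
               tolerance = 0.01)
  # pure steady current: peak equals end, transient component is zero
  es0 <- ephys_sim_spec(ito_params = list(amp_fast = 0, amp_slow = 0,
                                          tau_fast = 0.05, tau_slow = 0.3,
                                          steady_current = 2000),
                        noise_sd = 0)
  iv0 <- gen_vclamp_sweeps(es0, "iv")
  expect_equal(extract_ito(iv0$sweeps)$ito_pA, rep(0, 8), tolerance = 1e-9)
  # density scales as 1 / capacitance
  es2 <- ephys_sim_spec(noise_sd = 0, capacitance = 2 * es$capacitance)
  iv2 <- gen_vclamp_sweeps(es2, "iv")
  expect_equal(extract_ito(iv2$sweeps)$ito_density_pA_pF,
               ito$ito_density_pA_pF / 2, tolerance = 1e-9)
})

test_that("end-of-pulse means agree with a brute-force window mean", {
  es <- ephys_sim_spec(noise_sd = 5, seed = 9)
  iv <- gen_vclamp_sweeps(es, "iv")
  sw <- iv$sweeps$sweeps[[1]]
  pr <- iv$sweeps$protocol[1, ]
  w0 <- pr$pulse_end_s - 0.05 * (pr$pulse_end_s - pr$pulse_start_s)
  ref <- mean(sw$signal[sw$time_s >= w0 & sw$time_s < pr$pulse_end_s])
  expect_equal(extract_ik(iv$sweeps)$end_pA[1], ref, tolerance = 1e-12)
})

test_that("Ba-difference current isolates the inward rectifier", {
  es <- ephys_sim_spec(noise_sd = 0)
  k1 <- gen_vclamp_sweeps(es, "ik1")
  d <- extract_ik1(k1$control, k1$blocked)
  expect_equal(d$ik1_density_pA_pF, k1$truth$ik1_density_pA_pF,
               tolerance = 1e-9)
  expect_lt(d$ik1_density_pA_pF[d$v_pip_mv == -120], 0)  # inward = negative
  # blocked identical to control -> zero everywhere
  z <- extract_ik1(k1$blocked, k1$blocked)
  expect_equal(z$ik1_pA, rep(0, nrow(z)))
  # mismatched protocols are rejected
  es2 <- ephys_sim_spec(step_potentials = seq(-100, 0, 20))
  k2 <- gen_vclamp_sweeps(es2, "ik1")
  expect_error(extract_ik1(k1$control, k2$blocked), "do not match")
})

test_that("Boltzmann fits round-trip exactly and reject flat data", {
  v <- seq(-80, 10, by = 10)
  y <- 1 / (1 + exp((v - (-34)) / 5))
  f <- fit_boltzmann(v, y, "inactivation")
  expect_equal(f$v50, -34, tolerance = 1e-6)
  expect_equal(f$slope, 5, tolerance = 1e-6)
  va <- seq(-40, 60, by = 20)
  ya <- 1 / (1 + exp((5 - va) / 12))
  fa <- fit_boltzmann(va, ya, "activation")
  expect_equal(fa$v50, 5, tolerance = 1e-5)
  expect_error(fit_boltzmann(v, rep(1, length(v)), "inactivation"),
               "no transition")
  # 1% noise, many replicates: V50 bias well under half a millivolt
  set.seed(31)
  v50s <- replicate(100, {
    yn <- y + rnorm(length(y), 0, 0.01)
    fit_boltzmann(v, yn, "inactivation")$v50
  })
  expect_lt(abs(mean(v50s) + 34), 0.5)
})

test_that("bi-exponential fits recover the published-scale constants", {
  t <- seq(0, 0.6, 1 / 5000)
  I <- 4030 * exp(-t / 0.0487) + 3270 * exp(-t / 0.322) + 3300
  f <- fit_biexponential(t, I)
  expect_equal(f$tau_fast, 0.0487, tolerance = 1e-4)
  expect_equal(f$tau_slow, 0.322, tolerance = 1e-4)
  expect_equal(f$c1, 4030 / 7300, tolerance = 1e-4)
  expect_equal(f$c1 + f$c2, 1)
  # time-origin shift leaves the time constants unchanged
  f2 <- fit_biexponential(t + 0.25 - 0.25, I)  # identical grid
  fshift <- fit_biexponential(t, I)            # decays are fit from onset
  expect_equal(fshift$tau_fast, f$tau_fast)
  # single-exponential input: one component vanishes or merges
  I1 <- 5000 * exp(-t / 0.1) + 100
  expect_warning(f1 <- fit_biexponential(t, I1), "poorly separable")
  expect_equal(f1$amp_fast * exp(-0.05 / f1$tau_fast) +
                 f1$amp_slow * exp(-0.05 / f1$tau_slow) + f1$offset,
               5000 * exp(-0.05 / 0.1) + 100, tolerance = 1)
})

test_that("recovery fits honour their asymptotics and round-trip", {
  iv <- 0.01 * 1.5^(0:15)
  y <- 1 - 0.75 * exp(-iv / 0.0505) - 0.25 * exp(-iv / 1.319)
  f <- fit_recovery(iv, y)
  expect_equal(f$k_fast, 0.0505, tolerance = 1e-4)
  expect_equal(f$k_slow, 1.319, tolerance = 1e-4)
  expect_equal(f$frac_fast, 0.75, tolerance = 1e-4)
  # y(0) = 1 - a - b and y -> 1 by construction of the fitted model
  expect_equal(1 - f$a - f$b, y[1] - (0.75 * (1 - exp(-iv[1] / 0.0505)) +
                                        0.25 * (1 - exp(-iv[1] / 1.319))),
               tolerance = 1e-3)
})

test_that("sweep-level recovery extraction reproduces the truth curve", {
  es <- ephys_sim_spec(noise_sd = 0)
  rec <- gen_vclamp_sweeps(es, "recovery")
  rr <- extract_recovery(rec$sweeps)
  # intervals grow stepwise by a factor 1.5
  expect_equal(diff(log(rr$interval_s)), rep(log(1.5), nrow(rr) - 1),
               tolerance = 1e-9)
  expect_equal(rr$ratio, rec$truth$ratio, tolerance = 0.02)
  f <- fit_recovery(rr$interval_s, rr$ratio)
  expect_equal(f$k_fast, es$recovery_params$k_fast, tolerance = 0.05)
  expect_equal(f$k_slow, es$recovery_params$k_slow, tolerance = 0.05)
})

test_that("inactivation protocol sweeps recover the availability curve", {
  es <- ephys_sim_spec(noise_sd = 0)
  ina <- gen_vclamp_sweeps(es, "inactivation")
  amp <- extract_ito(ina$sweeps)
  y <- amp$ito_pA / max(amp$ito_pA)
  f <- fit_boltzmann(ina$truth$v_conditioning_mv, y, "inactivation")
  expect_equal(f$v50, -34, tolerance = 0.1)
  expect_equal(f$slope, 5, tolerance = 0.1)
})
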