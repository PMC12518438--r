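#!/usr/bin/env Rscript
# Patch-clamp analysis: I-V extraction from the simulated sweep files,
# Ba-difference inward rectifier, bi-exponential decay fit, and (from
# freshly generated protocols) steady-state inactivation and recovery fits
# plus action-potential metrics.

library(myoequiv)

raw <- "results/raw"
out <- "results"

iv <- read_sweeps(file.path(raw, "iv"))
ito <- extract_ito(iv)
ik <- extract_ik(iv)
write.csv(merge(ito, ik), file.path(out, "ito_ik_iv.csv"),
          row.names = FALSE)
cat(sprintf("I_to at +60 mV: %.1f pA/pF; I_K at +60 mV: %.1f pA/pF\n",
            ito$ito_density_pA_pF[ito$v_pip_mv == 60],
            ik$ik_density_pA_pF[ik$v_pip_mv == 60]))

bx <- fit_ito_decay(iv)
cat(sprintf("bi-exponential decay at +60 mV: tau_fast %.1f ms, tau_slow %.0f ms, c1 %.1f%%\n",
            1000 * bx$tau_fast, 1000 * bx$tau_slow, 100 * bx$c1))

k1c <- read_sweeps(file.path(raw, "ik1_control"))
k1b <- read_sweeps(file.path(raw, "ik1_blocked"))
d1 <- extract_ik1(k1c, k1b)
write.csv(d1, file.path(out, "ik1_iv.csv"), row.names = FALSE)
cat(sprintf("Ba-sensitive I_K1 at -120 mV: %.2f pA/pF\n",
            d1$ik1_density_pA_pF[d1$v_pip_mv == -120]))

es <- ephys_sim_spec(noise_sd = 20, seed = 2)
ina <- gen_vclamp_sweeps(es, "inactivation")
amp <- extract_ito(ina$sweeps)
fb <- fit_boltzmann(ina$truth$v_conditioning_mv,
                    amp$ito_pA / max(amp$ito_pA), "inactivation")
cat(sprintf("steady-state inactivation: V50 %.1f mV, k %.2f mV\n",
            fb$v50, fb$slope))

rec <- gen_vclamp_sweeps(es, "recovery")
rr <- extract_recovery(rec$sweeps)
fr <- fit_recovery(rr$interval_s, rr$ratio)
cat(sprintf("recovery from inactivation: K_fast %.1f ms, K_slow %.0f ms (fast fraction %.0f%%)\n",
            1000 * fr$k_fast, 1000 * fr$k_slow, 100 * fr$frac_fast))
fit_tab <- data.frame(parameter = c("tau_fast_ms", "tau_slow_ms", "c1_pct",
                                    "v50_inact_mv", "k_fast_ms",
                                    "k_slow_ms"),
                      value = c(1000 * bx$tau_fast, 1000 * bx$tau_slow,
                                100 * bx$c1, fb$v50, 1000 * fr$k_fast,
                                1000 * fr$k_slow))
write.csv(fit_tab, file.path(out, "ephys_fits.csv"), row.names = FALSE)

ap <- gen_ap_trace(noise_sd = 0.3, seed = 3)
m <- measure_ap(ap$recording)
write.csv(m, file.path(out, "ap_metrics.csv"), row.names = FALSE)
cat(sprintf("30th AP: RMP %.1f mV, dV/dt_max %.0f mV/ms, overshoot %.1f mV, APD90 %.1f ms\n",
            m$rmp, m$dvdt_max, m$overshoot, m$apd90))
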