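# myoequiv

Quantitative pipeline for testing whether cardiomyocytes isolated after
cold storage of the heart are *equivalent* — structurally and functionally —
to freshly isolated cells. Absence of a significant difference is not
evidence of equivalence, so the package pairs every group comparison
(Welch's *t*, Holm–Bonferroni corrected) with the two one-sided tests
(TOST): groups are declared equivalent when the 1−2α confidence interval
of the mean difference Δ lies inside relevance bounds of ±30% of the
control mean,

    −Δ_L < Δ < Δ_U,   Δ_U = −Δ_L = 0.30·x̄_control,   α = 0.05.

Around that statistics layer the package implements the full measurement
chain of a cold-storage equivalence study, plus a synthetic-data module
that generates every input modality with known ground truth so the whole
chain is testable by parameter recovery:

* **Stimulus-locked beat analysis** of Fura-2 340/380 ratio and sarcomere
  length traces: moving median (radius 10) + moving mean (radius 5)
  filtering, noise amplitude *A*_noise from 200 ms pre-stimulus windows at
  ≤1 Hz pacing, capture gating at 2·*A*_noise, and per-beat diastolic
  level, amplitude, TTP90, TTBL90 and CATD90 = TTP90 + TTBL90, averaged
  over the last six captured beats per pacing frequency
  (0.5–4 Hz ladder). Sarcomere length itself is estimated by Fourier
  analysis of striation profiles.
* **Transverse–axial tubular system (TATS)** quantification from 3D
  membrane-dye stacks: cell and tubule segmentation, volume and skeleton
  density (% of cell volume), mean intracellular voxel-to-tubule distance
  via an exact anisotropic Euclidean distance transform, and a spectral
  regularity score from the longitudinal occupancy spectrum.
* **Mitochondrial TMRM/MTG ratiometry**: autofluorescence cell masks,
  mode + 2 SD mitochondrial thresholding, summed-signal TMRM/MTG ratio
  (inner-membrane-potential indicator) and voxel-wise Pearson
  colocalization.
* **Patch-clamp analysis**: AP metrics from the 30th paced beat (RMP,
  dV/dt_max, overshoot, APD20/50/90/APD_0mV), I_to as peak minus
  end-of-pulse density, I_K as end-of-pulse density, I_K1 as the
  Ba²⁺-sensitive difference current, with Boltzmann activation/
  inactivation fits, bi-exponential decay fits (τ_fast < τ_slow,
  c₁ + c₂ = 1) and bi-phasic recovery fits on 1.5×-growing interval
  grids.

## Worked example

```r
library(myoequiv)

# a synthetic cell paced through the 0.5-4 Hz ladder with 5% noise
spec <- transient_sim_spec(noise_sd = 0.025, missed_beat_prob = 0.05, seed = 1)
cell <- gen_transient_trace(spec)
res  <- analyze_recording(cell$recording, "fura_ratio", "up")
res$summary[, c("pacing_frequency", "n_beats_used", "amplitude", "ttp90", "ttbl90")]
#>   pacing_frequency n_beats_used amplitude      ttp90    ttbl90
#> 1         0.500000            6 0.4921038 0.03978994 0.1364088
#> 2         1.000000            6 0.4930894 0.04015605 0.1323535
#> 3         1.499250            6 0.4958449 0.03969336 0.1345433
#> 4         2.000000            6 0.4936960 0.04064790 0.1377696
#> 5         2.500000            6 0.4907161 0.04124256 0.1336705
#> 6         3.003003            6 0.4842960 0.04092659 0.1290413
#> 7         4.000000            6 0.4857504 0.03952263 0.1227492
```

Each row is the mean over the six last captured beats of one pacing
interval: the recovered amplitude sits within ~2% of the generated 0.5
ratio units, time-to-peak near the template's 41 ms and time-to-baseline
near 132 ms, with the physiological shortening of TTBL at 4 Hz.

```r
# equivalence testing of two per-cell metric samples
g <- gen_group_samples(group_sim_spec(n_per_group = 20, relative_effect = 0))
tost_equivalence(g$control, g$treated)
#> <equivalence_result> effect -1.97, CI [-6.729, 2.789], bounds (-30.57, 30.57)
#>   p_lower = 1.21e-12, p_upper = 2.92e-14 -> EQUIVALENT
```

The `analysis/` directory holds the numbered study drivers
(`01_simulate_cohort.R` … `05_equivalence_study.R`); each writes its
tables under `results/` and prints what it found. The end-to-end driver
`run_synthetic_study()` generates a control and a "stored" synthetic
group across all modalities, runs every analysis stage and emits the
per-metric Welch/Holm/TOST table.

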