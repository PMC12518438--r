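---
title: "Models and methods behind myoequiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myoequiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

myoequiv tests a biological *equivalence* claim — that cardiomyocytes
isolated after cold storage behave like freshly isolated cells — by
re-implementing an entire measurement chain over synthetic data with known
ground truth. This vignette explains the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic
phantoms do and do not establish about real data.

## The equivalence layer

Each per-cell metric is compared between groups twice. Welch's
unequal-variance *t* test (Holm–Bonferroni corrected across the
comparisons of a metric) asks whether the groups differ; the two
one-sided tests (TOST) ask whether they are the same to within a stated
relevance margin. The margin is ±30% of the control-group mean and
α = 0.05; the groups are equivalent exactly when the 90% (1−2α)
confidence interval of the mean difference lies inside the margin, which
is identical to both one-sided p-values falling below α
(`tost_equivalence()` reports both forms and they agree by construction).

Anchoring the margin on the *observed* control mean makes the margin
random and positively correlated with the test statistic. The effect is
small but real: at the exact +30% boundary the data-anchored test
rejects in about 7% of samples at n = 20 instead of 5%. Strict size
control holds only for fixed margins, so `tost_equivalence()` accepts an
explicit `bounds` argument and the package's calibration simulations use
it; the data-anchored variant remains the default for study tables
because a reference level is rarely known a priori. Cells are treated as
independent units (no heart-level random effects); heart identifiers are
carried for reporting only.

The troponin worked example is pure arithmetic: with supernatant
troponin below the assay detection limit (0.045 µg/L) in a 40 ml storage
volume, at most 0.045 × 0.040 = 0.0018 µg were released, which against a
total heart content of 0.35 µg bounds cardiomyocyte damage at ~0.51%.

## Paced-transient model and beat analysis

The transient template is a peak-normalized sigmoidal-rise pulse

$$s(t) \propto \left(1 - e^{-t/\tau_r}\right)^2 e^{-t/\tau_d},$$

with closed-form peak time $t^* = \tau_r \log((\tau_r+2\tau_d)/\tau_r)$.
The squared exponential gives the S-shaped upstroke foot of real
transients; a plain difference of exponentials rises so steeply that its
10%-of-amplitude landmark sits ~1 ms after the stimulus — below the
resolution of the prescribed filtering — and was therefore rejected
during design. Defaults are τ_r = 35 ms and τ_d = 45 ms (TTP90 ≈ 41 ms,
TTBL90 ≈ 132 ms; mouse myocytes near 35 °C), chosen jointly so that (i)
the transient has fully decayed at the 4 Hz top of the pacing ladder —
the generator's truth tables assume isolated beats and the generator
rejects any parameterization leaving >3% residual at the shortest pacing
period — and (ii) the kinetic landmarks remain resolvable under the
fixed filter radii at the 1 kHz default sampling rate. The ladder
(0.5, 1, 1.5, 2, 2.5, 3, 4 Hz; each interval at least 24 stimulations or
at least 12 s) and the 5%-of-amplitude noise level used in recovery
tests are study conditions, not tuning knobs. Stimuli are rendered as
two-sample 5 V impulses so threshold detection is unambiguous; every
generator takes an explicit seed and restores the caller's RNG state.

The analysis pipeline runs in a fixed order: moving median filter
(radius 10 samples, shrinking symmetric windows at the edges), moving
mean filter (radius 5, clipped windows), orientation (contraction traces
are negated), global-minimum offset subtraction, noise estimation, beat
analysis. *A*_noise is the maximum of the offset-subtracted filtered
signal over 200 ms pre-stimulus windows at pacing ≤1 Hz; a beat is
captured when its peak exceeds the diastolic level by at least
2·*A*_noise. Two windowing details matter at this noise level: the
pre-stimulus windows end one filter half-width before the stimulus
(otherwise the smoothed upstroke bleeds in and inflates *A*_noise
several-fold), and the per-beat diastolic level is the *mean* of a short
(20 ms) pre-stimulus window rather than the 200 ms window minimum — a
minimum is biased low by the order of the filtered noise SD, which
shifts the 10% decay crossing by several milliseconds.

Landmarks are located in two stages: a heavily smoothed copy of the beat
window only *places* fit windows; the values come from local
least-squares polynomial fits of the pipeline-filtered signal (a quartic
at the peak, quadratics at the two 10% crossings, linear interpolation as
fallback). Because the final mean-filter stage is a known boxcar, which
maps a local quadratic to itself plus $\mathrm{var}(u)\,c_2$, the fitted
intercepts are deconvolved analytically. Naïve estimators (sample argmax,
first-sample crossing) carry noise-selection biases of almost a
millisecond each, which would consume the recovery tolerance. Per-beat
ties at the peak break toward the earliest sample; a decay truncated by
the next stimulus leaves the beat captured with TTBL90 flagged
unresolved. With these choices, 100 simulated ladder cells at 5% noise
recover amplitude to about −2% (the residual is genuine filter
flattening of the peak), TTP90/TTBL90 to within ~1.5/2 ms, and classify
capture essentially perfectly.

Sarcomere length is estimated from Hann-windowed striation profiles: the
dominant power-spectrum peak within the 1.4–2.4 µm period band, refined
by parabolic interpolation across the neighbouring bins; profiles whose
in-band peak carries under 5% of non-DC power (structureless noise) are
rejected with a diagnostic rather than inverted to a length.

## Tubule phantoms and TATS metrics

The phantom cell is a box (default 40 × 16 × 8 µm in a 2 µm margin,
0.25 × 0.25 × 0.5 µm voxels) whose transverse tubules are line elements
along y on a jittered (x, z) lattice at 2 µm spacing with radius 0.3 µm,
10% dropout and optional axial connectors; the rendered image adds a
cytosolic base level and a bright surface-membrane shell, a Gaussian PSF
(σ = 0.11 µm lateral, 0.30 µm axial — a high-NA confocal), and noise.
The pre-blur tubule mask and the cylinder-geometry closed form
(π r² × total length / cell volume) are kept as ground truth.

Cell segmentation thresholds at the half-maximum between the inside and
outside levels of the *lowest* bimodal split (Otsu applied recursively
downward, since a bright organelle class can dominate the variance),
keeps the largest 3D component (2D labelling per slice merged across
slices), fills holes per slice, and trims one erosion step: bright
structures at the surface bleed roughly one voxel outward regardless of
modality. Tubule segmentation works inside a rim-eroded interior
(default 0.5 µm lateral, 1 µm axial — the elongated axial PSF pushes the
surface membrane deeper in z) with a background-corrected half-maximum
threshold between the interior median and the top-0.1% tubule level;
half-maximum splitting recovers the true tubule radius when the PSF is
narrower than the tubule. A separability gate (the share of variance
explained by the split) returns an empty mask for tubule-free cells
instead of thresholding noise. The rim exclusion necessarily discards
genuine near-surface tubules, so voxel-wise segmentation quality is
evaluated on the analyzed interior, and measured volume densities sit
systematically below the whole-cell truth by roughly the rim share.

The mean tubule distance uses an exact anisotropic 3D Euclidean distance
transform (separable lower-envelope algorithm, compiled; verified
bit-for-bit against exhaustive search). The skeleton is the Lantuéjoul
morphological skeleton with a 6-connected structuring element — iterative
erosions minus openings — which is not homotopy-preserving but is a
faithful thin-set for the density metric (one-voxel tubes are their own
skeleton). The spectral density projects tubule occupancy along the long
axis (per-slice mean within the cell mask) and reports the share of
non-DC power in the 1.5–2.5 µm sarcomeric period band; the score is
translation-invariant, peaks at 1/spacing for lattice phantoms and
exceeds spatially shuffled controls. Because its normalization is an
artifact convention, its numeric values should not be compared with any
externally reported spectral densities — only within-study contrasts are
meaningful.

## Mitochondrial phantoms and ratiometry

Both channels share one mitochondrial compartment: a smoothed Gaussian
field cut at the quantile matching the target volume fraction (30% by
default), giving each channel base + amplitude·indicator within the cell.
The indicator contributes variance $f(1-f)a^2$ that is common to the two
channels, so independent per-channel noise with
$\sigma^2 = f(1-f)a^2(1-r)/r$ yields a within-cell Pearson correlation of
exactly r in expectation; at r = 1 the channels are strictly
proportional. One phantom family cannot make the mode + 2 SD threshold
recover the 30% fraction *and* carry r = 0.7 noise at the same time: at
high correlation (low noise) the threshold lands just under the
mitochondrial intensity and recovers the fraction within a couple of
percentage points, while at the study-realistic r = 0.7 the noise widens
the within-cell SD, pushes the threshold into the mitochondrial
distribution and underestimates the fraction. Real images escape this
because mitochondrial intensities are broad and bright; the phantom's
two-level structure is the worst case, and the package therefore tests
the two properties on the two corresponding phantom regimes.

The threshold itself is the histogram mode of within-cell intensities
(256 equal-width bins over the within-cell range, ties to the lower bin)
plus twice the SD of the raw (unbinned) intensities — binning only
affects the mode, as recorded in the output. The TMRM/MTG indicator is
the ratio of summed within-cell signals: invariant to common gain and to
voxel permutations, equivariant to single-channel gain (a simulated
uncoupler scaling TMRM by 0.2 scales the ratio by exactly 0.2).

## Voltage-clamp models and fits

Simulated currents follow
$I(t) = g(V)\,[A_f e^{-t/\tau_f} + A_s e^{-t/\tau_s} + C]$ during 600 ms
pulses, with Boltzmann gating $g(V) = 1/(1+e^{(V_{50}-V)/k})$
(activation; the inactivation form flips the sign, and slopes are
reported positive with a direction flag — the functional forms are
package conventions). Model constants default to the study scale:
τ_fast = 48.7 ms, τ_slow = 322 ms with a 55.2% fast contribution,
half-inactivation at −34 mV (slope 5 mV), bi-phasic recovery with
K_fast = 50.5 ms and K_slow = 1319 ms (75% fast) on an interval grid
growing stepwise by 1.5×, a cell capacitance of 172.6 pF, and transient/
steady amplitudes calibrated so the extracted noise-free densities are
42.3 pA/pF (peak-minus-end I_to) and 18.9 pA/pF (end-of-pulse I_K) at
+60 mV, with the Ba²⁺-sensitive inward rectifier reaching −5.9 pA/pF at
−120 mV. These are measured population values used as realistic
simulation truth, not quantities the synthetic pipeline "predicts". The
inward-rectifier protocol range is read from the protocol object
(−120 mV up to +40 mV supported).

Extraction follows the stated definitions: I_to = in-pulse maximum minus
the mean of the terminal window (last 5% of the pulse, configurable);
I_K = terminal-window mean; I_K1 = control-minus-blocked terminal
difference at matched potentials; all densities divide by the measured
capacitance and scale exactly as 1/C. One deliberate exception: the
*recovery ratio* measures each pulse's transient amplitude as
onset-window mean minus end mean rather than via the raw maximum — with
identical kinetics in both pulses the onset-window underestimate cancels
exactly in the ratio, whereas a per-sample maximum injects extreme-value
noise that degrades the slow recovery constant several-fold.

All nonlinear fits run Levenberg–Marquardt from a variable-projection
grid initialization: time constants on a log-spaced grid (pairs at least
3× apart), amplitudes solved linearly, best pair refined. Components are
ordered τ_fast < τ_slow after fitting, fractional contributions sum to 1
by construction, recovery amplitudes are bounded non-negative, and fits
with constants closer than 2× warn about poor separability. Noise-free
round trips recover the constants to optimizer precision; at 2%
multiplicative sweep noise the median relative errors of
τ_fast/τ_slow/V50/K_fast/K_slow across 100 seeds stay under 5%, with
K_slow the least identified (its information lives in a handful of
long-interval points).

The action-potential template is resting potential, a 1 ms linear
upstroke to the overshoot peak, and single-exponential repolarization
parameterized by APD50, so every duration has a closed form. Analysis
uses the 30th paced beat (steady state) by default and refuses shorter
trains by name; RMP is the pre-upstroke plateau mean, dV/dt_max the
maximum discrete derivative, overshoot the peak above 0 mV, and APDs run
from the 10%-of-dV/dt_max upstroke crossing to interpolated
repolarization levels. No Hodgkin–Huxley dynamics are simulated — the
template suffices to validate metric extraction, not to study
electrophysiology.

## The end-to-end synthetic study

`run_synthetic_study()` draws two groups of synthetic cells (default 10
per group, between-cell parameter CV 8%) across all modalities, runs
every analysis stage, and tabulates 22 per-cell metrics through the
Welch/Holm/TOST layer. The "stored" group's generating parameters can be
shifted by named relative effects (transient amplitude, sarcomere
shortening, TMRM intensity, I_to amplitude, capacitance). With zero
effects all metrics test equivalent at these settings; with +50% effects
the five affected metrics — and only those — are flagged non-equivalent.
Study phantom sizes are scaled to per-cell runtimes of a second or two
(e.g. a 36 µm-long tubule phantom, ~17 lattice periods, keeps the
spectral score's between-cell CV near 13%); the statistical behaviour,
not the voxel count, is what the study exercises.

## What the phantoms do not show

Synthetic traces have stationary Gaussian noise, identical kinetics for
every beat and no photobleaching, motion, or alternans; phantom cells are
boxes with ideal lattices and two-level intensity structure; sweeps have
no leak drift, series-resistance error or capacitive transients. Passing
recovery tests therefore demonstrates that the *algorithms* implement
their definitions correctly and are calibrated under controlled
conditions — not that segmentation or kinetics are accurate on arbitrary
real recordings. Conversely, every rule that the study conditions fix
(filter radii, the 2·A_noise gate, the six-beat summary, the ±30%
margin, mode + 2 SD) is exercised at those fixed values throughout.
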