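---
title: "Methods: EEG band-power indices, VEP components and the crossover design layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG band-power indices, VEP components and the crossover design layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svtephys)
```

svtephys implements the electrophysiological measurement chain used to
monitor progress in crossover sports-vision-training studies: a
per-epoch EEG relative power spectral density (PSD) pipeline feeding the
frontal theta/gamma Short-Term Memory Load Index (STMLI), transient
visual-evoked-potential (VEP) component extraction, and a
repeated-measures multivariate statistics layer. Because such studies
rarely deposit raw recordings, the package also ships seeded synthetic
generators whose ground truth gives every downstream stage a
parameter-recovery test surface. This vignette records the models,
conventions and numerical decisions; nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The EEG spectral chain

Records are multichannel (nine scalp sites including frontal-midline Fz)
at 256 Hz. Preprocessing removes the channel mean and applies a
zero-phase Butterworth band-pass with 0.5 and 65 Hz edges plus
second-order IIR notches at 50, 60, 100 and 120 Hz (Q = 30). The
band-pass is realized as a cascaded 2nd-order high-pass and 4th-order
low-pass: a transfer-function band-pass with a 0.5 Hz edge at 256 Hz is
numerically fragile under forward-backward filtering, while the cascade
rejects DC to machine precision after demeaning.

Artifact handling is mask-driven **zero insertion**: samples flagged by
an upstream artifact annotation are replaced by zeros and counted. The
package deliberately does not model artifact detection itself (vendor
classifiers are proprietary); the mask is an input, and the synthetic
generator produces masks directly.

PSD is estimated per 1-s epoch from **three 1-s overlays at 50%
overlap** — the only layout satisfying that geometry, so an epoch
labelled `t` spans `[t, t + 2 s)` while epochs advance in 1-s steps.
Each 256-sample overlay is Kaiser-windowed (shape `beta = 14` by
default, configurable), FFT'd and converted to a one-sided periodogram
with window-power correction, in units of µV²/Hz; at 256 samples the
1-Hz analysis bins 1–40 Hz coincide with the FFT grid. An overlay with
more than 128 zero-inserted samples is excluded; an epoch is **valid**
only when at least two overlays remain, and its PSD is the mean over
retained overlays. `overlay_validity()` exposes that rule directly.

Relative PSD divides each bin by the sum of bins 1–40 Hz, and band
powers are arithmetic means of the relative bins: theta 3–7, alpha
8–12, low beta 13–19, high beta 20–29, gamma 30–40 Hz (bins 1–2 enter
the denominator but belong to no band). Two conventions deserve note:

* **Linear-scale relative PSD.** Acquisition software typically reports
  a log10 PSD for normality; fractions of log-values, however, are not
  scale-invariant and can be negative, so relative PSD here is computed
  on the linear PSD and the log10 spectrum is carried as a separate
  reported field. All relative quantities (and the STMLI) are then
  exactly invariant to overall amplitude scaling, a property the test
  suite checks.
* **Kaiser `beta = 14`.** The vendor's shape parameter is unpublished;
  14 gives very strong sidelobe suppression at the price of a wide
  mainlobe (first null near ±4.5 bins), which matters for the generator
  calibration below.

## The STMLI

For each valid epoch at Fz, `STMLI = rPSD(theta) / rPSD(gamma)`, the
ratio of band-averaged relative powers; epochs with zero gamma power are
dropped with a warning. Epochs are assigned to a task when their nominal
1-s span lies fully inside the task's marker interval — strict
containment keeps abutting tasks disjoint. Per task, the series is
aggregated by a **5% trimmed mean** interpreted as symmetric trimming of
`floor(0.05 n)` values per tail (the common statistical definition; the
per-tail reading is a documented convention).

A point any user of per-epoch ratio indices should know: the per-epoch
ratio is a ratio of noisy band estimates, so its expectation exceeds the
ratio of expected band powers by roughly the squared coefficient of
variation of the denominator (a Jensen-inequality effect). With 2-s
windows, three overlapping overlays and a `beta = 14` window, the
package's simulations measure this upward bias at about +12% for the raw
epoch mean and about +6% after 5% trimming (the trim removes more mass
from the heavy right tail), with roughly ±5% between-record variation
for a single 5-min record. Recovery tests therefore average a dozen
simulated participants per condition, and the acceptance suite checks
trimmed-mean recovery of theta/gamma ratios over the grid
{0.25, 0.5, 1, 2} to within ±10% under exactly those problem sizes
(5-min records, 12 records per ratio). On real data the same bias is
present but constant across repeated assessments of a design, so it
cancels from within-subject contrasts; absolute STMLI levels should be
compared only across identical spectral settings.

## The synthetic EEG generator

Each channel is white Gaussian noise shaped in the frequency domain:
Hann-shaped narrow-band bumps for the five analysis bands superimposed
on a 1/f^chi pink floor restricted to the 0.5–65 Hz passband (the
remainder of the 1–40 Hz budget sits on the 1–2 Hz floor bins). Because
the analysis window's mainlobe redistributes power between neighbouring
1-Hz bins, per-region power scalings are **calibrated against the
analysis kernel**: the expected measured band fractions — band sums of
the kernel-convolved spectrum — are solved (one linear system per
record length) to equal the requested targets. Without this step a
concentrated low-frequency floor measurably inflates theta through
window leakage. Scalings are clamped at zero when a target is so extreme
that neighbour leakage alone exceeds it; the clamp is reachable only for
near-zero band targets under a dominant neighbour.

Artifacts are drawn as contiguous segments (Poisson count at a
segments-per-minute rate, uniform placement) and exposed as the mask
that decontamination will zero out; the emitted waveform itself is clean
signal. This mirrors the downstream effect of artifact removal without
modelling blink or EMG waveforms. What the generator does *not*
emulate: volume conduction or any head model (channels are
independent), non-stationarity within a record, real artifact
morphology, and line noise (the record is generated inside the
passband). Passing recovery tests therefore demonstrate correctness of
the measurement chain, not realism of scalp EEG.

Defaults: nine standard channel labels, 256 Hz, band fractions
(theta .20, alpha .25, low beta .15, high beta .12, gamma .10) — an
eyes-open-like profile summing to 0.82 with the remainder on the
low-frequency floor — pink exponent 1, artifacts disabled unless
requested. Every generator takes an explicit integer seed and is a pure
function of (specification, duration).

## Transient VEP simulation and component extraction

Stimulus geometry follows the two protocol families: checkerboards (85%
Michelson contrast, 2 reversals/s, sweeps of 512 samples at 1,024 Hz)
and vertical sinusoidal gratings (10% contrast, 4 reversals/s, 1,024
samples at 2,048 Hz); both sweep lengths equal 0.5 s. Sweeps are
time-locked to every reversal for checkerboards and alternate reversals
for gratings so that averaged sweeps never overlap; a 20-s presentation
yields 40 sweeps either way. `plan_session()` reproduces the session
arithmetic (4 patterns × 3 × 20 s = 240 s of stimulus time) and
`grating_cycles()` the display geometry (4 and 8 cycles for 0.25 and
0.5 cpd on a 15.92° display, half-cycle widths of 2° and 1°).

The noise-free template is a sum of raised-cosine lobes at the N75
(negative), P100 (positive) and N135 (negative) latencies, with lobe
half-widths chosen smaller than the inter-component gaps so the lobes
vanish at each other's peaks: peak latencies and the N75→P100
peak-to-peak amplitude are then exact by construction, which underwrites
the exact-recovery contracts. The peak-to-peak amplitude is split 60/40
between the P100 and N75 lobes.

Detection searches configurable windows — N75 in [55, 95] ms, P100 in
[80, 140] ms, N135 in [115, 190] ms — taking the P100 as the window
maximum, N75 as the pre-P100 minimum and N135 as the post-P100 minimum,
with flags for edge maxima (no interior peak) and ordering violations.
Latencies are reported on the sample grid with no sub-sample
interpolation, matching device-style output; the amplitude is
peak-to-peak and hence baseline-invariant. Three trials per stimulus are
ranked by latency (ties keep trial order — ranking is bookkeeping only),
averaged, and log10-transformed means are attached for the statistics
layer.

## The behavioral crossover generator

Two treatment-order groups (27 + 26 subjects by default) by three
assessments. Each subject's vector is cell mean + a shared subject
effect N(0, ρσ²) + independent noise N(0, (1−ρ)σ²), giving an exactly
compound-symmetric covariance with total variance σ² and correlation ρ
(default 0.5) between any two assessments. Group, time and interaction
cell-mean patterns are fixed zero-sum layouts scaled so that the
root-mean-square of each pattern equals f·σ — the cell-mean definition
of Cohen's f — which maps through the same noncentrality convention as
the power calculator (λ = f²·N·m/(1−ρ) for the interaction), so the
generator and `power_rm_anova()` agree by construction;
`behavioral_empirical_f()` recomputes f from the cell means to machine
precision.

## The statistics layer

Screening follows the conventions of this design family: standardized
z-scores flagged beyond |z| > 3.29 (α = 0.001), Mahalanobis D² per
subject over the full DV × time vector against the χ² cutoff at
α = 0.001 with df equal to the number of columns (a singular covariance
falls back to an eigenvalue pseudo-inverse, flagged), skewness/kurtosis
z-statistics with exact small-sample standard errors, Shapiro-Wilk and
Lilliefors tests, and a log10-transform recommendation when |z| of
skewness or kurtosis exceeds 3.29.

`rm_manova()` implements the doubly multivariate repeated-measures
MANOVA: for d DVs × m times, within-subject effects use the transformed
data Y(I_d ⊗ C) with C orthonormal polynomial contrasts, the between
effect uses per-DV time averages, and hypotheses are tested against a
sum-to-zero group coding so all effects are Type III. Pillai's trace,
Wilks' Λ and Roy's greatest root are computed from the eigenvalues of
HE⁻¹ with the standard F approximations (Rao's for Wilks; Roy's F is an
upper bound). Partial η² conventions: V/s for Pillai, 1 − Λ^(1/s) for
Wilks, λ₁/(1+λ₁) for Roy. Observed power uses the λ = F·df1 convention.
The test suite verifies all of this against `car::Anova` on simulated
tables and against `aov` for the univariate split-plot F.

Decision rules mirror reporting practice for this design:

* **Box's M** (χ² and F approximations) gates the primary multivariate
  statistic — Pillai's trace when M is significant at 0.05 (robustness
  under covariance heterogeneity), Wilks otherwise; all three statistics
  are always reported.
* **Sphericity.** Mauchly's W per DV on the contrasted pooled
  covariance; Greenhouse–Geisser ε in the 1959 form
  (tr T)²/(k·tr T²) and Huynh–Feldt ε with the group-count term
  ((n−g+1)kε−2)/(k(n−g−kε)), capped at 1 — the same dialect as
  `car`. The univariate F uses unadjusted df when Mauchly is
  non-significant; otherwise HF-adjusted df when GG ε > 0.7, else
  GG-adjusted df.
* **Pairwise comparisons** between the three assessment times use paired
  t-tests with the Sidak adjustment p' = 1 − (1 − p)^m at family size
  m = 3, per DV.
* Subjects are complete-case per analysis; collinear DV sets make the
  multivariate tests unavailable with an explicit rank note rather than
  an error.

## Power analysis

`power_rm_anova()` fixes the within-between interaction convention of
G*Power 3: λ = f²·N·m/(1−ρ), df (g−1)(m−1) and (N−g)(m−1), no
nonsphericity correction; at f = 0 the power equals α exactly, and power
is strictly increasing in f, N and ρ. `solve_f()` inverts the curve to
1e-6. For the reference design (N = 53, two groups, three assessments,
α = 0.05, ρ = 0.5) the minimal detectable interaction effect at 80%
power computes to f = 0.1767, and 2,000-replicate simulation of the
generator at f = 0.17 puts the interaction F-test's rejection rate near
0.75–0.77 — exactly the noncentral-F prediction at that λ, a consistency
the acceptance script re-derives at run time. Note that a planned power
of 0.80 at f = 0.17 under this convention corresponds to a slightly
larger sample (N ≈ 57) than 53; the package reports what the convention
yields rather than forcing agreement.

## Problem sizes and determinism

All simulations in the test and acceptance suites are sized for a
single-CPU desk run: 5-min single-channel records (12 per condition) for
ratio recovery, 100–200 replicates for VEP latency Monte Carlo, and
2,000 replicates for type-I calibration and power. Every random stage
consumes an explicit integer seed; `run_pipeline()` derives all stage
seeds from one root seed and is byte-reproducible for a fixed
(config, seed) pair.

## Known limitations

* Channels are simulated independently; no spatial covariance or
  reference-montage structure.
* The per-epoch ratio bias discussed above is a property of the index
  itself at this time-bandwidth product, not of the implementation;
  between-condition contrasts are unaffected, absolute levels are
  convention-dependent.
* Box's M is well known to be sensitive at large N and to non-normality;
  it is used here only as the reporting gate it is in practice.
* Roy's statistic's F is an upper bound (liberal); it is reported for
  completeness, never used as the primary gate.
* The artifact model (zero-insertion segments) reproduces the
  bookkeeping consequences of artifact removal, not artifact physics.
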