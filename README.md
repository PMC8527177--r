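# svtephys

Electrophysiological indices for sports-vision-training studies: an R
package implementing the EEG and transient-VEP measurement chain used to
monitor training progress in crossover designs, together with the
statistical layer such studies report and seeded synthetic generators
that give every stage a known ground truth.

## What it computes

**EEG → STMLI.** Multichannel 256 Hz EEG is band-pass filtered
(0.5–65 Hz) and notch filtered (50/60/100/120 Hz), artifact samples are
zero-inserted from a mask, and a power spectral density is estimated for
every 1-s epoch from three Kaiser-windowed 1-s overlays at 50% overlap
(an overlay with more than 128 zero-inserted samples is excluded; an
epoch is valid only if at least 2 of 3 overlays remain). Relative PSD in
1-Hz bins (each bin over the 1–40 Hz sum) is averaged into theta
(3–7 Hz), alpha (8–12), low beta (13–19), high beta (20–29) and gamma
(30–40 Hz) bands, and the frontal **Short-Term Memory Load Index** is

    STMLI = rPSD(theta, Fz) / rPSD(gamma, Fz)

per epoch, aggregated per task by a 5% trimmed mean.

**VEP components.** Per-reversal sweeps (512 points at 1,024 Hz for
checkerboards, 1,024 points at 2,048 Hz for gratings; 0.5 s either way)
are averaged per trial; the N75–P100–N135 complex is extracted by
windowed peak picking (P100 = maximum in [80, 140] ms, N75/N135 =
flanking minima), giving sample-grid latencies and the baseline-free
ΔN75–P100 amplitude; three trials per stimulus are ranked, averaged and
log10-transformed.

**Design statistics.** Outlier and normality screening (|z| > 3.29,
Mahalanobis D² at χ²(α = 0.001), skewness/kurtosis z), doubly
multivariate repeated-measures MANOVA (Pillai / Wilks / Roy with F
approximations, partial η², observed power), Box's M as the gate for the
primary statistic, Mauchly's test with Greenhouse–Geisser and
Huynh–Feldt ε and the ε rule for corrected univariate F, Sidak-adjusted
pairwise comparisons, and a-priori power for the within-between
interaction under the noncentral-F convention
λ = f²·N·m/(1−ρ).

**Synthetic data.** `simulate_eeg()` (band-structured 1/f noise with
window-kernel-calibrated relative band powers, artifact segments, task
markers), `simulate_vep_trials()` (parameterized N75-P100-N135 template
plus noise) and `simulate_behavioral_table()` (compound-symmetric
crossover tables with exact Cohen's f cell-mean effects) — all pure
functions of an explicit seed.

## Worked example

```r
library(svtephys)

mk <- data.frame(label = c("fixation", "task"),
                 start_s = c(2, 32), end_s = c(30, 88))
truth <- eeg_ground_truth(
  band_fractions = c(theta = 0.22, alpha = 0.25, low_beta = 0.15,
                     high_beta = 0.12, gamma = 0.09),
  artifact_rate = 2, markers = mk, seed = 14L)
rec <- simulate_eeg(truth, 90)
rec <- decontaminate(eeg_preprocess(rec))
task_stmli(stmli_series(rec), mk)
#>       task n_epochs_valid stmli_trimmed_mean
#> 1 fixation             27           7.634547
#> 2     task             56           5.582358
eeg_truth_stmli(truth)
#> [1] 5.377778
```

The 56-epoch task recovers the generator's population STMLI (5.38)
within a few percent; the 27-epoch fixation block shows the variance to
expect from short tasks with a small gamma fraction (per-epoch ratios
are noisy and right-skewed — see the methods vignette).

```r
vt <- vep_ground_truth(p100 = 104, amplitude = 12, noise_sd = 2, seed = 3L)
trials <- simulate_vep_trials(vt)
comps <- lapply(1:3, function(k)
  detect_components(average_sweeps(trials$trials[[k]]), 1024, trial = k))
s <- summarize_stimulus(comps)
sprintf("mean P100: %.2f ms (log10 %.4f), mean dN75-P100: %.2f uV",
        s$mean_latency_ms, s$log10_latency, s$mean_amplitude_uv)
#> "mean P100: 103.19 ms (log10 2.0136), mean dN75-P100: 12.51 uV"

solve_f(n = 53, g = 2, m = 3, alpha = 0.05, rho = 0.5, power = 0.80)
#> [1] 0.1766509   # minimal detectable interaction effect at 80% power
```

An end-to-end synthetic study (EEG → STMLI table, VEP summaries,
behavioral table, screening, RM-MANOVA, power planning) runs with

```r
res <- run_pipeline(seed = 1L, out_dir = "study_out")
```

writing `stmli.csv`, `vep_summary.csv`, `behavioral.csv`,
`screening.csv`, `manova.csv`, `session_plan.csv`, `power.txt` and a
text summary; the run is byte-reproducible for a fixed (config, seed).
A thin command-line wrapper with `simulate` / `power` / `run-all`
subcommands lives at `inst/cli/svtephys.R`.

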