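# Shared fixtures and independent oracles, built in code at test time.

# explicit-sum DFT periodogram of one windowed overlay: independent of the
# package's fft-based path
dft_overlay_psd <- function(seg, beta = 14, fs = 256) {
  n <- length(seg)
  w <- signal::kaiser(n, beta)
  xw <- seg * w
  t <- seq_len(n) - 1
  vapply(1:40, function(k) {
    re <- sum(xw * cos(2 * pi * k * t / n))
    im <- -sum(xw * sin(2 * pi * k * t / n))
    2 * (re^2 + im^2) / (fs * sum(w^2))
  }, numeric(1))
}

# single-channel Fz record holding a pure sinusoid
tone_record <- function(freq, duration_s = 4, fs = 256, amp = 1) {
  t <- seq_len(duration_s * fs) / fs
  decontaminate(eeg_record(matrix(amp * sin(2 * pi * freq * t), ncol = 1),
                           fs = fs, channels = "Fz"))
}

# 2-s single-epoch record with a prescribed zero-insertion count per
# overlay. Overlays share samples, so counts are realised through the
# exclusive regions: o1 = a + b, o2 = b + c, o3 = c + d with a in 1..128,
# b in 129..256, c in 257..384, d in 385..512.
record_with_zero_counts <- function(o1, o2, o3, fs = 256) {
  c <- min(o3, o2)
  b <- o2 - c
  a <- o1 - b
  d <- o3 - c
  stopifnot(a >= 0, a <= 128, c >= 0, c <= 128, d >= 0, d <= 128)
  mask <- rep(FALSE, 2 * fs)
  if (a > 0) mask[1:a] <- TRUE
  if (b > 0) mask[129:(128 + b)] <- TRUE
  if (c > 0) mask[257:(256 + c)] <- TRUE
  if (d > 0) mask[385:(384 + d)] <- TRUE
  rec <- eeg_record(matrix(stats::rnorm(2 * fs), ncol = 1), fs = fs,
                    channels = "Fz", artifact_mask = mask)
  decontaminate(rec)
}

# epoch_spectrum literal for unit tests of downstream stages
fake_epoch <- function(psd) {
  psd <- stats::setNames(psd, as.character(1:40))
  structure(list(psd = psd, log10_psd = suppressWarnings(log10(psd)),
                 overlays_used = 3L, zero_counts = c(0L, 0L, 0L),
                 valid = TRUE, start_s = 0, channel = "Fz"),
            class = "epoch_spectrum")
}

# band-fraction set with the theta/gamma per-bin ratio r, gamma fixed
ratio_band_fractions <- function(r, gamma = 0.20) {
  theta <- r * (5 / 11) * gamma
  c(theta = theta, alpha = 0.30,
    low_beta = 0.95 - theta - 0.30 - 0.15 - gamma,
    high_beta = 0.15, gamma = gamma)
}
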