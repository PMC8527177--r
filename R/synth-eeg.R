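#' Ground-truth specification for synthetic EEG
#'
#' Describes a multichannel EEG record with controllable relative band
#' powers, a 1/f^chi pink-noise floor, artifact segments and task markers.
#' Band targets are the fractions of total 1--40 Hz power the theta
#' (3--7 Hz), alpha (8--12 Hz), low-beta (13--19 Hz), high-beta
#' (20--29 Hz) and gamma (30--40 Hz) bands should carry at every channel;
#' the remainder (if any) is left on the pink floor of the 1--2 Hz bins.
#'
#' @param channels Character vector of channel labels; must include "Fz".
#' @param fs Sampling rate in Hz.
#' @param band_fractions Named numeric vector with entries `theta`, `alpha`,
#'   `low_beta`, `high_beta`, `gamma`; each in (0, 1), sum at most 1.
#' @param pink_exponent Exponent chi of the 1/f^chi floor.
#' @param artifact_rate Expected artifact segments per minute (0 disables).
#' @param artifact_duration Artifact segment length in samples.
#' @param markers Data frame with columns `label`, `start_s`, `end_s`
#'   giving the task schedule, or NULL.
#' @param seed Integer seed; the generator is a pure function of
#'   (specification, duration).
#'
#' @return An object of class `eeg_ground_truth`.
#' @export
eeg_ground_truth <- function(channels = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                                          "P3", "POz", "P4"),
                             fs = 256,
                             band_fractions = c(theta = 0.20, alpha = 0.25,
                                                low_beta = 0.15,
                                                high_beta = 0.12,
                                                gamma = 0.10),
                             pink_exponent = 1,
                             artifact_rate = 0,
                             artifact_duration = 256,
                             markers = NULL,
                             seed = 1L) {
  stopifnot(is.character(channels), "Fz" %in% channels, fs > 0)
  need <- c("theta", "alpha", "low_beta", "high_beta", "gamma")
  if (!all(need %in% names(band_fractions)))
    stop("band_fractions must name all of: ", paste(need, collapse = ", "))
  bf <- band_fractions[need]
  if (any(bf <= 0) || any(bf >= 1))
    stop("each band fraction must lie strictly in (0, 1)")
  if (sum(bf) > 1 + 1e-12)
    stop("band fractions sum to ", signif(sum(bf), 4), " > 1")
  if (artifact_rate < 0) stop("artifact_rate must be >= 0")
  if (!is.null(markers)) .check_markers(markers)
  structure(list(channels = channels, fs = fs, band_fractions = bf,
                 pink_exponent = pink_exponent,
                 artifact_rate = artifact_rate,
                 artifact_duration = as.integer(artifact_duration),
                 markers = markers, seed = as.integer(seed)),
            class = "eeg_ground_truth")
}

.check_markers <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("label", "start_s", "end_s") %in% names(markers)))
  if (any(markers$end_s <= markers$start_s))
    stop("marker end_s must exceed start_s")
  o <- order(markers$start_s)
  s <- markers$start_s[o]; e <- markers$end_s[o]
  if (nrow(markers) > 1 && any(s[-1] < e[-nrow(markers)]))
    stop("marker intervals overlap")
  invisible(markers)
}

#' Theta/gamma STMLI implied by a ground-truth specification
#'
#' The STMLI is the ratio of the per-bin band averages, so the implied
#' value is (theta fraction / 5) / (gamma fraction / 11).
#'
#' @param truth An `eeg_ground_truth`.
#' @return The population STMLI at every channel.
#' @export
eeg_truth_stmli <- function(truth) {
  bf <- truth$band_fractions
  (bf[["theta"]] / 5) / (bf[["gamma"]] / 11)
}

#' Generate a synthetic multichannel EEG record
#'
#' Each channel is independently synthesised by spectral shaping of white
#' Gaussian noise: narrow-band Hann-shaped bumps for the five analysis
#' bands over a 1/f^chi pink floor restricted to the 0.5--65 Hz
#' acquisition passband. Per-band power scalings are calibrated against
#' the spectral kernel of the 1-s Kaiser analysis window so that the
#' *measured* relative band powers (as computed by [epoch_psd()] and
#' [band_average()]) match the targets in expectation.
#' Artifact segments are drawn as contiguous intervals (their union forms
#' the per-sample artifact mask); the emitted samples themselves are clean
#' signal, the mask marks what the decontamination step will zero out.
#'
#' @param truth An [eeg_ground_truth()] specification.
#' @param duration_s Record duration in seconds; at least 2 s (one epoch).
#' @return An object of class `eeg_record`: list with `data` (samples x
#'   channels matrix, microvolts), `fs`, `channels`, `artifact_mask`
#'   (logical per sample), `markers`, and the originating `truth`.
#' @export
simulate_eeg <- function(truth, duration_s) {
  stopifnot(inherits(truth, "eeg_ground_truth"))
  if (duration_s < 2)
    stop("duration_s must be >= 2 s (one PSD epoch spans 2 s)")
  fs <- truth$fs
  n <- as.integer(round(duration_s * fs))
  if (!is.null(truth$markers) && any(truth$markers$end_s > duration_s))
    stop("marker schedule extends beyond the record duration")

  gain <- .spectral_gain(n, fs, truth$band_fractions, truth$pink_exponent)
  set.seed(truth$seed)
  dat <- matrix(0, n, length(truth$channels),
                dimnames = list(NULL, truth$channels))
  for (j in seq_along(truth$channels)) {
    w <- stats::rnorm(n)
    X <- stats::fft(w) * gain
    dat[, j] <- Re(stats::fft(X, inverse = TRUE)) / n
  }

  mask <- rep(FALSE, n)
  if (truth$artifact_rate > 0) {
    n_seg <- stats::rpois(1, truth$artifact_rate * duration_s / 60)
    if (n_seg > 0) {
      starts <- sort(sample.int(max(1L, n - truth$artifact_duration), n_seg,
                                replace = TRUE))
      for (s in starts)
        mask[s:min(n, s + truth$artifact_duration - 1L)] <- TRUE
    }
  }
  structure(list(data = dat, fs = fs, channels = truth$channels,
                 artifact_mask = mask, markers = truth$markers,
                 truth = truth),
            class = "eeg_record")
}

#' Construct an EEG record from raw data
#'
#' Wraps an existing samples-by-channels matrix (e.g. a test tone or data
#' read from disk) in the container the spectral chain consumes.
#'
#' @param data Numeric matrix, samples x channels, or a vector (one channel).
#' @param fs Sampling rate (Hz).
#' @param channels Channel labels; default taken from column names.
#' @param artifact_mask Logical per-sample mask (default all clean).
#' @param markers Optional task marker data frame (`label`, `start_s`, `end_s`).
#' @return An `eeg_record`.
#' @export
eeg_record <- function(data, fs = 256, channels = NULL,
                       artifact_mask = NULL, markers = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  if (is.null(channels))
    channels <- colnames(data) %||% paste0("ch", seq_len(ncol(data)))
  colnames(data) <- channels
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, nrow(data))
  stopifnot(length(artifact_mask) == nrow(data))
  if (!is.null(markers)) .check_markers(markers)
  structure(list(data = data, fs = fs, channels = channels,
                 artifact_mask = artifact_mask, markers = markers,
                 truth = NULL),
            class = "eeg_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eeg_record <- function(x, ...) {
  cat("<eeg_record> ", nrow(x$data), " samples x ", ncol(x$data),
      " channels @ ", x$fs, " Hz (",
      round(nrow(x$data) / x$fs, 2), " s); ",
      sum(x$artifact_mask), " artifact-masked samples\n", sep = "")
  invisible(x)
}

# Amplitude gain over the full FFT grid of an n-sample record.
#
# Each band is synthesised as a Hann-shaped narrow-band bump spanning its
# analysis range (power tapering to zero at the band edges); the non-band
# remainder (1-2 Hz bins plus the 40.5-65 Hz tail of the acquisition
# passband) keeps a 1/f^chi pink floor. Because the downstream PSD uses a
# 1-s Kaiser(beta = 14) window whose mainlobe smears neighbouring 1-Hz
# bins, the per-region power scalings are calibrated against that window's
# spectral kernel: the expected measured band fractions (band sums of the
# kernel-convolved spectrum over bins 1-40) are solved to equal the
# targets. Scalings are clamped at zero if a target is so extreme that
# neighbour leakage alone exceeds it.
.spectral_gain <- function(n, fs, band_fractions, chi,
                           analysis_beta = 14) {
  nseg <- fs                                # 1-s analysis overlay
  freq <- pmin((seq_len(n) - 1) * fs / n,
               fs - (seq_len(n) - 1) * fs / n)     # folded two-sided grid
  pink2 <- ifelse(freq >= 0.5 & freq <= 65, pmax(freq, 0.5)^(-chi), 0)

  bands <- eeg_bands()
  shapes <- lapply(bands, function(bins) {
    lo <- min(bins) - 0.5; hi <- max(bins) + 0.5
    s <- numeric(n); i <- freq >= lo & freq < hi
    s[i] <- 0.5 * (1 - cos(2 * pi * (freq[i] - lo) / (hi - lo)))
    s
  })
  shapes$rest <- pink2 * (freq < 2.5) + pink2 * (freq >= 40.5)
  shapes <- lapply(shapes, function(s) s / sum(s))

  # expected-measurement matrix: group sums of the kernel-convolved unit
  # spectra over analysis bins 1-40
  w <- signal::kaiser(nseg, analysis_beta)
  FW <- stats::fft(Mod(stats::fft(c(w, rep(0, n - nseg))))^2)
  kidx <- round((1:40) * n / fs) + 1L
  binreg <- c(rep("rest", 2), rep(names(bands),
                                  times = lengths(bands)))
  groups <- c(names(bands), "rest")
  M <- vapply(shapes[groups], function(p) {
    ek <- Re(stats::fft(stats::fft(p) * FW, inverse = TRUE))[kidx] / n
    tapply(ek, binreg, sum)[groups]
  }, numeric(6))
  tgt <- c(band_fractions, rest = max(0, 1 - sum(band_fractions)))[groups]
  x <- pmax(solve(M, tgt), 0)
  g2 <- numeric(n)
  for (s in groups) g2 <- g2 + shapes[[s]] * x[[s]]
  sqrt(g2)
}
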