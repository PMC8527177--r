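#' Acquisition filter specification
#'
#' Band-pass plus mains-harmonic notches, matching a 256 Hz ambulatory
#' EEG front end: 0.5--65 Hz pass band (3 dB edges) and notches at 50,
#' 60, 100 and 120 Hz.
#'
#' @param low,high Band-pass edges in Hz.
#' @param notches Notch centre frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param notch_q Quality factor of each IIR notch.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.5, high = 65,
                        notches = c(50, 60, 100, 120),
                        fs = 256, notch_q = 30) {
  nyq <- fs / 2
  if (low <= 0 || high <= low || high >= nyq)
    stop("need 0 < low < high < Nyquist (", nyq, " Hz)")
  if (any(notches >= nyq)) stop("notch frequencies must be below Nyquist")
  structure(list(low = low, high = high, notches = notches, fs = fs,
                 notch_q = notch_q),
            class = "filter_spec")
}

#' Zero-phase band-pass and notch filtering
#'
#' Per channel: the mean is removed, then a Butterworth band-pass
#' (cascaded 2nd-order high-pass at the low edge and 4th-order low-pass at
#' the high edge; low-order high-pass keeps the recursion numerically
#' stable at 0.5 Hz / 256 Hz) and second-order IIR notches are applied,
#' each forward-backward (`signal::filtfilt`) so the output is zero-phase.
#' Output length equals input length.
#'
#' @param record An [eeg_record()].
#' @param spec A [filter_spec()]; its sampling rate must match the record.
#' @return The filtered `eeg_record`.
#' @export
eeg_preprocess <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "eeg_record"), inherits(spec, "filter_spec"))
  if (record$fs != spec$fs)
    stop("record sampled at ", record$fs, " Hz but filter spec expects ",
         spec$fs, " Hz")
  if (anyNA(record$data)) stop("record contains NA samples")
  nyq <- spec$fs / 2
  hp <- signal::butter(2, spec$low / nyq, type = "high")
  lp <- signal::butter(4, spec$high / nyq, type = "low")
  filters <- c(list(hp, lp), lapply(spec$notches, .notch_biquad,
                                    fs = spec$fs, q = spec$notch_q))
  out <- record$data
  for (j in seq_len(ncol(out))) {
    x <- out[, j] - mean(out[, j])
    for (f in filters) x <- signal::filtfilt(f, x)
    out[, j] <- x
  }
  record$data <- out
  record
}

# RBJ-cookbook second-order notch at f0 with quality factor q
.notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::Arma(b = b, a = a)
}

#' Mask-driven decontamination (zero insertion)
#'
#' Replaces artifact-masked samples by zeros across all channels and
#' records per-sample zero-insertion flags, mirroring the output an
#' artifact-removal stage hands to the PSD computation.
#'
#' @param record An `eeg_record`.
#' @param mask Logical per-sample mask; defaults to the record's own
#'   `artifact_mask`.
#' @return The record with masked samples zeroed and a `zero_flags` field.
#' @export
decontaminate <- function(record, mask = record$artifact_mask) {
  stopifnot(inherits(record, "eeg_record"))
  if (length(mask) != nrow(record$data))
    stop("mask length ", length(mask), " does not match record length ",
         nrow(record$data))
  record$data[mask, ] <- 0
  record$zero_flags <- as.logical(mask)
  record
}

#' Per-epoch power spectral density at one channel
#'
#' One epoch spans the 2-s window `[start_s, start_s + 2)` and is estimated
#' from three 1-s overlays (256 samples at 256 Hz) at 50% overlap, i.e. at
#' sample offsets 0, 128 and 256. Each overlay is Kaiser-windowed, FFT'd
#' and converted to a one-sided PSD with window-power correction; the 1-Hz
#' analysis bins 1--40 Hz fall on the exact FFT grid of a 1-s segment. An
#' overlay containing more than 128 zero-inserted samples is excluded; the
#' epoch is valid only when at least 2 overlays remain, and its PSD is the
#' mean over retained overlays. log10 PSD is computed from the averaged
#' linear PSD.
#'
#' @param record A cleaned `eeg_record` (see [decontaminate()]).
#' @param start_s Epoch start time in seconds.
#' @param channel Channel label (default "Fz").
#' @param kaiser_beta Kaiser window shape parameter.
#' @return An object of class `epoch_spectrum` with fields `psd` and
#'   `log10_psd` (named bins 1--40, microvolt^2/Hz), `overlays_used`,
#'   `zero_counts`, `valid`, `start_s`, `channel`.
#' @export
epoch_psd <- function(record, start_s, channel = "Fz", kaiser_beta = 14) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (!channel %in% record$channels) stop("unknown channel: ", channel)
  i0 <- as.integer(round(start_s * fs))
  if (i0 < 0 || i0 + 2 * fs > nrow(record$data))
    stop("epoch [", start_s, ", ", start_s + 2, ") s exceeds the record")
  x <- record$data[(i0 + 1):(i0 + 2 * fs), channel]
  zf <- record$zero_flags %||% rep(FALSE, nrow(record$data))
  z <- zf[(i0 + 1):(i0 + 2 * fs)]

  nseg <- fs                       # 1-s overlays
  offsets <- c(0L, nseg %/% 2L, nseg)
  w <- signal::kaiser(nseg, kaiser_beta)
  zero_counts <- vapply(1:3, function(k)
    sum(z[(offsets[k] + 1):(offsets[k] + nseg)]), integer(1))
  rule <- overlay_validity(zero_counts, overlay_len = nseg)
  psd_list <- lapply(which(!rule$excluded), function(k)
    .overlay_psd(x[(offsets[k] + 1):(offsets[k] + nseg)], w, fs))
  used <- rule$overlays_used
  valid <- rule$valid
  psd <- if (used > 0) Reduce(`+`, psd_list) / used else rep(NA_real_, 40)
  names(psd) <- as.character(1:40)
  log10_psd <- ifelse(!is.na(psd) & psd > 0, log10(psd), NA_real_)
  structure(list(psd = psd, log10_psd = log10_psd,
                 overlays_used = used, zero_counts = zero_counts,
                 valid = valid, start_s = start_s, channel = channel),
            class = "epoch_spectrum")
}

#' Overlay exclusion and epoch validity rule
#'
#' An overlay is excluded when more than half of its samples (more than
#' 128 of 256) are zero-inserted; the epoch is valid only when at least 2
#' of its 3 overlays remain. Exposed separately so the decision rule can
#' be exercised on arbitrary zero-count patterns.
#'
#' @param zero_counts Integer vector of zero-inserted sample counts, one
#'   per overlay.
#' @param overlay_len Samples per overlay.
#' @return List with `excluded` (logical per overlay), `overlays_used`,
#'   `valid`.
#' @export
overlay_validity <- function(zero_counts, overlay_len = 256L) {
  excluded <- zero_counts > overlay_len %/% 2L
  used <- sum(!excluded)
  list(excluded = excluded, overlays_used = used, valid = used >= 2L)
}

# one-sided periodogram of one windowed overlay, bins 1..40 Hz
.overlay_psd <- function(seg, w, fs) {
  X <- stats::fft(seg * w)
  p <- 2 * Mod(X)^2 / (fs * sum(w^2))     # one-sided, window-power corrected
  p[1:40 + 1L]                            # df = fs/n = 1 Hz; bin b at index b+1
}

#' Epoch spectra over a whole record
#'
#' Runs [epoch_psd()] at every 1-s step t = 0, 1, ..., floor(T) - 2.
#'
#' @inheritParams epoch_psd
#' @return List of `epoch_spectrum` objects.
#' @export
epoch_spectra <- function(record, channel = "Fz", kaiser_beta = 14) {
  t_max <- floor(nrow(record$data) / record$fs) - 2
  if (t_max < 0) stop("record shorter than one 2-s epoch window")
  lapply(0:t_max, function(t)
    epoch_psd(record, t, channel = channel, kaiser_beta = kaiser_beta))
}

#' Relative PSD of a valid epoch
#'
#' Each 1-Hz bin divided by the sum of bins 1--40, so the result sums to 1.
#' Computed on the linear-scale PSD (the log10 PSD is reporting-only).
#'
#' @param e An `epoch_spectrum`.
#' @return An object of class `relative_spectrum` (named bins 1--40).
#' @export
relative_psd <- function(e) {
  stopifnot(inherits(e, "epoch_spectrum"))
  if (!e$valid) stop("cannot compute relative PSD of an invalid epoch")
  s <- sum(e$psd)
  if (!is.finite(s) || s <= 0) stop("epoch PSD sums to zero")
  structure(list(rel = e$psd / s, start_s = e$start_s, channel = e$channel),
            class = "relative_spectrum")
}

#' Band-averaged relative power
#'
#' Arithmetic mean of the relative 1-Hz bins inside each band (see
#' [eeg_bands()]): theta over 5 bins, alpha 5, low beta 7, high beta 10,
#' gamma 11.
#'
#' @param r A `relative_spectrum`.
#' @return Object of class `band_powers`: named numeric (theta, alpha,
#'   low_beta, high_beta, gamma) with a `channel` attribute.
#' @export
band_average <- function(r) {
  stopifnot(inherits(r, "relative_spectrum"))
  b <- vapply(eeg_bands(), function(bins) mean(r$rel[bins]), numeric(1))
  structure(b, channel = r$channel, class = "band_powers")
}
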