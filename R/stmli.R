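#' Short-Term Memory Load Index for one epoch
#'
#' STMLI = relative theta power / relative gamma power at Fz, per 1-s
#' epoch. Undefined (NA, with a warning) when gamma power is zero; such
#' epochs are dropped from task aggregation.
#'
#' @param b A [band_average()] result computed at Fz.
#' @return A positive ratio, or NA when undefined.
#' @export
compute_stmli <- function(b) {
  stopifnot(inherits(b, "band_powers"))
  if (!identical(attr(b, "channel"), "Fz"))
    stop("STMLI is defined at Fz; got channel ", attr(b, "channel"))
  if (b[["gamma"]] <= 0) {
    warning("gamma relative power is zero; STMLI undefined for this epoch")
    return(NA_real_)
  }
  b[["theta"]] / b[["gamma"]]
}

#' Per-epoch STMLI series for a cleaned record
#'
#' Runs the full per-epoch chain (PSD, relative PSD, band averages, ratio)
#' at Fz for every 1-s epoch start. Invalid epochs yield NA with
#' `valid = FALSE`.
#'
#' @param record A cleaned `eeg_record`.
#' @param kaiser_beta Kaiser window shape parameter for the PSD stage.
#' @return Data frame with columns `epoch_start`, `valid`, `stmli`.
#' @export
stmli_series <- function(record, kaiser_beta = 14) {
  sp <- epoch_spectra(record, channel = "Fz", kaiser_beta = kaiser_beta)
  out <- data.frame(epoch_start = vapply(sp, `[[`, 0, "start_s"),
                    valid = vapply(sp, `[[`, NA, "valid"),
                    stmli = NA_real_)
  for (i in seq_along(sp)) {
    if (!sp[[i]]$valid) next
    out$stmli[i] <- suppressWarnings(
      compute_stmli(band_average(relative_psd(sp[[i]]))))
  }
  out$valid <- out$valid & !is.na(out$stmli)
  out
}

#' Assign epochs to tasks
#'
#' An epoch belongs to a task iff its nominal 1-s span `[t, t + 1)` lies
#' fully inside the task's `[start_s, end_s)`. Invalid epochs are excluded.
#' Abutting tasks therefore partition the epoch grid: no epoch lands in two.
#'
#' @param series Data frame from [stmli_series()] (columns `epoch_start`,
#'   `valid`, `stmli`).
#' @param markers Data frame with `label`, `start_s`, `end_s`.
#' @return `series` restricted to in-task valid epochs, with a `task` column.
#' @export
segment_tasks <- function(series, markers) {
  .check_markers(markers)
  out <- series[series$valid, , drop = FALSE]
  out$task <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(markers))) {
    inside <- out$epoch_start >= markers$start_s[i] &
      out$epoch_start + 1 <= markers$end_s[i]
    out$task[inside] <- markers$label[i]
  }
  out[!is.na(out$task), , drop = FALSE]
}

#' Symmetric trimmed mean with floor counts
#'
#' Drops `floor(trim * n)` smallest and the same number of largest values,
#' then averages the remainder; with fewer than `1/trim` values this is the
#' ordinary mean. The default 5% trim is the aggregation used for per-task
#' STMLI series to discard 1-s epochs with extreme values.
#'
#' @param x Numeric vector, length >= 1.
#' @param trim Fraction trimmed from each tail.
#' @return The trimmed mean.
#' @export
stmli_trimmed_mean <- function(x, trim = 0.05) {
  if (length(x) == 0) stop("empty series")
  k <- floor(trim * length(x))
  s <- sort(x)
  mean(s[(k + 1):(length(x) - k)])
}

#' Per-task STMLI aggregation
#'
#' 5% trimmed mean of the valid epoch STMLI ratios inside each task marker.
#' Tasks with no valid epoch are reported with `n_epochs_valid = 0` and an
#' NA mean.
#'
#' @param series Data frame from [stmli_series()].
#' @param markers Task marker data frame (`label`, `start_s`, `end_s`).
#' @param trim Trim fraction per tail.
#' @return Data frame: `task`, `n_epochs_valid`, `stmli_trimmed_mean`.
#' @export
task_stmli <- function(series, markers, trim = 0.05) {
  seg <- segment_tasks(series, markers)
  out <- data.frame(task = markers$label,
                    n_epochs_valid = 0L,
                    stmli_trimmed_mean = NA_real_)
  for (i in seq_len(nrow(out))) {
    v <- seg$stmli[seg$task == out$task[i]]
    out$n_epochs_valid[i] <- length(v)
    if (length(v) > 0)
      out$stmli_trimmed_mean[i] <- stmli_trimmed_mean(v, trim)
  }
  out
}
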