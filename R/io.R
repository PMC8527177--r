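# Delimited on-disk interchange: EEG data as TSV (one column per channel),
# artifact mask and task markers as CSV sidecars; VEP sweeps as delimited
# matrices (rows = sweeps); measurement tables as CSV.

#' Write / read an EEG record as delimited text
#'
#' `<prefix>_eeg.tsv` holds the samples-by-channels matrix,
#' `<prefix>_mask.csv` the artifact segments (`label,start_s,end_s`) and
#' `<prefix>_markers.csv` the task markers.
#'
#' @param record An `eeg_record`.
#' @param prefix Path prefix for the three files.
#' @return `write_eeg_record` the prefix, invisibly; `read_eeg_record`
#'   the reconstructed record.
#' @export
write_eeg_record <- function(record, prefix) {
  utils::write.table(data.frame(record$data, check.names = FALSE),
                     paste0(prefix, "_eeg.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(fs = record$fs), paste0(prefix, "_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(.mask_to_segments(record$artifact_mask, record$fs),
                   paste0(prefix, "_mask.csv"), row.names = FALSE)
  mk <- record$markers %||%
    data.frame(label = character(0), start_s = numeric(0),
               end_s = numeric(0))
  utils::write.csv(mk, paste0(prefix, "_markers.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_eeg_record
#' @export
read_eeg_record <- function(prefix) {
  dat <- as.matrix(utils::read.delim(paste0(prefix, "_eeg.tsv"),
                                     check.names = FALSE))
  fs <- utils::read.csv(paste0(prefix, "_meta.csv"))$fs[1]
  seg <- utils::read.csv(paste0(prefix, "_mask.csv"))
  mask <- .segments_to_mask(seg, nrow(dat), fs)
  mk <- utils::read.csv(paste0(prefix, "_markers.csv"),
                        colClasses = c("character", "numeric", "numeric"))
  if (nrow(mk) == 0) mk <- NULL
  eeg_record(dat, fs = fs, artifact_mask = mask, markers = mk)
}

.mask_to_segments <- function(mask, fs) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(label = rep("artifact", sum(keep)),
             start_s = (starts[keep] - 1) / fs,
             end_s = ends[keep] / fs)
}

.segments_to_mask <- function(seg, n, fs) {
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(seg))) {
    a <- round(seg$start_s[i] * fs) + 1
    b <- round(seg$end_s[i] * fs)
    mask[a:min(b, n)] <- TRUE
  }
  mask
}

#' Write VEP trials as delimited sweep matrices
#'
#' One `<prefix>_trial<k>.tsv` per trial, rows = sweeps.
#'
#' @param trials A `vep_trials` object.
#' @param prefix Path prefix.
#' @export
write_vep_trials <- function(trials, prefix) {
  for (k in seq_along(trials$trials))
    utils::write.table(trials$trials[[k]],
                       sprintf("%s_trial%d.tsv", prefix, k),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read one delimited sweep matrix
#' @param path TSV file, rows = sweeps.
#' @return Numeric matrix.
#' @export
read_sweeps <- function(path) {
  as.matrix(utils::read.delim(path, header = FALSE))
}

#' Write / read a long measurement table as CSV
#' @param table A `measurement_table`.
#' @param path CSV path.
#' @export
write_measurement_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_table
#' @export
read_measurement_table <- function(path) {
  out <- utils::read.csv(path, colClasses = c(
    subject_id = "character", group = "character", time = "character",
    dv_name = "character", value = "numeric"))
  class(out) <- c("measurement_table", "data.frame")
  out
}
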