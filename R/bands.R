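#' Frequency band definitions
#'
#' The five analysis bands used throughout the package, expressed as the
#' 1-Hz PSD bins (1--40 Hz) they average over: theta 3--7 Hz, alpha
#' 8--12 Hz, low beta 13--19 Hz, high beta 20--29 Hz, gamma 30--40 Hz.
#' Bins 1--2 Hz enter the relative-PSD denominator but belong to no band.
#'
#' @return Named list of integer bin vectors.
#' @export
eeg_bands <- function() {
  list(
    theta     = 3:7,
    alpha     = 8:12,
    low_beta  = 13:19,
    high_beta = 20:29,
    gamma     = 30:40
  )
}

# frequency span covered by analysis bin b: [b - 0.5, b + 0.5)
.bin_edges <- function(b) c(b - 0.5, b + 0.5)
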