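#' Screening report for a measurement table
#'
#' Per-DV univariate screening and joint multivariate screening, following
#' the conventions of the design layer: standardized z scores with outlier
#' flags at |z| > 3.29 (alpha = 0.001), Mahalanobis D^2 per subject over
#' the subject's full DV x time vector against the chi-square cutoff at
#' alpha = 0.001 (df = number of columns), skewness/kurtosis z statistics,
#' Shapiro-Wilk and Lilliefors (Kolmogorov-Smirnov) normality tests, and a
#' log10-transform recommendation when |z_skew| or |z_kurt| exceeds 3.29
#' (substantial non-normality).
#'
#' @param table A long `measurement_table` (see
#'   [simulate_behavioral_table()] for the format).
#' @param z_cut Outlier cutoff on |z| (also used for the transform rule).
#' @param maha_alpha Alpha for the Mahalanobis chi-square cutoff.
#' @return Object of class `screening_report` with elements `values`
#'   (per-observation z and flag), `dv` (per-DV normality statistics and
#'   `recommend_log10`), `mahalanobis` (per-subject D^2, cutoff, flag,
#'   `pseudo_inverse` flag).
#' @export
screen_table <- function(table, z_cut = 3.29, maha_alpha = 0.001) {
  stopifnot(all(c("subject_id", "dv_name", "value") %in% names(table)))
  vals <- table
  vals$z <- stats::ave(vals$value, vals$dv_name,
                       FUN = function(v) as.numeric(scale(v)))
  vals$outlier <- abs(vals$z) > z_cut

  dv_stats <- do.call(rbind, lapply(split(vals$value, vals$dv_name),
                                    .normality_row))
  dv <- data.frame(dv_name = rownames(dv_stats), dv_stats,
                   row.names = NULL)
  dv$recommend_log10 <- abs(dv$z_skew) > z_cut | abs(dv$z_kurt) > z_cut

  # subjects x (dv x time) matrix for joint screening
  key <- paste(table$dv_name, table$time, sep = ".")
  mat <- tapply(table$value, list(table$subject_id, key), mean)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  S <- stats::cov(mat)
  pseudo <- FALSE
  d2 <- tryCatch(stats::mahalanobis(mat, colMeans(mat), S),
                 error = function(e) NULL)
  if (is.null(d2)) {
    pseudo <- TRUE
    Sinv <- .pseudo_inverse(S)
    ctr <- sweep(mat, 2, colMeans(mat))
    d2 <- rowSums((ctr %*% Sinv) * ctr)
  }
  cutoff <- stats::qchisq(1 - maha_alpha, df = ncol(mat))
  maha <- data.frame(subject_id = rownames(mat), d2 = unname(d2),
                     cutoff = cutoff, outlier = unname(d2) > cutoff)

  structure(list(values = vals, dv = dv, mahalanobis = maha,
                 pseudo_inverse = pseudo, z_cut = z_cut),
            class = "screening_report")
}

.normality_row <- function(v) {
  n <- length(v)
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  sw <- if (n >= 3 && n <= 5000) stats::shapiro.test(v)$p.value else NA_real_
  ks <- if (n >= 5) nortest::lillie.test(v)$p.value else NA_real_
  data.frame(n = n,
             skew = e1071::skewness(v, type = 2),
             z_skew = e1071::skewness(v, type = 2) / se_skew,
             kurt = e1071::kurtosis(v, type = 2),
             z_kurt = e1071::kurtosis(v, type = 2) / se_kurt,
             shapiro_p = sw, lilliefors_p = ks)
}

.pseudo_inverse <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

#' Elementwise log10 transform
#'
#' @param x Positive values.
#' @return log10(x).
#' @seealso [inv_log10_transform()] for reporting raw-scale means.
#' @export
log10_transform <- function(x) {
  if (any(x <= 0, na.rm = TRUE))
    stop("log10 transform requires strictly positive values")
  log10(x)
}

#' @rdname log10_transform
#' @export
inv_log10_transform <- function(x) 10^x
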