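#' Doubly multivariate repeated-measures MANOVA
#'
#' The statistical core of the crossover design: several dependent
#' variables each measured at three assessments, with treatment order as
#' the between-subject factor. Multivariate tests (Pillai's trace, Wilks'
#' lambda, Roy's greatest root with their F approximations, partial
#' eta^2 and observed power) are computed for the time effect, the group
#' effect and the group x time interaction from the hypothesis and error
#' SSCP matrices of the within-subject-contrasted data. Box's M gates the
#' choice of primary statistic (Pillai when M is significant at 0.05,
#' mirroring robustness practice under covariance heterogeneity); per-DV
#' univariate follow-ups carry Mauchly's sphericity test, Greenhouse-
#' Geisser and Huynh-Feldt epsilons, and the epsilon rule for the
#' corrected F: unadjusted df when Mauchly is non-significant, otherwise
#' Huynh-Feldt when GG epsilon > 0.7 and Greenhouse-Geisser below that.
#' Sidak-adjusted pairwise comparisons between assessment times are
#' attached per DV. Subjects are complete-case per analysis.
#'
#' @param table Long `measurement_table` (may hold several `dv_name`s).
#' @param dvs DVs to include (default: all present).
#' @param alpha Level for the Box's M gate, Mauchly decision and pairwise
#'   comparisons.
#' @return Object of class `rm_manova` with elements `multivariate` (per
#'   effect), `box_m`, `primary_statistic`, `univariate` (per DV),
#'   `pairwise` (per DV), `n`, `dvs`, notes on unavailable tests.
#' @export
rm_manova <- function(table, dvs = NULL, alpha = 0.05) {
  if (is.null(dvs)) dvs <- unique(table$dv_name)
  wides <- lapply(dvs, function(d) measurement_wide(table, d))
  ids <- Reduce(intersect, lapply(wides, `[[`, "subject_id"))
  wides <- lapply(wides, function(w) {
    k <- w$subject_id %in% ids
    w$y <- w$y[k, , drop = FALSE]; w$group <- w$group[k]
    w$subject_id <- w$subject_id[k]; w
  })
  ord <- lapply(wides, function(w) order(w$subject_id))
  for (i in seq_along(wides)) {
    w <- wides[[i]]
    wides[[i]]$y <- w$y[ord[[i]], , drop = FALSE]
    wides[[i]]$group <- w$group[ord[[i]]]
    wides[[i]]$subject_id <- w$subject_id[ord[[i]]]
  }
  group <- wides[[1]]$group
  m <- ncol(wides[[1]]$y)
  d <- length(dvs)
  n <- length(group)
  Y <- do.call(cbind, lapply(wides, `[[`, "y"))   # time fastest within DV
  g <- nlevels(group)
  X <- stats::model.matrix(~group,
    contrasts.arg = list(group = "contr.sum"))  # Type III hypotheses
  v <- n - g

  C <- .orthonormal_contrasts(m)
  Id <- diag(d)
  M_within <- Id %x% C                   # d*m -> d*(m-1), per-DV contrasts
  M_between <- Id %x% matrix(1 / m, m, 1)

  notes <- character(0)
  mv <- list(
    time = .mlm_effect(Y %*% M_within, X, rows = 1L),
    group = .mlm_effect(Y %*% M_between, X, rows = 2:g),
    `group:time` = .mlm_effect(Y %*% M_within, X, rows = 2:g))
  for (e in names(mv))
    if (is.character(mv[[e]])) {
      notes <- c(notes, paste0("multivariate test for '", e,
                               "' unavailable: ", mv[[e]]))
      mv[[e]] <- NULL
    }

  bm <- box_m(Y, group)
  primary <- if (!is.na(bm$p) && bm$p < alpha) "Pillai" else "Wilks"

  uni <- lapply(seq_along(dvs), function(i)
    .univariate_followup(wides[[i]]$y, group, alpha))
  names(uni) <- dvs
  pw <- lapply(seq_along(dvs), function(i)
    sidak_pairwise_times(wides[[i]]$y, wides[[i]]$times))
  names(pw) <- dvs

  structure(list(multivariate = mv, box_m = bm,
                 primary_statistic = primary, univariate = uni,
                 pairwise = pw, n = n, dvs = dvs, alpha = alpha,
                 notes = notes),
            class = "rm_manova")
}

# H/E SSCP machinery for one effect of the transformed MLM; returns a
# data.frame of the three multivariate statistics or a character string
# explaining why the test is unavailable.
.mlm_effect <- function(Z, X, rows) {
  n <- nrow(Z); p <- ncol(Z)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Z)
  E <- crossprod(Z) - t(B) %*% crossprod(X) %*% B
  L <- diag(ncol(X))[rows, , drop = FALSE]
  LB <- L %*% B
  H <- t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
  q <- nrow(L)
  v <- n - ncol(X)
  if (v - p + q < 1 || qr(E)$rank < p)
    return("rank-deficient error SSCP (collinear or too few subjects)")
  ev <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  ev <- pmax(ev, 0)
  s <- min(p, q)
  m_ <- (abs(p - q) - 1) / 2
  n_ <- (v - p - 1) / 2

  pillai <- sum(ev / (1 + ev))
  f_p <- ((2 * n_ + s + 1) / (2 * m_ + s + 1)) * pillai / (s - pillai)
  df1_p <- s * (2 * m_ + s + 1); df2_p <- s * (2 * n_ + s + 1)

  wilks <- prod(1 / (1 + ev))
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w_ <- v - (p - q + 1) / 2
  df1_w <- p * q; df2_w <- w_ * tt - (p * q - 2) / 2
  f_w <- ((1 - wilks^(1 / tt)) / wilks^(1 / tt)) * df2_w / df1_w

  roy <- max(ev)
  r_ <- max(p, q)
  df1_r <- r_; df2_r <- v - r_ + q
  f_r <- roy * df2_r / df1_r

  out <- data.frame(
    statistic = c("Pillai", "Wilks", "Roy"),
    value = c(pillai, wilks, roy),
    F = c(f_p, f_w, f_r),
    df1 = c(df1_p, df1_w, df1_r),
    df2 = c(df2_p, df2_w, df2_r))
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  out$partial_eta_sq <- c(pillai / s, 1 - wilks^(1 / s), roy / (1 + roy))
  out$observed_power <- .observed_power(out$F, out$df1, out$df2)
  out
}

# SPSS convention: lambda-hat = F * df1
.observed_power <- function(F, df1, df2, alpha = 0.05) {
  stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = F * df1,
            lower.tail = FALSE)
}

# Mauchly, GG/HF epsilons and the corrected univariate F for one DV
.univariate_followup <- function(y, group, alpha = 0.05) {
  n <- nrow(y); m <- ncol(y); g <- nlevels(group)
  C <- .orthonormal_contrasts(m)
  X <- stats::model.matrix(~group,
    contrasts.arg = list(group = "contr.sum"))  # Type III hypotheses
  Z <- y %*% C
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Z)
  E <- crossprod(Z) - t(B) %*% crossprod(X) %*% B
  df_e <- (n - g) * (m - 1)
  k <- m - 1

  # Mauchly on the contrasted pooled covariance
  Tm <- E / (n - g)
  lam <- eigen(Tm, symmetric = TRUE, only.values = TRUE)$values
  W <- prod(lam) / (mean(lam))^k
  f2 <- (2 * k^2 + k + 2) / (6 * k)
  chi <- -(n - g - f2) * log(W)
  df_m <- k * (k + 1) / 2 - 1
  p_m <- stats::pchisq(chi, df_m, lower.tail = FALSE)

  gg <- sum(lam)^2 / (k * sum(lam^2))
  hf <- min(1, ((n - g + 1) * k * gg - 2) / (k * (n - g - k * gg)))

  hyp <- function(rows) {
    L <- diag(g)[rows, , drop = FALSE]
    LB <- L %*% B
    sum(diag(t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB))
  }
  mse <- sum(diag(E)) / df_e
  eff <- function(ss, df1) {
    F <- (ss / df1) / mse
    # epsilon rule: sphericity tenable -> unadjusted; GG eps > 0.7 -> HF;
    # otherwise GG
    eps_used <- if (p_m >= alpha) 1 else if (gg > 0.7) hf else gg
    correction <- if (p_m >= alpha) "none" else if (gg > 0.7) "HF" else "GG"
    adf1 <- eps_used * df1; adf2 <- eps_used * df_e
    p <- stats::pf(F, adf1, adf2, lower.tail = FALSE)
    peta <- ss / (ss + sum(diag(E)))
    data.frame(F = F, df1 = adf1, df2 = adf2, p = p,
               correction = correction, epsilon = eps_used,
               partial_eta_sq = peta,
               observed_power = .observed_power(F, adf1, adf2))
  }
  res <- rbind(cbind(effect = "time", eff(hyp(1L), k)),
               cbind(effect = "group:time", eff(hyp(2:g), (g - 1) * k)))
  list(mauchly = list(W = W, chisq = chi, df = df_m, p = p_m),
       gg_epsilon = gg, hf_epsilon = hf, anova = res)
}

#' Box's M test of homogeneity of covariance matrices
#'
#' Chi-square and F approximations (Box 1949) of the equality of the
#' group covariance matrices of a subjects-by-variables matrix.
#'
#' @param Y Numeric matrix, subjects x variables.
#' @param group Factor of group membership.
#' @return List with `M`, `chisq`, `df_chisq`, `p_chisq`, `F`, `df1`,
#'   `df2`, `p` (F approximation; `p` is NA when a group covariance is
#'   singular).
#' @export
box_m <- function(Y, group) {
  group <- droplevels(as.factor(group))
  p <- ncol(Y); g <- nlevels(group)
  nj <- table(group); vj <- as.numeric(nj) - 1; v <- sum(vj)
  Sj <- lapply(levels(group), function(l) stats::cov(Y[group == l, ,
                                                       drop = FALSE]))
  Sp <- Reduce(`+`, Map(`*`, Sj, vj)) / v
  ld <- vapply(Sj, function(S) determinant(S)$modulus, numeric(1))
  if (any(!is.finite(ld)) || !is.finite(determinant(Sp)$modulus))
    return(list(M = NA, chisq = NA, df_chisq = NA, p_chisq = NA,
                F = NA, df1 = NA, df2 = NA, p = NA))
  M <- v * determinant(Sp)$modulus - sum(vj * ld)
  c1 <- (sum(1 / vj) - 1 / v) * (2 * p^2 + 3 * p - 1) /
    (6 * (p + 1) * (g - 1))
  c2 <- (sum(1 / vj^2) - 1 / v^2) * (p - 1) * (p + 2) / (6 * (g - 1))
  df1 <- p * (p + 1) * (g - 1) / 2
  chisq <- M * (1 - c1)
  p_chi <- stats::pchisq(chisq, df1, lower.tail = FALSE)
  if (c2 > c1^2) {
    df2 <- (df1 + 2) / (c2 - c1^2)
    Fst <- M / (df1 * (1 - c1 - df1 / df2))
  } else {
    df2 <- (df1 + 2) / (c1^2 - c2)
    b <- df2 / (1 - c1 - 2 / df2)
    Fst <- df2 * M / (df1 * (b - M))
  }
  list(M = as.numeric(M), chisq = as.numeric(chisq), df_chisq = df1,
       p_chisq = p_chi, F = as.numeric(Fst), df1 = df1, df2 = df2,
       p = stats::pf(as.numeric(Fst), df1, df2, lower.tail = FALSE))
}

#' Sidak adjustment of raw p values
#'
#' p_adj = 1 - (1 - p)^m, capped at 1; monotone in both p and m.
#'
#' @param p Raw p values in \[0, 1\].
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p values.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, 1 - (1 - p)^m)
}

#' Sidak-adjusted pairwise comparisons between assessment times
#'
#' Paired t tests between each pair of time points on one DV's wide
#' matrix, with the Sidak family-size equal to the number of pairs
#' (3 for three assessments).
#'
#' @param y Subjects x times matrix.
#' @param times Time labels (column order).
#' @return Data frame: `contrast`, `estimate`, `t`, `df`, `p_raw`, `p_sidak`.
#' @export
sidak_pairwise_times <- function(y, times = colnames(y)) {
  m <- ncol(y)
  if (is.null(times)) times <- paste0("t", seq_len(m))
  pairs <- utils::combn(m, 2)
  out <- do.call(rbind, apply(pairs, 2, function(pr) {
    d <- y[, pr[1]] - y[, pr[2]]
    tt <- stats::t.test(d)
    data.frame(contrast = paste(times[pr[1]], "-", times[pr[2]]),
               estimate = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value)
  }))
  out$p_sidak <- sidak_adjust(out$p_raw, ncol(pairs))
  out
}

#' @export
print.rm_manova <- function(x, ...) {
  cat("Repeated-measures MANOVA:", length(x$dvs), "DV(s) x 3 times,",
      x$n, "complete-case subjects\n")
  cat("Box's M p =", format.pval(x$box_m$p, digits = 3),
      "-> primary statistic:", x$primary_statistic, "\n")
  for (e in names(x$multivariate)) {
    cat("\nEffect:", e, "\n")
    print(x$multivariate[[e]], digits = 4, row.names = FALSE)
  }
  if (length(x$notes)) cat("\nNotes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
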