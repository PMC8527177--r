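#' A-priori power for the within-between interaction of a repeated-measures
#' ANOVA
#'
#' Uses the G*Power 3 convention for the group x time interaction of a
#' design with `g` between-subject groups and `m` repeated measurements:
#' noncentrality lambda = f^2 * n * m / (1 - rho), numerator df
#' (g - 1)(m - 1), denominator df (n - g)(m - 1), no nonsphericity
#' correction. At f = 0 the power equals alpha exactly.
#'
#' @param n Total sample size.
#' @param g Number of between-subject groups.
#' @param m Number of repeated measurements.
#' @param alpha Type-I error rate.
#' @param rho Correlation between any two repeated measurements, in \[0, 1).
#' @param f Cohen's f of the interaction (cell-mean rms / error SD).
#' @return Power in \[alpha, 1).
#' @export
power_rm_anova <- function(n, g = 2, m = 3, alpha = 0.05, rho = 0.5, f) {
  stopifnot(n > g, rho >= 0, rho < 1, f >= 0, alpha > 0, alpha < 1)
  lambda <- f^2 * n * m / (1 - rho)
  df1 <- (g - 1) * (m - 1)
  df2 <- (n - g) * (m - 1)
  stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda,
            lower.tail = FALSE)
}

#' Minimal detectable Cohen's f at a target power
#'
#' Inverts [power_rm_anova()] in f by bisection to 1e-6.
#'
#' @inheritParams power_rm_anova
#' @param power Target power, in (alpha, 1).
#' @return The Cohen's f at which the design reaches the target power.
#' @export
solve_f <- function(n, g = 2, m = 3, alpha = 0.05, rho = 0.5, power = 0.80) {
  if (power >= 1 || power <= alpha)
    stop("target power must lie in (alpha, 1)")
  stats::uniroot(function(f)
    power_rm_anova(n, g, m, alpha, rho, f) - power,
    interval = c(0, 10), tol = 1e-6)$root
}

#' Two-tailed critical t value
#'
#' @param alpha Two-tailed alpha.
#' @param df Degrees of freedom (>= 1).
#' @return `qt(1 - alpha / 2, df)`.
#' @export
critical_t <- function(alpha = 0.05, df) {
  stopifnot(alpha > 0, alpha < 1, df >= 1)
  stats::qt(1 - alpha / 2, df)
}

#' Fast split-plot repeated-measures ANOVA (one between factor)
#'
#' Univariate time and group x time F tests via orthonormal within-subject
#' contrasts: with C the orthonormal polynomial contrast matrix, SS are
#' traces of the hypothesis and residual SSCP matrices of Z = Y C
#' regressed on the group design. This is the averaged (sphericity-
#' assuming) F, exact under compound symmetry; it is the kernel behind the
#' Monte-Carlo power checks.
#'
#' @param y n x m matrix, one row per subject, columns in time order.
#' @param group Factor of length n.
#' @return List with `F_time`, `F_interaction`, dfs and p values.
#' @export
rm_anova_f <- function(y, group) {
  stopifnot(is.matrix(y), nrow(y) == length(group))
  group <- droplevels(as.factor(group))
  n <- nrow(y); m <- ncol(y); g <- nlevels(group)
  C <- .orthonormal_contrasts(m)
  Z <- y %*% C
  X <- stats::model.matrix(~group,
    contrasts.arg = list(group = "contr.sum"))  # Type III hypotheses
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Z)
  E <- crossprod(Z) - t(B) %*% crossprod(X) %*% B
  hyp <- function(rows) {
    L <- diag(ncol(X))[rows, , drop = FALSE]
    LB <- L %*% B
    t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
  }
  H_time <- hyp(1L)                       # intercept of the contrasted data
  H_int <- hyp(2:g)
  df_e <- (n - g) * (m - 1)
  mse <- sum(diag(E)) / df_e
  F_time <- (sum(diag(H_time)) / (m - 1)) / mse
  F_int <- (sum(diag(H_int)) / ((g - 1) * (m - 1))) / mse
  list(F_time = F_time, df1_time = m - 1,
       F_interaction = F_int, df1_interaction = (g - 1) * (m - 1),
       df2 = df_e,
       p_time = stats::pf(F_time, m - 1, df_e, lower.tail = FALSE),
       p_interaction = stats::pf(F_int, (g - 1) * (m - 1), df_e,
                                 lower.tail = FALSE))
}

#' Monte-Carlo power of the interaction test on generated crossover tables
#'
#' Draws `n_rep` tables from [simulate_behavioral_table()] (seeds derived
#' from `seed`), runs the split-plot interaction F test at `alpha` on
#' each, and returns the rejection fraction.
#'
#' @param truth A [behavioral_ground_truth()] (its own seed is ignored).
#' @param n_rep Number of replicates.
#' @param alpha Test level.
#' @param seed Root seed for the replicate stream.
#' @return Rejection proportion.
#' @export
mc_interaction_power <- function(truth, n_rep = 2000, alpha = 0.05,
                                 seed = 1L) {
  rej <- 0L
  base <- (abs(as.integer(seed)) %% 1000L) * 1000003L   # separated streams
  for (r in seq_len(n_rep)) {
    tr <- truth
    tr$seed <- (base + r) %% .Machine$integer.max
    w <- measurement_wide(simulate_behavioral_table(tr))
    if (rm_anova_f(w$y, w$group)$p_interaction < alpha) rej <- rej + 1L
  }
  rej / n_rep
}

.orthonormal_contrasts <- function(m) {
  C <- stats::contr.poly(m)
  # contr.poly columns are already orthonormal
  C
}
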