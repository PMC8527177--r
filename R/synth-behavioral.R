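#' Ground truth for synthetic crossover behavioral tables
#'
#' Describes the two-arm crossover design: two treatment-order groups
#' (hardware-software vs. software-hardware), three assessments (baseline,
#' 5 weeks, 10 weeks), compound-symmetric within-subject correlation rho,
#' and Cohen's f effect sizes for the group, time and group x time
#' interaction cell-mean patterns. Effect sizes use the cell-mean
#' definition f = sd(cell-mean offsets) / sd(error), mapped through the
#' same noncentrality convention as [power_rm_anova()], so the generator
#' and the power calculator agree by construction.
#'
#' @param n_per_group Integer vector of length 2 (default the 27/26 split
#'   of 53 completers).
#' @param rho Repeated-measures correlation in \[0, 1).
#' @param f_interaction,f_time,f_group Cohen's f of each effect (>= 0).
#' @param sd Total within-cell SD (DV units).
#' @param mu Grand mean.
#' @param dv_name Dependent-variable label for the long table.
#' @param seed Integer seed.
#' @return An object of class `behavioral_ground_truth`.
#' @export
behavioral_ground_truth <- function(n_per_group = c(27L, 26L),
                                    rho = 0.5,
                                    f_interaction = 0.17,
                                    f_time = 0, f_group = 0,
                                    sd = 1, mu = 0,
                                    dv_name = "score",
                                    seed = 1L) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2))
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (f_interaction < 0 || f_time < 0 || f_group < 0)
    stop("effect sizes must be >= 0")
  if (sd <= 0) stop("residual sd must be positive")
  structure(list(n_per_group = as.integer(n_per_group), rho = rho,
                 f_interaction = f_interaction, f_time = f_time,
                 f_group = f_group, sd = sd, mu = mu, dv_name = dv_name,
                 seed = as.integer(seed),
                 groups = c("hardware-software", "software-hardware"),
                 times = c("baseline", "wk5", "wk10")),
            class = "behavioral_ground_truth")
}

#' Population cell means implied by a behavioral ground truth
#'
#' Group, time and interaction offsets are fixed zero-sum patterns scaled
#' so the root-mean-square of each pattern's offsets equals f * sd.
#'
#' @param truth A [behavioral_ground_truth()].
#' @return 2 x 3 matrix of cell means (groups x times).
#' @export
behavioral_cell_means <- function(truth) {
  g_pat <- c(1, -1)                              # rms 1
  t_pat <- c(1, 0, -1) / sqrt(2 / 3)             # rms 1
  i_pat <- rbind(c(1, 0, -1), c(-1, 0, 1)) / sqrt(2 / 3)  # rms 1, doubly centered
  m <- truth$mu +
    outer(truth$f_group * truth$sd * g_pat, rep(1, 3)) +
    outer(rep(1, 2), truth$f_time * truth$sd * t_pat) +
    truth$f_interaction * truth$sd * i_pat
  dimnames(m) <- list(truth$groups, truth$times)
  m
}

#' Cohen's f of the interaction recomputed from cell means
#'
#' Double-centers the cell-mean matrix and returns rms(offsets) / sd;
#' equals the requested `f_interaction` to machine precision.
#'
#' @param truth A [behavioral_ground_truth()].
#' @return Cohen's f.
#' @export
behavioral_empirical_f <- function(truth) {
  m <- behavioral_cell_means(truth)
  d <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  sqrt(mean(d^2)) / truth$sd
}

#' Generate a long-format crossover measurement table
#'
#' Each subject's three measurements are cell mean + shared subject effect
#' N(0, rho sd^2) + independent noise N(0, (1 - rho) sd^2), giving an
#' exactly compound-symmetric covariance with total variance sd^2 and
#' correlation rho between any two time points.
#'
#' @param truth A [behavioral_ground_truth()].
#' @return Data frame (`subject_id`, `group`, `time`, `dv_name`, `value`)
#'   of class `measurement_table`.
#' @export
simulate_behavioral_table <- function(truth) {
  stopifnot(inherits(truth, "behavioral_ground_truth"))
  set.seed(truth$seed)
  cm <- behavioral_cell_means(truth)
  n <- sum(truth$n_per_group)
  grp <- rep(1:2, truth$n_per_group)
  subj <- rep(0.0, n)
  y <- cm[grp, , drop = FALSE] +
    stats::rnorm(n, sd = sqrt(truth$rho) * truth$sd) +
    matrix(stats::rnorm(n * 3, sd = sqrt(1 - truth$rho) * truth$sd), n, 3)
  out <- data.frame(
    subject_id = rep(sprintf("S%03d", seq_len(n)), each = 3),
    group = rep(truth$groups[grp], each = 3),
    time = rep(truth$times, n),
    dv_name = truth$dv_name,
    value = as.vector(t(y)))
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Reshape a long measurement table to subjects x times for one DV
#'
#' @param table A `measurement_table`.
#' @param dv DV name (default the only one present).
#' @return List with `y` (n x m matrix, columns in time order) and `group`
#'   (factor), complete cases only.
#' @export
measurement_wide <- function(table, dv = NULL) {
  stopifnot(all(c("subject_id", "group", "time", "dv_name", "value")
                %in% names(table)))
  if (is.null(dv)) dv <- unique(table$dv_name)[1]
  tab <- table[table$dv_name == dv, ]
  times <- unique(tab$time)
  wide <- stats::reshape(tab[, c("subject_id", "group", "time", "value")],
                         idvar = c("subject_id", "group"),
                         timevar = "time", direction = "wide")
  y <- as.matrix(wide[, paste0("value.", times), drop = FALSE])
  keep <- stats::complete.cases(y)
  list(y = unname(y[keep, , drop = FALSE]),
       group = factor(wide$group[keep]),
       subject_id = wide$subject_id[keep],
       times = times)
}
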