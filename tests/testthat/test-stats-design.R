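test_that("screening flags constructed outliers and calibrates near alpha", {
  set.seed(20)
  n <- 1000
  tab <- data.frame(subject_id = sprintf("S%04d", rep(1:n, each = 3)),
                    group = "g1", time = rep(c("t1", "t2", "t3"), n),
                    dv_name = "dv", value = rnorm(3 * n))
  scr <- screen_table(tab)
  expect_lt(mean(scr$values$outlier), 0.004)   # ~0.001 expected

  # small clean sample plus one planted z = 5 value: only it is flagged
  set.seed(22)
  tab2 <- data.frame(subject_id = sprintf("S%03d", rep(1:20, each = 3)),
                     group = "g1", time = rep(c("t1", "t2", "t3"), 20),
                     dv_name = "dv",
                     value = qnorm(ppoints(60)))   # z range well inside 3.29
  tab2$value[30] <- 5
  scr2 <- screen_table(tab2)
  expect_true(scr2$values$outlier[30])
  expect_equal(sum(scr2$values$outlier), 1)
})

test_that("log-normal data triggers the log10 recommendation, transformed
           data does not", {
  set.seed(21)
  v <- exp(rnorm(300, sd = 1.2))
  tab <- data.frame(subject_id = sprintf("S%03d", rep(1:100, each = 3)),
                    group = "g1", time = rep(c("t1", "t2", "t3"), 100),
                    dv_name = "dv", value = v)
  expect_true(screen_table(tab)$dv$recommend_log10)
  tab$value <- log10_transform(tab$value)
  expect_false(screen_table(tab)$dv$recommend_log10)
})

test_that("log10 transform guards positivity and round-trips", {
  expect_equal(log10_transform(100), 2)
  expect_equal(log10_transform(1), 0)
  expect_error(log10_transform(c(1, 0)), "positive")
  x <- runif(20, 0.1, 50)
  expect_equal(inv_log10_transform(log10_transform(x)), x,
               tolerance = 1e-12)
})

test_that("multivariate tests, sphericity and epsilons match car::Anova", {
  library(car)
  tr <- behavioral_ground_truth(f_interaction = 0.35, f_time = 0.15,
                                seed = 30L)
  tab <- simulate_behavioral_table(tr)
  fit <- rm_manova(tab)

  w <- measurement_wide(tab)
  g <- w$group; contrasts(g) <- contr.sum(2)
  Y <- w$y; colnames(Y) <- w$times
  a <- car::Anova(lm(Y ~ g),
                  idata = data.frame(time = factor(w$times,
                                                   levels = w$times)),
                  idesign = ~time, type = 3)
  s <- suppressWarnings(summary(a, multivariate = TRUE))

  sph <- s$sphericity.tests
  u <- fit$univariate[[1]]
  expect_equal(u$mauchly$W, sph["time", "Test statistic"],
               tolerance = 1e-8)
  expect_equal(u$mauchly$p, sph["time", "p-value"], tolerance = 1e-6)
  expect_equal(u$gg_epsilon, unname(s$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-8)
  expect_equal(u$hf_epsilon,
               min(1, unname(s$pval.adjustments[1, "HF eps"])),
               tolerance = 1e-8)

  mt <- s$multivariate.tests$`g:time`
  ev <- Re(eigen(solve(mt$SSPE) %*% mt$SSPH, only.values = TRUE)$values)
  pillai_car <- sum(ev / (1 + ev))
  my <- fit$multivariate$`group:time`
  expect_equal(my$value[my$statistic == "Pillai"], pillai_car,
               tolerance = 1e-8)

  ut <- s$univariate.tests
  expect_equal(fit$univariate[[1]]$anova$F,
               unname(ut[c("time", "g:time"), "F value"]),
               tolerance = 1e-8)
})

test_that("epsilon bounds and the k = 2 degeneracy hold", {
  set.seed(33)
  # k = 2 levels: GG epsilon is exactly 1
  y <- matrix(rnorm(40), 20, 2)
  g <- factor(rep(1:2, each = 10))
  u <- svtephys:::.univariate_followup(y, g)
  expect_equal(u$gg_epsilon, 1, tolerance = 1e-12)

  for (i in 1:10) {
    y3 <- matrix(rnorm(90), 30, 3) %*% matrix(rnorm(9), 3, 3)
    u3 <- svtephys:::.univariate_followup(y3, factor(rep(1:2, each = 15)))
    expect_gte(u3$gg_epsilon, 1 / 2 - 1e-12)
    expect_lte(u3$gg_epsilon, 1 + 1e-12)
    expect_gte(u3$hf_epsilon + 1e-12, u3$gg_epsilon)
    expect_lte(u3$hf_epsilon, 1)
  }
})

test_that("compound-symmetric data keeps GG epsilon near 1 with HF above", {
  gg <- hf <- numeric(40)
  for (i in 1:40) {
    tr <- behavioral_ground_truth(seed = 400L + i)
    w <- measurement_wide(simulate_behavioral_table(tr))
    u <- svtephys:::.univariate_followup(w$y, w$group)
    gg[i] <- u$gg_epsilon; hf[i] <- u$hf_epsilon
  }
  expect_gt(mean(gg), 0.9)
  expect_true(all(hf >= gg))
})

test_that("collinear DVs make the multivariate tests unavailable", {
  tr <- behavioral_ground_truth(seed = 44L)
  tab <- simulate_behavioral_table(tr)
  tab2 <- tab; tab2$dv_name <- "copy"
  both <- rbind(tab, tab2)
  class(both) <- class(tab)
  fit <- rm_manova(both)
  expect_true(length(fit$notes) > 0)
  expect_match(fit$notes[1], "rank-deficient")
})

test_that("Box's M gate selects Pillai under covariance heterogeneity", {
  set.seed(50)
  n <- 40
  y1 <- matrix(rnorm(n * 3, sd = 1), n, 3)
  y2 <- matrix(rnorm(n * 3, sd = 3), n, 3)
  tab <- data.frame(
    subject_id = sprintf("S%03d", rep(1:(2 * n), each = 3)),
    group = rep(c("a", "b"), each = 3 * n),
    time = rep(c("t1", "t2", "t3"), 2 * n),
    dv_name = "dv",
    value = as.vector(t(rbind(y1, y2))))
  fit <- rm_manova(tab)
  expect_lt(fit$box_m$p, 0.05)
  expect_identical(fit$primary_statistic, "Pillai")

  tr <- behavioral_ground_truth(seed = 51L)
  fit2 <- rm_manova(simulate_behavioral_table(tr))
  expect_identical(fit2$primary_statistic, "Wilks")
})

test_that("Sidak adjustment is the closed form and monotone", {
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  expect_equal(round(sidak_adjust(0.5, 10), 6), 0.999023)
  p <- seq(0, 1, by = 0.1)
  expect_true(all(diff(sidak_adjust(p, 4)) >= 0))
  expect_true(all(sidak_adjust(p, 5) >= sidak_adjust(p, 2)))
  expect_true(all(sidak_adjust(p, 7) >= p))
})

test_that("pairwise time comparisons use the 3-comparison Sidak family", {
  set.seed(55)
  y <- matrix(rnorm(90), 30, 3) + rep(c(0, 0.5, 1), each = 30)
  pw <- sidak_pairwise_times(y, c("baseline", "wk5", "wk10"))
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_sidak, sidak_adjust(pw$p_raw, 3))
  expect_true(all(pw$p_sidak >= pw$p_raw))
})
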