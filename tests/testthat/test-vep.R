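test_that("sweep geometry matches the recording protocol", {
  ck <- stimulus_spec("checkerboard")
  expect_equal(ck$sweep_length / ck$sweep_rate, 0.5)
  expect_equal(c(ck$sweep_rate, ck$sweep_length), c(1024, 512))
  expect_equal(ck$contrast_pct, 85)
  gr <- stimulus_spec("grating")
  expect_equal(c(gr$sweep_rate, gr$sweep_length), c(2048, 1024))
  expect_equal(gr$sweep_length / gr$sweep_rate, 0.5)
})

test_that("ground-truth validation enforces component ordering and window", {
  expect_error(vep_ground_truth(n75 = 110), "n75 < p100")
  expect_error(vep_ground_truth(n135 = 495), "outside")
  expect_error(vep_ground_truth(amplitude = -1), "positive")
})

test_that("averaging is the pointwise mean with the expected noise gain", {
  m <- matrix(rep(c(1, 2, 3, 4), each = 3), 3)
  av <- average_sweeps(m)
  expect_equal(as.numeric(av), c(1, 2, 3, 4))
  expect_equal(attr(av, "n_sweeps"), 3)
  expect_equal(as.numeric(average_sweeps(m[1, , drop = FALSE])), m[1, ])
  expect_error(average_sweeps(list(1:3, 1:4)), "ragged")

  # RMS error of a 40-sweep average shrinks ~ 1/sqrt(40)
  tmpl <- vep_template(vep_ground_truth(noise_sd = 2))
  set.seed(10)
  r_single <- r_avg <- numeric(30)
  for (i in 1:30) {
    noise <- matrix(rnorm(40 * length(tmpl), sd = 2), 40)
    sweeps <- sweep(noise, 2, tmpl, `+`)
    r_single[i] <- sqrt(mean((sweeps[1, ] - tmpl)^2))
    r_avg[i] <- sqrt(mean((average_sweeps(sweeps) - tmpl)^2))
  }
  expect_equal(mean(r_avg) / mean(r_single), 1 / sqrt(40), tolerance = 0.1)
})

test_that("noise-free templates are recovered exactly on the sample grid", {
  vt <- vep_ground_truth(noise_sd = 0)
  tr <- simulate_vep_trials(vt)
  expect_equal(tr$trials[[1]][1, ], tr$template)   # sd 0: sweep == template
  cc <- detect_components(average_sweeps(tr$trials[[2]]), 1024)
  half_sample_ms <- 1000 / 1024 / 2
  expect_lt(abs(cc$n75 - 75), half_sample_ms)
  expect_lt(abs(cc$p100 - 100), half_sample_ms)
  expect_lt(abs(cc$n135 - 135), half_sample_ms)
  # detected indices coincide with the template's sampled extrema
  expect_equal(cc$amplitude, max(tr$template) - min(tr$template[1:103]))
  expect_true(cc$measurable)
})

test_that("latencies are translation equivariant, amplitude baseline
           invariant", {
  vt <- vep_ground_truth(noise_sd = 0)
  w0 <- vep_template(vt)
  shift <- round(10 / 1000 * 1024)          # +10 ms in samples
  w10 <- c(rep(0, shift), w0[1:(length(w0) - shift)])
  c0 <- detect_components(w0, 1024)
  c10 <- detect_components(w10, 1024)
  expect_equal(c10$p100 - c0$p100, shift / 1024 * 1000)
  expect_equal(c10$n75 - c0$n75, shift / 1024 * 1000)
  expect_equal(c10$amplitude, c0$amplitude, tolerance = 1e-12)
  cb <- detect_components(w0 + 12.3, 1024)
  expect_equal(cb$amplitude, c0$amplitude, tolerance = 1e-12)
})

test_that("monotone waveform in the P100 window is flagged unmeasurable", {
  t_ms <- (0:511) / 1024 * 1000
  ramp <- t_ms / 50
  cc <- detect_components(ramp, 1024)
  expect_false(cc$measurable)
  expect_true("p100_no_local_maximum" %in% cc$flags)
})

test_that("noisy P100 latency stays within 2 samples of truth for most
           heavy-noise averages (Monte Carlo)", {
  # at noise sd = amplitude/4 the 40-sweep average still carries ~0.6 uV
  # of noise against a broad 9 uV peak; the argmax jitters by a sample or
  # two in a minority of draws
  vt0 <- vep_ground_truth(noise_sd = 15 / 4)
  err <- numeric(100)
  for (i in 1:100) {
    vt <- vt0; vt$seed <- 1000L + i
    tr <- simulate_vep_trials(vt)
    cc <- detect_components(average_sweeps(tr$trials[[1]]), 1024)
    err[i] <- abs(cc$p100 - 100)
  }
  expect_gte(mean(err <= 2 * 1000 / 1024), 0.80)
  expect_lt(max(err), 5)                       # never off by > 5 ms
})

test_that("stimulus summaries rank by latency and log-transform the means", {
  mk <- function(lat, amp, k) structure(
    list(n75 = lat - 25, p100 = lat, n135 = lat + 35, amplitude = amp,
         trial = k, measurable = TRUE, flags = character(0)),
    class = "vep_components")
  s <- summarize_stimulus(list(mk(105, 15, 1), mk(100, 14, 2),
                               mk(110, 16, 3)))
  expect_equal(s$mean_latency_ms, 105)
  expect_equal(s$ranking, c(2, 1, 3))
  expect_equal(s$per_trial_latency, c(100, 105, 110))
  expect_true(s$complete)

  ties <- summarize_stimulus(list(mk(104.46, 10, 1), mk(104.46, 10, 2),
                                  mk(104.46, 10, 3)))
  expect_equal(ties$ranking, c(1, 2, 3))     # ties keep trial order
  expect_equal(ties$mean_latency_ms, 104.46)
  expect_equal(round(ties$log10_latency, 4), 2.0190)

  # mean over trials ignores the ranking bookkeeping
  perm <- summarize_stimulus(list(mk(110, 16, 1), mk(100, 14, 2),
                                  mk(105, 15, 3)))
  expect_equal(perm$mean_latency_ms, s$mean_latency_ms)
  expect_equal(perm$mean_amplitude_uv, s$mean_amplitude_uv)

  bad <- mk(100, 15, 1); bad$measurable <- FALSE
  expect_false(summarize_stimulus(list(bad, mk(100, 15, 2),
                                       mk(100, 15, 3)))$complete)
})
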