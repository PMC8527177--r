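test_that("filtering removes DC and notched mains, keeps the passband", {
  fs <- 256
  t <- seq_len(8 * fs) / fs
  rms <- function(x) sqrt(mean(x^2))
  mid <- (2 * fs):(6 * fs)   # avoid filter edge transients

  dc <- eeg_preprocess(eeg_record(matrix(1, 8 * fs, 1), channels = "Fz"))
  expect_lt(max(abs(dc$data[mid, 1])), 1e-10)

  hum <- eeg_preprocess(eeg_record(sin(2 * pi * 50 * t), channels = "Fz"))
  expect_lt(rms(hum$data[mid, 1]), 0.05 * rms(sin(2 * pi * 50 * t)))

  alpha <- eeg_preprocess(eeg_record(sin(2 * pi * 10 * t), channels = "Fz"))
  expect_lt(abs(rms(alpha$data[mid, 1]) / rms(sin(2 * pi * 10 * t)) - 1),
            0.10)
})

test_that("preprocess rejects rate mismatch and NaN input", {
  expect_error(eeg_preprocess(eeg_record(rnorm(1000), fs = 512)), "512")
  bad <- eeg_record(c(rnorm(999), NA))
  expect_error(eeg_preprocess(bad), "NA")
})

test_that("decontamination zeros exactly the masked samples", {
  rec <- eeg_record(matrix(rnorm(1024), ncol = 1), channels = "Fz")
  out <- decontaminate(rec, rep(FALSE, 1024))
  expect_identical(out$data, rec$data)
  expect_false(any(out$zero_flags))

  mask <- rep(FALSE, 1024); mask[1:300] <- TRUE
  out <- decontaminate(rec, mask)
  expect_equal(sum(out$zero_flags), 300)
  expect_true(all(out$data[1:300, 1] == 0))
  expect_identical(out$data[301:1024, 1], rec$data[301:1024, 1])
  expect_error(decontaminate(rec, rep(FALSE, 10)), "length")
})

test_that("per-overlay PSD matches an explicit-sum DFT oracle", {
  fs <- 256
  t <- seq_len(2 * fs) / fs
  x <- 3 * sin(2 * pi * 10 * t) + 1.5 * sin(2 * pi * 27 * t + 0.4)
  rec <- decontaminate(eeg_record(x, channels = "Fz"))
  e <- epoch_psd(rec, 0)
  oracle <- (dft_overlay_psd(x[1:256]) + dft_overlay_psd(x[129:384]) +
               dft_overlay_psd(x[257:512])) / 3
  expect_lt(max(abs(e$psd - oracle) / oracle[oracle > 0]), 1e-6)
  expect_equal(unname(which.max(e$psd)), 10)
})

test_that("windowed PSD integrates to the windowed mean square (Parseval)", {
  fs <- 256
  w <- signal::kaiser(fs, 14)
  for (freq in c(7, 10.5, 33)) {
    t <- seq_len(2 * fs) / fs
    x <- sin(2 * pi * freq * t)
    rec <- decontaminate(eeg_record(x, channels = "Fz"))
    e <- epoch_psd(rec, 0)
    ms <- mean(vapply(list(1:256, 129:384, 257:512), function(i)
      sum((x[i] * w)^2) / sum(w^2), numeric(1)))
    expect_equal(sum(e$psd) * 1, ms, tolerance = 1e-6)
  }
})

test_that("overlay exclusion and epoch validity follow the zero-count rule", {
  r <- overlay_validity(c(130L, 50L, 20L))
  expect_identical(r$excluded, c(TRUE, FALSE, FALSE))
  expect_identical(r$overlays_used, 2L)
  expect_true(r$valid)

  r <- overlay_validity(c(130L, 129L, 0L))
  expect_identical(r$overlays_used, 1L)
  expect_false(r$valid)

  expect_true(overlay_validity(c(128L, 128L, 128L))$valid)  # boundary: kept

  # realizable mask with counts (130, 50, 20) traced through epoch_psd
  set.seed(1)
  rec <- record_with_zero_counts(130, 50, 20)
  e <- epoch_psd(rec, 0)
  expect_identical(e$zero_counts, c(130L, 50L, 20L))
  expect_identical(e$overlays_used, 2L)
  expect_true(e$valid)
})

test_that("a mask covering one full overlay excludes exactly that overlay", {
  set.seed(2)
  rec <- eeg_record(matrix(rnorm(512), ncol = 1), channels = "Fz")
  mask <- rep(FALSE, 512); mask[1:256] <- TRUE   # first overlay fully zeroed
  e <- epoch_psd(decontaminate(rec, mask), 0)
  expect_identical(e$zero_counts[1], 256L)
  expect_identical(e$overlays_used, 2L)
  expect_true(e$valid)
})

test_that("relative PSD normalizes, band averages follow the bin layout", {
  flat <- relative_psd(fake_epoch(rep(7, 40)))
  expect_equal(unname(flat$rel), rep(1 / 40, 40))
  b <- band_average(flat)
  expect_equal(as.numeric(b), rep(0.025, 5))
  expect_equal(compute_stmli(b), 1.0)

  one <- relative_psd(fake_epoch(c(rep(0, 9), 5, rep(0, 30))))
  expect_equal(unname(one$rel[10]), 1)
  expect_equal(sum(one$rel), 1)

  spike5 <- band_average(relative_psd(fake_epoch(c(0, 0, 0, 0, 3,
                                                   rep(0, 35)))))
  expect_equal(spike5[["theta"]], 1 / 5)
  expect_equal(spike5[["gamma"]], 0)

  set.seed(4)
  r <- relative_psd(fake_epoch(runif(40)))
  expect_equal(sum(r$rel), 1, tolerance = 1e-9)
  bsum <- sum(as.numeric(band_average(r)) * lengths(eeg_bands()))
  expect_equal(bsum, sum(r$rel[3:40]))
  expect_lte(bsum, 1)

  inv <- fake_epoch(rep(1, 40)); inv$valid <- FALSE
  expect_error(relative_psd(inv), "invalid")
})

test_that("relative spectra, band powers and STMLI are scale invariant", {
  set.seed(5)
  x <- rnorm(4 * 256)
  for (c_ in c(0.001, 42)) {
    r1 <- decontaminate(eeg_record(x, channels = "Fz"))
    r2 <- decontaminate(eeg_record(c_ * x, channels = "Fz"))
    b1 <- band_average(relative_psd(epoch_psd(r1, 1)))
    b2 <- band_average(relative_psd(epoch_psd(r2, 1)))
    expect_equal(as.numeric(b1), as.numeric(b2), tolerance = 1e-12)
    expect_equal(compute_stmli(b1), compute_stmli(b2), tolerance = 1e-12)
  }
})
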