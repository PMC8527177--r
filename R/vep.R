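#' Transient-VEP stimulus specification
#'
#' The two stimulus families of the recording protocol: checkerboards
#' (85% Michelson contrast, 2 reversals/s, sweeps sampled at 1,024 Hz over
#' 512 points) and vertical sinusoidal gratings (10% contrast,
#' 4 reversals/s, 2,048 Hz over 1,024 points). Either way a sweep spans
#' 0.5 s; each pattern is presented 3 times for 20 s.
#'
#' @param kind "checkerboard" or "grating".
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("checkerboard", "grating")) {
  kind <- match.arg(kind)
  if (kind == "checkerboard")
    out <- list(kind = kind, contrast_pct = 85, reversal_rate = 2,
                sweep_rate = 1024, sweep_length = 512L)
  else
    out <- list(kind = kind, contrast_pct = 10, reversal_rate = 4,
                sweep_rate = 2048, sweep_length = 1024L)
  out$presentations <- 3L
  out$presentation_s <- 20
  stopifnot(out$sweep_length / out$sweep_rate == 0.5)
  structure(out, class = "stimulus_spec")
}

#' Ground truth for synthetic VEP sweeps
#'
#' Parameterises the N75-P100-N135 complex: component latencies (ms),
#' the N75-to-P100 peak-to-peak amplitude (microvolts), the full width of
#' each component lobe, additive white-noise SD per sample, and the sweep
#' set geometry. The noise-free template is built from raised-cosine lobes
#' whose supports do not reach the neighbouring peaks, so peak latencies
#' and the peak-to-peak amplitude are exact by construction.
#'
#' @param n75,p100,n135 Component latencies in ms (must be increasing).
#' @param amplitude Peak-to-peak N75-P100 amplitude in microvolts (> 0).
#' @param width Full lobe width in ms.
#' @param noise_sd Per-sample noise SD in microvolts.
#' @param sweeps_per_trial Sweeps averaged per trial (40 = one 20-s
#'   checkerboard presentation at 2 rev/s, or a grating presentation
#'   locked to alternate reversals).
#' @param stimulus A [stimulus_spec()] fixing sweep rate and length.
#' @param trials Presentations per stimulus (3).
#' @param seed Integer seed.
#' @return An object of class `vep_ground_truth`.
#' @export
vep_ground_truth <- function(n75 = 75, p100 = 100, n135 = 135,
                             amplitude = 15, width = 30, noise_sd = 2,
                             sweeps_per_trial = 40,
                             stimulus = stimulus_spec("checkerboard"),
                             trials = 3L, seed = 1L) {
  if (!(n75 < p100 && p100 < n135))
    stop("latencies must satisfy n75 < p100 < n135")
  if (amplitude <= 0) stop("amplitude must be positive")
  sweep_ms <- stimulus$sweep_length / stimulus$sweep_rate * 1000
  if (n135 + width / 2 >= sweep_ms)
    stop("component latencies fall outside the ", sweep_ms, " ms sweep")
  if (width / 2 >= min(p100 - n75, n135 - p100))
    stop("lobe half-width reaches a neighbouring peak; reduce width")
  structure(list(n75 = n75, p100 = p100, n135 = n135,
                 amplitude = amplitude, width = width, noise_sd = noise_sd,
                 sweeps_per_trial = as.integer(sweeps_per_trial),
                 stimulus = stimulus, trials = as.integer(trials),
                 seed = as.integer(seed)),
            class = "vep_ground_truth")
}

#' Noise-free VEP template
#'
#' @param truth A [vep_ground_truth()].
#' @return Numeric vector of `sweep_length` samples (microvolts).
#' @export
vep_template <- function(truth) {
  st <- truth$stimulus
  t_ms <- (seq_len(st$sweep_length) - 1) / st$sweep_rate * 1000
  hw <- truth$width / 2
  lobe <- function(t0, a) {
    v <- numeric(length(t_ms))
    i <- abs(t_ms - t0) <= hw
    v[i] <- a * 0.5 * (1 + cos(pi * (t_ms[i] - t0) / hw))
    v
  }
  # amplitude split: P100 carries 60%, N75 40% of the peak-to-peak value
  lobe(truth$p100, 0.6 * truth$amplitude) -
    lobe(truth$n75, 0.4 * truth$amplitude) -
    lobe(truth$n135, 0.3 * truth$amplitude)
}

#' Generate VEP sweep sets grouped into trials
#'
#' Each sweep is the template plus independent white Gaussian noise;
#' `noise_sd = 0` reproduces the template in every sweep.
#'
#' @param truth A [vep_ground_truth()].
#' @return List of class `vep_trials`: per trial a sweeps-by-samples
#'   matrix, plus `template`, `stimulus`, `truth`.
#' @export
simulate_vep_trials <- function(truth) {
  stopifnot(inherits(truth, "vep_ground_truth"))
  tmpl <- vep_template(truth)
  set.seed(truth$seed)
  trials <- lapply(seq_len(truth$trials), function(i) {
    noise <- matrix(stats::rnorm(truth$sweeps_per_trial * length(tmpl),
                                 sd = truth$noise_sd),
                    truth$sweeps_per_trial, length(tmpl))
    sweep_mat <- sweep(noise, 2, tmpl, `+`)
    sweep_mat
  })
  structure(list(trials = trials, template = tmpl,
                 stimulus = truth$stimulus, truth = truth),
            class = "vep_trials")
}

#' Average the sweeps of one trial
#'
#' @param sweeps Sweeps-by-samples matrix (or list of equal-length sweeps).
#' @return Numeric averaged waveform with attribute `n_sweeps`.
#' @export
average_sweeps <- function(sweeps) {
  if (is.list(sweeps)) {
    if (length(unique(lengths(sweeps))) != 1)
      stop("ragged sweep lengths")
    sweeps <- do.call(rbind, sweeps)
  }
  stopifnot(is.matrix(sweeps), nrow(sweeps) >= 1)
  structure(colMeans(sweeps), n_sweeps = nrow(sweeps))
}

#' Default component search windows (ms)
#' @return Named list of `c(lo, hi)` windows for n75, p100, n135.
#' @export
vep_windows <- function() {
  list(n75 = c(55, 95), p100 = c(80, 140), n135 = c(115, 190))
}

#' Extract N75-P100-N135 components from an averaged waveform
#'
#' P100 is the maximum inside its search window; N75 the minimum inside
#' its window before the detected P100; N135 the minimum after P100.
#' Latencies are reported on the sample grid (ms); the component amplitude
#' is the peak-to-peak difference value(P100) - value(N75), which is
#' invariant to any constant baseline. A component is flagged unmeasurable
#' when the P100 maximum sits on a window edge (no interior local maximum)
#' or its window is empty; an ordering violation after detection is also
#' flagged.
#'
#' @param waveform Averaged waveform (microvolts).
#' @param sweep_rate Sampling rate of the sweep in Hz.
#' @param windows Search windows as from [vep_windows()].
#' @param trial Trial index for bookkeeping.
#' @return Object of class `vep_components`: latencies `n75`, `p100`,
#'   `n135` (ms), `amplitude` (microvolts), `trial`, `measurable`, `flags`.
#' @export
detect_components <- function(waveform, sweep_rate,
                              windows = vep_windows(), trial = NA_integer_) {
  t_ms <- (seq_along(waveform) - 1) / sweep_rate * 1000
  if (max(t_ms) < 250)
    stop("waveform must cover at least 250 ms post-reversal")
  flags <- character(0)

  win_idx <- function(w, extra = TRUE) which(t_ms >= w[1] & t_ms <= w[2])
  ip <- win_idx(windows$p100)
  p100_i <- ip[which.max(waveform[ip])]
  if (p100_i == ip[1] || p100_i == ip[length(ip)])
    flags <- c(flags, "p100_no_local_maximum")

  in75 <- intersect(win_idx(windows$n75), which(t_ms < t_ms[p100_i]))
  in135 <- intersect(win_idx(windows$n135), which(t_ms > t_ms[p100_i]))
  if (length(in75) == 0) flags <- c(flags, "n75_window_empty")
  if (length(in135) == 0) flags <- c(flags, "n135_window_empty")
  measurable <- length(flags) == 0
  n75_i <- if (length(in75)) in75[which.min(waveform[in75])] else NA_integer_
  n135_i <- if (length(in135)) in135[which.min(waveform[in135])] else NA_integer_

  lat <- c(n75 = if (is.na(n75_i)) NA_real_ else t_ms[n75_i],
           p100 = t_ms[p100_i],
           n135 = if (is.na(n135_i)) NA_real_ else t_ms[n135_i])
  if (measurable && !(lat["n75"] < lat["p100"] && lat["p100"] < lat["n135"])) {
    flags <- c(flags, "ordering_violation")
    measurable <- FALSE
  }
  amp <- if (is.na(n75_i)) NA_real_ else waveform[p100_i] - waveform[n75_i]
  structure(list(n75 = unname(lat["n75"]), p100 = unname(lat["p100"]),
                 n135 = unname(lat["n135"]), amplitude = amp,
                 trial = trial, measurable = measurable, flags = flags),
            class = "vep_components")
}

#' Summarize three trials of one stimulus
#'
#' Ranks the trials by P100 latency (fastest / medium / slowest; ties
#' broken by trial index), averages latency and amplitude over the three
#' responses, and attaches the log10-transformed means used by the
#' statistics layer.
#'
#' @param components List of three `vep_components`.
#' @return Object of class `vep_stimulus_summary`: `mean_latency_ms`,
#'   `mean_amplitude_uv`, `log10_latency`, `log10_amplitude`, `ranking`
#'   (trial indices fastest to slowest), `complete`.
#' @export
summarize_stimulus <- function(components) {
  stopifnot(is.list(components),
            all(vapply(components, inherits, NA, "vep_components")))
  complete <- length(components) == 3 &&
    all(vapply(components, `[[`, NA, "measurable"))
  lat <- vapply(components, `[[`, 0, "p100")
  amp <- vapply(components, `[[`, 0, "amplitude")
  ranking <- order(lat)                    # stable: ties keep trial order
  structure(list(mean_latency_ms = mean(lat),
                 mean_amplitude_uv = mean(amp),
                 log10_latency = log10(mean(lat)),
                 log10_amplitude = if (mean(amp) > 0) log10(mean(amp))
                                   else NA_real_,
                 ranking = ranking,
                 per_trial_latency = lat[ranking],
                 complete = complete),
            class = "vep_stimulus_summary")
}
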