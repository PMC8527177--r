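#' Default pipeline configuration
#'
#' A small end-to-end demonstration study: a handful of subjects, short
#' EEG task blocks, the four-pattern VEP session and a crossover
#' behavioral table. All sizes are deliberately modest; scale up through
#' the config for serious simulation work.
#'
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    n_subjects = 6,
    eeg = list(
      duration_s = 70,
      band_fractions = c(theta = 0.20, alpha = 0.25, low_beta = 0.15,
                         high_beta = 0.12, gamma = 0.10),
      artifact_rate = 2,
      tasks = data.frame(label = c("task_a", "task_b", "task_c"),
                         start_s = c(5, 30, 50),
                         end_s = c(25, 45, 68))),
    vep = list(noise_sd = 2, sweeps_per_trial = 10),
    behavioral = list(n_per_group = c(27, 26), rho = 0.5,
                      f_interaction = 0.17),
    power = list(n = 53, g = 2, m = 3, alpha = 0.05, rho = 0.5,
                 target_power = 0.80))
}

#' Run the full synthetic study pipeline
#'
#' simulate -> spectral -> STMLI -> VEP -> statistics, writing every
#' stage's table under `out_dir`. All randomness derives from `seed`, so
#' a given (config, seed) pair reproduces byte-identical numeric outputs.
#'
#' @param config Nested list as from [default_pipeline_config()], or a
#'   path to a YAML file with the same structure (the `tasks` entry may be
#'   a list of `label`/`start_s`/`end_s` records).
#' @param seed Root integer seed.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the main result objects and file paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1L,
                         out_dir = tempfile("svtephys_run_")) {
  if (is.character(config)) config <- .load_config(config)
  base <- default_pipeline_config()
  if (!is.null(config$eeg$tasks)) base$eeg$tasks <- NULL
  cfg <- utils::modifyList(base, config)
  if (!is.data.frame(cfg$eeg$tasks)) cfg$eeg$tasks <-
      do.call(rbind, lapply(cfg$eeg$tasks, as.data.frame))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                            "\n", file = log_path, append = TRUE)
  logf("svtephys pipeline, seed", seed)

  # --- EEG -> STMLI per subject and task -------------------------------
  stmli_rows <- list()
  for (i in seq_len(cfg$n_subjects)) {
    truth <- eeg_ground_truth(band_fractions = cfg$eeg$band_fractions,
                              artifact_rate = cfg$eeg$artifact_rate,
                              markers = cfg$eeg$tasks,
                              seed = seed * 1000L + i)
    rec <- simulate_eeg(truth, cfg$eeg$duration_s)
    rec <- decontaminate(eeg_preprocess(rec))
    ts <- task_stmli(stmli_series(rec), cfg$eeg$tasks)
    ts$participant_id <- sprintf("P%03d", i)
    stmli_rows[[i]] <- ts
  }
  stmli_tab <- do.call(rbind, stmli_rows)[, c("participant_id", "task",
                                              "n_epochs_valid",
                                              "stmli_trimmed_mean")]
  utils::write.csv(stmli_tab, file.path(out_dir, "stmli.csv"),
                   row.names = FALSE)
  logf("STMLI table:", nrow(stmli_tab), "rows")

  # --- VEP per subject and stimulus ------------------------------------
  schedule <- plan_session()
  utils::write.csv(schedule$blocks, file.path(out_dir, "session_plan.csv"),
                   row.names = FALSE)
  vep_rows <- list()
  for (i in seq_len(cfg$n_subjects)) {
    for (b in seq_len(nrow(schedule$blocks))) {
      kind <- if (grepl("checkerboard", schedule$blocks$pattern[b]))
        "checkerboard" else "grating"
      truth <- vep_ground_truth(noise_sd = cfg$vep$noise_sd,
                                sweeps_per_trial = cfg$vep$sweeps_per_trial,
                                stimulus = stimulus_spec(kind),
                                seed = seed * 10000L + i * 10L + b)
      tr <- simulate_vep_trials(truth)
      comps <- lapply(seq_along(tr$trials), function(k)
        detect_components(average_sweeps(tr$trials[[k]]),
                          truth$stimulus$sweep_rate, trial = k))
      sm <- summarize_stimulus(comps)
      vep_rows[[length(vep_rows) + 1]] <- data.frame(
        participant_id = sprintf("P%03d", i),
        stimulus = schedule$blocks$pattern[b],
        mean_latency_ms = sm$mean_latency_ms,
        mean_amplitude_uv = sm$mean_amplitude_uv,
        log10_latency = sm$log10_latency,
        log10_amplitude = sm$log10_amplitude,
        complete = sm$complete)
    }
  }
  vep_tab <- do.call(rbind, vep_rows)
  utils::write.csv(vep_tab, file.path(out_dir, "vep_summary.csv"),
                   row.names = FALSE)
  logf("VEP summary:", nrow(vep_tab), "rows")

  # --- behavioral table, screening and RM-MANOVA -----------------------
  btruth <- behavioral_ground_truth(
    n_per_group = cfg$behavioral$n_per_group,
    rho = cfg$behavioral$rho,
    f_interaction = cfg$behavioral$f_interaction,
    seed = seed + 77L)
  btab <- simulate_behavioral_table(btruth)
  write_measurement_table(btab, file.path(out_dir, "behavioral.csv"))
  scr <- screen_table(btab)
  utils::write.csv(scr$dv, file.path(out_dir, "screening.csv"),
                   row.names = FALSE)
  fit <- rm_manova(btab)
  mv <- do.call(rbind, Map(function(e, df) cbind(effect = e, df),
                           names(fit$multivariate), fit$multivariate))
  utils::write.csv(mv, file.path(out_dir, "manova.csv"), row.names = FALSE)
  logf("RM-MANOVA on behavioral table: primary =", fit$primary_statistic)

  # --- power planning ---------------------------------------------------
  pw <- cfg$power
  f_min <- solve_f(pw$n, pw$g, pw$m, pw$alpha, pw$rho, pw$target_power)
  power_txt <- file.path(out_dir, "power.txt")
  cat(sprintf(paste0(
    "A-priori power analysis (within-between interaction)\n",
    "N = %d, groups = %d, measurements = %d, alpha = %.2f, rho = %.2f\n",
    "target power = %.2f -> minimal detectable f = %.4f\n"),
    pw$n, pw$g, pw$m, pw$alpha, pw$rho, pw$target_power, f_min),
    file = power_txt)
  logf("power analysis: minimal f =", round(f_min, 4))

  summary_path <- file.path(out_dir, "summary.txt")
  cat(sprintf(paste0(
    "svtephys pipeline run (seed %d)\n",
    "subjects: %d\nSTMLI rows: %d\nVEP rows: %d\n",
    "behavioral N: %d\nprimary multivariate statistic: %s\n",
    "minimal detectable f at %.0f%% power: %.4f\n"),
    seed, cfg$n_subjects, nrow(stmli_tab), nrow(vep_tab),
    sum(cfg$behavioral$n_per_group), fit$primary_statistic,
    100 * pw$target_power, f_min), file = summary_path)

  invisible(list(out_dir = out_dir, stmli = stmli_tab, vep = vep_tab,
                 behavioral = btab, screening = scr, manova = fit,
                 f_min = f_min))
}

.load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
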