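#' Plan a VEP stimulus session
#'
#' Computes per-pattern and whole-sequence stimulus time for an ordered
#' block schedule. The default schedule is the four-pattern protocol:
#' 2-degree checkerboard, 0.25 cpd grating, 1-degree checkerboard,
#' 0.5 cpd grating, each presented 3 times for 20 s (240 s of stimulus
#' time in total). Inter-trial breaks are bookkeeping only and never enter
#' the stimulus-time totals.
#'
#' @param blocks Data frame with columns `pattern`, `presentations`,
#'   `presentation_s` and optionally `break_s`.
#' @return Object of class `session_schedule`: the blocks with a
#'   `pattern_time_s` column, plus `total_stimulus_s`.
#' @export
plan_session <- function(blocks = default_session_blocks()) {
  stopifnot(nrow(blocks) >= 1,
            all(c("pattern", "presentations", "presentation_s")
                %in% names(blocks)))
  if (any(blocks$presentations <= 0) || any(blocks$presentation_s <= 0))
    stop("presentations and presentation_s must be positive")
  blocks$pattern_time_s <- blocks$presentations * blocks$presentation_s
  structure(list(blocks = blocks,
                 total_stimulus_s = sum(blocks$pattern_time_s)),
            class = "session_schedule")
}

#' @rdname plan_session
#' @export
default_session_blocks <- function() {
  data.frame(
    pattern = c("checkerboard_2deg", "grating_0.25cpd",
                "checkerboard_1deg", "grating_0.5cpd"),
    presentations = 3L, presentation_s = 20, break_s = 3)
}

#' Grating geometry on the display
#'
#' Number of full cycles a sinusoidal grating spans on the display
#' (round(spatial frequency x extent)) and the physical half-cycle width
#' in degrees (1 / (2 x frequency)); at the protocol's 15.92 degree
#' display, 0.25 and 0.5 cpd gratings span 4 and 8 cycles and their
#' half-cycles match the 2- and 1-degree check sizes.
#'
#' @param spatial_freq Spatial frequency in cycles/degree.
#' @param extent_deg Display extent in degrees.
#' @return List with `cycles` and `half_cycle_deg`.
#' @export
grating_cycles <- function(spatial_freq, extent_deg = 15.92) {
  stopifnot(spatial_freq > 0, extent_deg > 0)
  list(cycles = round(spatial_freq * extent_deg),
       half_cycle_deg = 1 / (2 * spatial_freq))
}
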