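# Cyclic desired-motion generators.
#
# Five motions: FE30 (flexion-extension, +/-30 deg), RUD10 (radioulnar
# deviation, +/-10 deg), DTM (dart thrower's motion, a straight oblique
# segment from 20 deg extension + 15 deg radial deviation to 20 deg flexion
# + 15 deg ulnar deviation), and circumduction in both directions (an
# axis-aligned ellipse, 30 deg FE semi-axis by 10 deg RUD semi-axis,
# traversed clockwise: flexion -> ulnar -> extension -> radial, or
# anticlockwise: flexion -> radial -> extension -> ulnar).

#' Known motion names
#' @return Character vector of the five cyclic motions.
#' @export
motion_names <- function() c("FE30", "RUD10", "DTM", "CCD_CW", "CCD_ACW")

#' Cyclic desired-motion specification
#'
#' @param name one of [motion_names()].
#' @param period cycle period in seconds (default 4 s; the in-vitro protocol
#'   does not pin the speed, so it is a parameter).
#' @param n_cycles number of cycles (default 5).
#' @param amplitude_scale scalar multiplying all amplitudes (default 1; 0
#'   gives a constant neutral series).
#' @return An object of class `trajectory_spec`.
#' @examples
#' trajectory_spec("DTM", n_cycles = 2)
#' @export
trajectory_spec <- function(name, period = 4, n_cycles = 5, amplitude_scale = 1) {
  name <- match.arg(toupper(name), motion_names())
  if (!is.finite(period) || period <= 0) stop("trajectory_spec: period must be > 0")
  if (n_cycles < 1) stop("trajectory_spec: n_cycles must be >= 1")
  if (!is.finite(amplitude_scale) || amplitude_scale < 0)
    stop("trajectory_spec: amplitude_scale must be >= 0")
  structure(list(name = name, period = period, n_cycles = as.integer(n_cycles),
                 amplitude_scale = amplitude_scale),
            class = "trajectory_spec")
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat(sprintf("<trajectory_spec> %s: %d cycle(s) of %g s (amplitude scale %g)\n",
              x$name, x$n_cycles, x$period, x$amplitude_scale))
  invisible(x)
}

# Desired angles at phase ph (radians within a cycle, 0 at cycle start).
# Phase convention: each cycle starts at FE = 0 moving toward flexion
# (FE30, both circumductions), toward ulnar deviation (RUD10), or toward the
# extension-radial corner (DTM).
trajectory_angles <- function(name, ph, scale = 1) {
  switch(name,
         FE30 = list(fe = 30 * scale * sin(ph), rud = 0 * ph),
         RUD10 = list(fe = 0 * ph, rud = 10 * scale * sin(ph)),
         DTM = list(fe = -20 * scale * sin(ph), rud = -15 * scale * sin(ph)),
         # ellipse corners in temporal order: CW radial(-10) start ->
         # flexion -> ulnar -> extension; ACW ulnar start -> flexion ->
         # radial -> extension
         CCD_CW = list(fe = 30 * scale * sin(ph), rud = -10 * scale * cos(ph)),
         CCD_ACW = list(fe = 30 * scale * sin(ph), rud = 10 * scale * cos(ph)),
         stop("unknown motion name: ", name))
}

#' Generate a sampled desired trajectory
#'
#' Sinusoidal per-axis waveforms hitting each motion's extrema exactly once
#' per cycle. DTM is a straight segment in (FE, RUD) space traversed
#' sinusoidally; the circumductions are the same axis-aligned ellipse
#' traversed at constant phase rate in opposite directions.
#'
#' @param spec a [trajectory_spec()].
#' @param sample_rate samples per second (>= 50 Hz, default 100).
#' @return Data frame with columns `time_s`, `desired_fe_deg`,
#'   `desired_rud_deg`, `desired_dfe_dps`, `desired_drud_dps` (angular
#'   velocities in deg/s) and `cycle` (1-based cycle index).
#' @examples
#' tr <- generate_trajectory(trajectory_spec("FE30", n_cycles = 1))
#' range(tr$desired_fe_deg)
#' @export
generate_trajectory <- function(spec, sample_rate = 100) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (sample_rate < 50) stop("generate_trajectory: sample_rate must be >= 50 Hz")
  tt <- seq(0, spec$n_cycles * spec$period, by = 1 / sample_rate)
  w <- 2 * pi / spec$period
  a <- trajectory_angles(spec$name, w * tt, spec$amplitude_scale)
  # analytic velocities from a small central difference of the closed form
  h <- 1e-6
  ap <- trajectory_angles(spec$name, w * (tt + h), spec$amplitude_scale)
  am <- trajectory_angles(spec$name, w * (tt - h), spec$amplitude_scale)
  data.frame(time_s = tt,
             desired_fe_deg = a$fe, desired_rud_deg = a$rud,
             desired_dfe_dps = (ap$fe - am$fe) / (2 * h),
             desired_drud_dps = (ap$rud - am$rud) / (2 * h),
             cycle = pmin(floor(tt / spec$period) + 1L, spec$n_cycles))
}
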