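# Tendon excursion method: passive sweeps and moment-arm estimation.

#' Passive sweep of one wrist axis under constant tendon preload
#'
#' Quasi-statically moves the named axis across `+/- range` degrees while the
#' other axis is held at zero, with every tendon held at a constant preload
#' so that no tendon unloads, and records the tendon excursions the plant
#' produces at each sampled posture. This is the passive-motion protocol run
#' before every active simulation, from which specimen-specific moment arms
#' are estimated.
#'
#' @param specimen a [specimen_model()].
#' @param axis `"FE"` or `"RUD"`: the axis to sweep.
#' @param range sweep half-amplitude in degrees; must stay within the
#'   anatomical stops.
#' @param preload constant tendon load in newtons applied to every tendon
#'   (default 10 N); must be strictly positive or the tendons would unload.
#' @param n_samples number of postures sampled across the sweep (default 200).
#' @return An object of class `passive_sweep_record`: a list with `angles`
#'   (data frame of `theta_fe`, `theta_rud` in degrees), `excursions`
#'   (n x 6 matrix, mm), `forces` (n x 6 matrix, N, constant at `preload`),
#'   `axis` and `preload`.
#' @examples
#' sw <- passive_sweep(default_specimen(), "FE", range = 40)
#' range(sw$forces)   # every tendon at 10 N throughout
#' @export
passive_sweep <- function(specimen, axis = c("FE", "RUD"), range = 40,
                          preload = 10, n_samples = 200) {
  axis <- match.arg(axis)
  if (!is.finite(preload) || preload <= 0)
    stop("passive_sweep: preload must be > 0 N (tendons would unload)")
  stop_lim <- if (axis == "FE") FE_STOP else RUD_STOP
  if (!is.finite(range) || range < 0 || range > stop_lim)
    stop("passive_sweep: range must lie within the anatomical stops")
  if (n_samples < 2) stop("passive_sweep: need at least 2 samples")

  theta <- seq(-range, range, length.out = n_samples)
  fe <- if (axis == "FE") theta else numeric(n_samples)
  rud <- if (axis == "RUD") theta else numeric(n_samples)
  exc <- t(vapply(seq_len(n_samples), function(i) {
    tendon_excursions(wrist_state(fe[i], rud[i]), specimen$muscles)
  }, numeric(6)))
  colnames(exc) <- specimen$muscles$names
  forces <- matrix(preload, n_samples, 6,
                   dimnames = list(NULL, specimen$muscles$names))
  structure(list(angles = data.frame(theta_fe = fe, theta_rud = rud),
                 excursions = exc, forces = forces,
                 axis = axis, preload = preload),
            class = "passive_sweep_record")
}

#' @export
print.passive_sweep_record <- function(x, ...) {
  cat(sprintf("<passive_sweep_record> %s axis, %d samples, %.2f to %.2f deg, preload %g N\n",
              x$axis, nrow(x$angles), min(x$angles[[tolower_axis(x$axis)]]),
              max(x$angles[[tolower_axis(x$axis)]]), x$preload))
  invisible(x)
}

tolower_axis <- function(axis) if (axis == "FE") "theta_fe" else "theta_rud"

#' Estimate moment arms from passive sweeps (tendon excursion method)
#'
#' For each muscle, the moment arm about an axis is minus the derivative of
#' its tendon excursion with respect to that joint angle. The mean moment
#' arm over the swept range is estimated as the least-squares slope of
#' excursion against angle (in radians), which for linear excursion-angle
#' data is the variance-minimising estimator of that mean. Row 1 (FE) comes
#' from the FE sweep only, row 2 (RUD) from the RUD sweep only.
#'
#' @param sweep_fe,sweep_rud [passive_sweep_record]s of the FE and RUD axes.
#' @return 2 x 6 moment-arm matrix in mm (rows `FE`, `RUD`).
#' @examples
#' sp <- default_specimen()
#' Rhat <- estimate_moment_arms(passive_sweep(sp, "FE", 40),
#'                              passive_sweep(sp, "RUD", 20))
#' max(abs(Rhat - sp$muscles$R))   # exact recovery for constant-arm plants
#' @export
estimate_moment_arms <- function(sweep_fe, sweep_rud) {
  row_fe <- sweep_slope(sweep_fe, "FE")
  row_rud <- sweep_slope(sweep_rud, "RUD")
  R <- rbind(FE = row_fe, RUD = row_rud)
  colnames(R) <- colnames(sweep_fe$excursions)
  R
}

sweep_slope <- function(sw, axis) {
  if (!inherits(sw, "passive_sweep_record"))
    stop("estimate_moment_arms: inputs must be passive_sweep_record objects")
  if (sw$axis != axis)
    stop(sprintf("estimate_moment_arms: expected a %s-axis sweep", axis))
  theta <- deg2rad(sw$angles[[tolower_axis(axis)]])
  if (length(theta) < 10)
    stop("estimate_moment_arms: need at least 10 samples per sweep")
  if (stats::var(theta) < 1e-12)
    stop("estimate_moment_arms: degenerate (constant-angle) sweep")
  dth <- theta - mean(theta)
  dex <- sweep(sw$excursions, 2, colMeans(sw$excursions), `-`)
  # arm = -cov(excursion, angle)/var(angle), per muscle
  -drop(crossprod(dex, dth)) / sum(dth^2)
}
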