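# Forward-dynamics wrist plant.
#
# Forearm frame: e1 distal along the forearm/third-metacarpal axis at neutral,
# e2 palmar (flexion direction), e3 ulnar. FE rotates about e3, RUD about e2;
# positive RUD (ulnar) takes e1 toward +e3. The hand-segment axis at
# (theta_fe, theta_rud) is
#   u = (cos(fe) cos(rud), sin(fe) cos(rud), sin(rud)).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

segment_axis <- function(theta_fe, theta_rud) {
  f <- deg2rad(theta_fe); r <- deg2rad(theta_rud)
  c(cos(f) * cos(r), sin(f) * cos(r), sin(r))
}

gravity_direction <- function(orientation) {
  switch(match_orientation(orientation),
         vertical_up = c(-1, 0, 0),          # hand above elbow: gravity proximal
         vertical_down = c(1, 0, 0),         # hand below elbow: gravity distal
         horizontal_palm_down = c(0, 1, 0))  # palm down: gravity palmar
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Gravitational moment of the hand segment about the wrist axes
#'
#' Rotates the hand centre-of-mass offset by the current wrist angles and
#' crosses it with the orientation-specific gravity force expressed in the
#' forearm frame. In the horizontal palm-down orientation at neutral the FE
#' moment equals `hand_mass * gravity_accel * com_distance` and acts in the
#' flexion direction (the extensors must counteract it); in either vertical
#' orientation the neutral wrist carries no gravitational moment and the
#' plant behaves as an (inverted, for vertical-up) pendulum away from
#' neutral.
#'
#' @param state a [wrist_state()] within the anatomical stops.
#' @param orientation one of [orientations()].
#' @param specimen a [specimen_model()].
#' @return Named numeric vector `c(FE =, RUD =)` of moments in N m;
#'   positive FE = flexion sense, positive RUD = ulnar sense.
#' @examples
#' sp <- default_specimen()
#' gravity_torque(wrist_state(0, 0), "horizontal_palm_down", sp)
#' @export
gravity_torque <- function(state, orientation, specimen) {
  validate_wrist_state(state)
  p <- specimen$com_distance * segment_axis(state$theta_fe, state$theta_rud)
  Fg <- specimen$hand_mass * specimen$gravity_accel * gravity_direction(orientation)
  tau <- cross3(p, Fg)
  # generalized torques: FE rotates about the fixed +e3 axis; the RUD axis
  # is carried by the FE rotation (positive ulnar rotation about
  # (sin fe, -cos fe, 0) after composing FE over RUD)
  f <- deg2rad(state$theta_fe)
  c(FE = tau[3], RUD = tau[1] * sin(f) - tau[2] * cos(f))
}

#' Joint torque produced by a set of tendon tensions
#'
#' Maps six non-negative muscle forces through the moment-arm matrix:
#' `tau = (R / 1000) %*% forces` (moment arms are stored in mm).
#'
#' @param forces six tendon tensions in newtons; tendons cannot push, so all
#'   must be non-negative.
#' @param muscles a [muscle_set()].
#' @return Named numeric vector `c(FE =, RUD =)` in N m.
#' @examples
#' muscle_torque(rep(10, 6), default_muscle_set())
#' @export
muscle_torque <- function(forces, muscles) {
  forces <- as.numeric(forces)
  if (length(forces) != 6 || !all(is.finite(forces)))
    stop("muscle_torque: forces must be six finite values")
  if (any(forces < 0))
    stop("muscle_torque: negative tendon force requested (tendons cannot push)")
  tau <- drop(muscles$R %*% forces) / 1000
  c(FE = tau[1], RUD = tau[2])
}

# Moment arms at a given state, honouring any angle-dependent slope.
effective_R <- function(muscles, state) {
  muscles$R + muscles$arm_slope * rbind(rep(state$theta_fe, 6),
                                        rep(state$theta_rud, 6))
}

#' Advance the wrist plant by one integration step
#'
#' Per-axis rigid-body dynamics
#' `I * theta_dd = tau_muscle + tau_gravity - k * theta - b * theta_dot`,
#' integrated by one fixed semi-implicit Euler step. Angles clamp inelastically
#' at the anatomical stops (+/-90 deg FE, +/-45 deg RUD) with zeroed velocity.
#'
#' @inheritParams gravity_torque
#' @param forces six tendon tensions in newtons, each within
#'   `[0, f_upper]` of the specimen's muscle set.
#' @param dt integration step in seconds, in (0, 0.01].
#' @return The new `wrist_state`.
#' @export
step_dynamics <- function(state, forces, orientation, specimen, dt = 0.001) {
  if (!is.numeric(dt) || dt <= 0 || dt > 0.01)
    stop("step_dynamics: dt must lie in (0, 0.01] s")
  forces <- as.numeric(forces)
  if (!all(is.finite(forces))) stop("step_dynamics: non-finite force")
  if (any(forces < -1e-9) || any(forces > specimen$muscles$f_upper + 1e-6))
    stop("step_dynamics: forces outside [0, f_upper]")
  validate_wrist_state(state)

  Reff <- effective_R(specimen$muscles, state)
  tau_m <- drop(Reff %*% forces) / 1000
  tau_g <- gravity_torque(state, orientation, specimen)
  k <- specimen$passive_stiffness; b <- specimen$passive_damping
  th <- c(state$theta_fe, state$theta_rud)
  om <- c(state$omega_fe, state$omega_rud)
  tau <- tau_m + tau_g - k * th - b * om
  acc <- rad2deg(tau / c(specimen$inertia_fe, specimen$inertia_rud))

  om <- om + dt * acc          # semi-implicit: velocity first
  th <- th + dt * om
  stops <- c(FE_STOP, RUD_STOP)
  hit <- th > stops | th < -stops
  th <- pmin(pmax(th, -stops), stops)
  om[hit] <- 0

  s <- list(theta_fe = unname(th[1]), theta_rud = unname(th[2]),
            omega_fe = unname(om[1]), omega_rud = unname(om[2]))
  class(s) <- "wrist_state"
  s
}

#' Tendon excursions relative to a neutral reference posture
#'
#' For each muscle, the integral of minus its moment arm over the angle
#' change from `neutral` to `state` (radians), in mm:
#' `excursion_i = -R_i . (theta - neutral)` for constant-arm plants.
#' Positive excursion means the tendon pays out (the muscle-tendon path
#' lengthens); the moment arm is recovered as minus the derivative of
#' excursion with respect to angle, which is what the tendon excursion
#' method exploits.
#'
#' @inheritParams gravity_torque
#' @param muscles a [muscle_set()].
#' @param neutral reference [wrist_state()] (default: neutral posture).
#' @return Named numeric vector of six excursions in mm.
#' @export
tendon_excursions <- function(state, muscles, neutral = wrist_state()) {
  validate_wrist_state(state); validate_wrist_state(neutral)
  th <- c(state$theta_fe, state$theta_rud)
  th0 <- c(neutral$theta_fe, neutral$theta_rud)
  # exact integral of -(R + slope*theta) d(theta_rad) between the postures
  lin <- muscles$R * deg2rad(th - th0)
  quad <- muscles$arm_slope * deg2rad(th^2 - th0^2) / 2
  exc <- -colSums(lin + quad)
  stats::setNames(exc, muscles$names)
}
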