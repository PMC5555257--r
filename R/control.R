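# Hybrid and cascade control of the tendon-driven wrist.

#' Hybrid control configuration
#'
#' Hybrid control drives joint kinematics with position feedback while force
#' feedback keeps every muscle within its physiologic bounds. Joint-angle
#' error is mapped into per-tendon excursion error through the moment-arm
#' matrix, a PID acts per tendon, and the resulting force commands are
#' expressed as offsets from a co-contraction baseline, then clamped into
#' `[f_lower, f_upper]`.
#'
#' Default gains were tuned once on the default specimen (they are tuned
#' values, not measured ones) and are expressed per mm of tendon excursion
#' error: `kp` in N/mm, `ki` in N/(mm s), `kd` in N s/mm.
#'
#' @param kp,ki,kd PID gains per tendon (scalar or length 6).
#' @param baseline co-contraction baseline force, N (default 10). The
#'   baseline force pattern applied to the tendons is this level projected
#'   onto the null space of the moment-arm matrix, so resting co-contraction
#'   produces no net joint torque.
#' @param t_track anti-windup tracking time constant, s (default 0.1):
#'   back-calculation pulls the integrator toward the clamp whenever a force
#'   command saturates.
#' @param control_period controller sampling period, s (default 0.005).
#' @return An object of class `hybrid_config`.
#' @export
hybrid_config <- function(kp = 15, ki = 60, kd = 0.3, baseline = 10,
                          t_track = 0.1, control_period = 0.005) {
  g <- c(kp, ki, kd, baseline, t_track, control_period)
  if (!all(is.finite(g)) || any(c(kp, ki, kd) < 0) || control_period <= 0 ||
      t_track <= 0)
    stop("hybrid_config: gains must be finite and non-negative, periods > 0")
  structure(list(kp = rep_len(kp, 6), ki = rep_len(ki, 6), kd = rep_len(kd, 6),
                 baseline = baseline, t_track = t_track,
                 control_period = control_period),
            class = "hybrid_config")
}

#' Cascade control configuration
#'
#' Cascade control nests force control within position control: an outer
#' PID on the joint angles (with optional gravity feedforward) commands a
#' joint torque, a quadratic optimisation distributes that torque to target
#' tendon tensions minimising the sum of squared muscle stresses under
#' bounds on each force and on the muscle impedance rho = sum(F), and an
#' inner first-order force loop drives the measured tensions toward the
#' targets.
#'
#' @param kp,ki,kd outer position-loop gains per joint axis (scalar or
#'   length 2), in N m/deg, N m/(deg s) and N m s/deg.
#' @param tau_inner inner force-loop time constant, s.
#' @param rho_min,rho_max muscle-impedance bounds, N (defaults 0 and 400 N,
#'   leaving the sum of forces effectively unconstrained).
#' @param gravity_feedforward logical: feed the modelled gravity moment
#'   forward to the torque command (default TRUE).
#' @param control_period inner-loop sampling period, s.
#' @param qp_period period at which the distribution QP re-solves, s
#'   (the outer loop runs slower than the inner loop).
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(kp = 0.08, ki = 0.6, kd = 0.003,
                           tau_inner = 0.01,
                           rho_min = 0, rho_max = 400,
                           gravity_feedforward = TRUE,
                           control_period = 0.005, qp_period = 0.01) {
  if (!all(is.finite(c(kp, ki, kd, tau_inner, rho_min, rho_max))))
    stop("cascade_config: non-finite parameter")
  if (rho_min < 0 || rho_min >= rho_max)
    stop("cascade_config: need 0 <= rho_min < rho_max")
  if (tau_inner <= 0 || control_period <= 0 || qp_period <= 0)
    stop("cascade_config: time constants and periods must be > 0")
  structure(list(kp = rep_len(kp, 2), ki = rep_len(ki, 2), kd = rep_len(kd, 2),
                 tau_inner = tau_inner, rho_min = rho_min, rho_max = rho_max,
                 gravity_feedforward = isTRUE(gravity_feedforward),
                 control_period = control_period, qp_period = qp_period),
            class = "cascade_config")
}

#' Fresh controller memory
#'
#' @param controller `"hybrid"` or `"cascade"`.
#' @return A list carrying integrator and inner-loop state, to be threaded
#'   through successive [hybrid_step()] / [cascade_step()] calls.
#' @export
controller_memory <- function(controller = c("hybrid", "cascade")) {
  controller <- match.arg(controller)
  if (controller == "hybrid") {
    list(integral = numeric(6))
  } else {
    list(integral = numeric(2), f_cmd = NULL, f_target = NULL, t_since_qp = Inf,
         infeasible = FALSE)
  }
}

joint_error <- function(desired, measured) {
  c(desired$theta_fe - measured$theta_fe,
    desired$theta_rud - measured$theta_rud)
}

joint_rate_error <- function(desired, measured) {
  c(desired$omega_fe - measured$omega_fe,
    desired$omega_rud - measured$omega_rud)
}

#' One hybrid-control update
#'
#' @param desired,measured desired and measured [wrist_state()]s; the
#'   measured state is what the controller sees (it may carry sensor noise).
#' @param measured_forces six measured tendon tensions, N.
#' @param muscles the [muscle_set()] the controller believes in (normally
#'   built from estimated moment arms).
#' @param cfg a [hybrid_config()].
#' @param memory controller memory from [controller_memory()] or a previous
#'   call.
#' @return List with `forces` (six commanded tensions, N, always within
#'   `[f_lower, f_upper]`) and updated `memory`.
#' @export
hybrid_step <- function(desired, measured, measured_forces, muscles, cfg, memory) {
  e <- deg2rad(joint_error(desired, measured))
  edot <- deg2rad(joint_rate_error(desired, measured))
  # per-tendon excursion-error signal (mm): positive where more force is needed
  s <- drop(crossprod(muscles$R, e))
  sdot <- drop(crossprod(muscles$R, edot))
  if (is.null(memory$baseline_vec))
    memory$baseline_vec <- cocontraction_baseline(muscles, cfg$baseline)
  raw <- memory$baseline_vec + cfg$kp * s + cfg$ki * memory$integral + cfg$kd * sdot
  f <- pmin(pmax(raw, muscles$f_lower), muscles$f_upper)
  # tendon-space integration with back-calculation anti-windup: where the
  # clamp is active the integrator is pulled back toward the bound, so the
  # integral state cannot wander through the null space of the moment-arm
  # matrix and strand co-contraction on saturated muscles
  aw <- if (any(cfg$ki > 0)) (f - raw) / (cfg$ki * cfg$t_track) else 0
  memory$integral <- memory$integral + (s + aw) * cfg$control_period
  list(forces = stats::setNames(f, muscles$names), memory = memory)
}

#' One cascade-control update
#'
#' @inheritParams hybrid_step
#' @param specimen the [specimen_model()] used for the gravity feedforward
#'   term.
#' @param orientation hand orientation, one of [orientations()].
#' @param cfg a [cascade_config()].
#' @return List with `forces` (six commanded tensions, N; always within
#'   bounds and with `rho_min <= sum(forces) <= rho_max`), `feasible`
#'   (did the last distribution solve meet its torque target), and updated
#'   `memory`.
#' @export
cascade_step <- function(desired, measured, measured_forces, muscles,
                         specimen, orientation, cfg, memory) {
  e <- joint_error(desired, measured)
  edot <- joint_rate_error(desired, measured)
  memory$integral <- memory$integral + e * cfg$control_period
  tau <- cfg$kp * e + cfg$ki * memory$integral + cfg$kd * edot
  if (cfg$gravity_feedforward)
    tau <- tau - gravity_torque(measured, orientation, specimen)

  memory$t_since_qp <- memory$t_since_qp + cfg$control_period
  if (is.null(memory$f_target) || memory$t_since_qp >= cfg$qp_period - 1e-12) {
    pr <- force_distribution_problem(tau, muscles$R, muscles$pcsa,
                                     muscles$f_lower, muscles$f_upper,
                                     cfg$rho_min, cfg$rho_max)
    sol <- solve_force_distribution(pr)
    memory$f_target <- sol$forces
    memory$infeasible <- !sol$feasible
    memory$t_since_qp <- 0
  }
  if (is.null(memory$f_cmd)) memory$f_cmd <- memory$f_target

  alpha <- min(1, cfg$control_period / cfg$tau_inner)
  f <- memory$f_cmd + alpha * (memory$f_target - measured_forces)
  f <- pmin(pmax(f, muscles$f_lower), muscles$f_upper)
  f <- project_rho(f, muscles$f_lower, muscles$f_upper, cfg$rho_min, cfg$rho_max)
  memory$f_cmd <- f
  list(forces = stats::setNames(f, muscles$names),
       feasible = !memory$infeasible, memory = memory)
}

# Tonic co-contraction vector: the level-`baseline` force pattern projected
# onto the null space of the moment-arm matrix, so that the resting
# co-contraction produces no net joint torque, then kept within bounds.
cocontraction_baseline <- function(muscles, baseline) {
  R <- muscles$R
  b0 <- rep(baseline, ncol(R))
  b <- b0 - crossprod(R, solve(tcrossprod(R), R %*% b0))
  # clip and rescale so the mean stays at the requested level
  b <- pmax(drop(b), muscles$f_lower)
  pmin(b * baseline / mean(b), muscles$f_upper)
}

# Scale forces (relative to the bound they would violate) so that
# rho_min <= sum(f) <= rho_max, preserving elementwise bounds.
project_rho <- function(f, lower, upper, rho_min, rho_max) {
  s <- sum(f)
  if (s > rho_max) {
    slack <- f - lower
    excess <- s - rho_max
    if (sum(slack) > 0) f <- f - slack * (excess / sum(slack))
  } else if (s < rho_min) {
    head <- upper - f
    deficit <- rho_min - s
    if (sum(head) > 0) f <- f + head * (deficit / sum(head))
  }
  f
}
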