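# Closed-loop simulation: controller + plant, standing in for one
# instrumented specimen run.

# Closed-form desired state (angles deg, velocities deg/s) at time t.
trajectory_state <- function(name, t, period, scale = 1) {
  w <- 2 * pi / period
  ph <- w * t
  sn <- sin(ph); cs <- cos(ph)
  switch(name,
    FE30 = list(fe = 30 * scale * sn, rud = 0,
                dfe = 30 * scale * w * cs, drud = 0),
    RUD10 = list(fe = 0, rud = 10 * scale * sn,
                 dfe = 0, drud = 10 * scale * w * cs),
    DTM = list(fe = -20 * scale * sn, rud = -15 * scale * sn,
               dfe = -20 * scale * w * cs, drud = -15 * scale * w * cs),
    CCD_CW = list(fe = 30 * scale * sn, rud = -10 * scale * cs,
                  dfe = 30 * scale * w * cs, drud = 10 * scale * w * sn),
    CCD_ACW = list(fe = 30 * scale * sn, rud = 10 * scale * cs,
                   dfe = 30 * scale * w * cs, drud = -10 * scale * w * sn),
    stop("unknown motion name: ", name))
}

#' Measurement-noise settings
#'
#' Zero-mean Gaussian noise applied to the signals the controller sees,
#' emulating optical motion capture (angles) and load cells (forces). Noise
#' never perturbs the plant itself, only the controller inputs. Set both
#' to zero for noise-free runs.
#'
#' @param angle_sd standard deviation of measured-angle noise, degrees
#'   (default 0.1).
#' @param force_sd standard deviation of measured-force noise, N
#'   (default 0.2).
#' @return A list with class `noise_config`.
#' @export
noise_config <- function(angle_sd = 0.1, force_sd = 0.2) {
  if (angle_sd < 0 || force_sd < 0) stop("noise_config: SDs must be >= 0")
  structure(list(angle_sd = angle_sd, force_sd = force_sd),
            class = "noise_config")
}

#' Run one closed-loop simulation
#'
#' Drives the plant through a cyclic desired motion with the chosen
#' controller in the chosen hand orientation. The controller runs at its
#' configured period and commands tendon tensions; the plant integrates at a
#' finer fixed step between controller updates. A settle period holding the
#' initial posture precedes the recorded cycles, mirroring how a specimen is
#' brought to the start posture before cycling begins.
#'
#' @param specimen the true [specimen_model()] being "mounted".
#' @param trajectory a [trajectory_spec()].
#' @param controller `"hybrid"` or `"cascade"`.
#' @param orientation one of [orientations()].
#' @param cfg a [hybrid_config()] or [cascade_config()] matching
#'   `controller`; default configuration if `NULL`.
#' @param muscles_ctrl the [muscle_set()] the controller uses — normally the
#'   specimen's muscle set with moment arms replaced by the
#'   tendon-excursion estimates. Defaults to the specimen's true muscles.
#' @param noise a [noise_config()].
#' @param seed integer seed for the measurement noise (`NULL`: do not touch
#'   the RNG).
#' @param sample_rate recording rate, Hz.
#' @param dt plant integration step, s.
#' @param settle_time seconds of unrecorded hold at the start posture.
#' @param initial_state starting [wrist_state()]; defaults to the
#'   trajectory's start posture at rest.
#' @param specimen_id label stored in the record metadata.
#' @return A `simulation_record`: a data frame with columns `time_s`,
#'   `theta_fe_deg`, `theta_rud_deg`, `desired_fe_deg`, `desired_rud_deg`,
#'   `F_FCR_N` ... `F_APL_N` and `cycle`, with metadata (motion, controller,
#'   orientation, specimen id, period, seed, instability flag) in
#'   attributes; see [record_meta()].
#' @export
run_simulation <- function(specimen, trajectory, controller = c("hybrid", "cascade"),
                           orientation = "vertical_up", cfg = NULL,
                           muscles_ctrl = NULL, noise = noise_config(),
                           seed = NULL, sample_rate = 100, dt = 0.001,
                           settle_time = 1, initial_state = NULL,
                           specimen_id = "S1") {
  controller <- match.arg(controller)
  orientation <- match_orientation(orientation)
  stopifnot(inherits(specimen, "specimen_model"), inherits(trajectory, "trajectory_spec"))
  if (is.null(cfg)) cfg <- if (controller == "hybrid") hybrid_config() else cascade_config()
  if (is.null(muscles_ctrl)) muscles_ctrl <- specimen$muscles
  if (!is.null(seed)) set.seed(as.integer(seed))

  dtc <- cfg$control_period
  spc <- round(dtc / dt)
  if (abs(spc * dt - dtc) > 1e-9)
    stop("run_simulation: control_period must be an integer multiple of dt")
  rec_every <- round(1 / sample_rate / dtc)
  if (abs(rec_every * dtc - 1 / sample_rate) > 1e-9)
    stop("run_simulation: 1/sample_rate must be an integer multiple of control_period")

  period <- trajectory$period; ncyc <- trajectory$n_cycles
  n_settle <- round(settle_time / dtc)
  n_run <- round(ncyc * period / dtc)
  n_rec <- floor(n_run / rec_every) + 1

  out_t <- numeric(n_rec); out_th <- matrix(0, n_rec, 2)
  out_des <- matrix(0, n_rec, 2); out_F <- matrix(0, n_rec, 6)

  des0 <- trajectory_state(trajectory$name, 0, period, trajectory$amplitude_scale)
  if (is.null(initial_state)) {
    th <- c(des0$fe, des0$rud); om <- c(0, 0)
  } else {
    validate_wrist_state(initial_state)
    th <- c(initial_state$theta_fe, initial_state$theta_rud)
    om <- c(initial_state$omega_fe, initial_state$omega_rud)
  }
  mem <- controller_memory(controller)
  Rtrue <- specimen$muscles$R
  k <- specimen$passive_stiffness; b <- specimen$passive_damping
  inv_I <- 1 / c(specimen$inertia_fe, specimen$inertia_rud)
  mgd <- specimen$hand_mass * specimen$gravity_accel * specimen$com_distance
  stops <- c(FE_STOP, RUD_STOP)
  r2d <- 180 / pi
  forces <- pmin(pmax(rep(10, 6), specimen$muscles$f_lower), specimen$muscles$f_upper)
  stop_hits <- 0L; i_rec <- 0L; infeasible_any <- FALSE

  for (step in seq_len(n_settle + n_run + 1) - 1L) {
    running <- step >= n_settle
    t_run <- (step - n_settle) * dtc
    des <- if (running)
      trajectory_state(trajectory$name, t_run, period, trajectory$amplitude_scale)
    else list(fe = des0$fe, rud = des0$rud, dfe = 0, drud = 0)

    # what the controller sees
    th_meas <- th + if (noise$angle_sd > 0) stats::rnorm(2, 0, noise$angle_sd) else 0
    f_meas <- forces + if (noise$force_sd > 0) stats::rnorm(6, 0, noise$force_sd) else 0
    desired <- structure(list(theta_fe = des$fe, theta_rud = des$rud,
                              omega_fe = des$dfe, omega_rud = des$drud),
                         class = "wrist_state")
    measured <- structure(list(theta_fe = th_meas[1], theta_rud = th_meas[2],
                               omega_fe = om[1], omega_rud = om[2]),
                          class = "wrist_state")
    if (controller == "hybrid") {
      upd <- hybrid_step(desired, measured, f_meas, muscles_ctrl, cfg, mem)
    } else {
      upd <- cascade_step(desired, measured, f_meas, muscles_ctrl, specimen,
                          orientation, cfg, mem)
      if (!isTRUE(upd$feasible)) infeasible_any <- TRUE
    }
    forces <- unname(upd$forces); mem <- upd$memory

    # record before integrating onward (state at the control instant)
    if (running && (step - n_settle) %% rec_every == 0 && i_rec < n_rec) {
      i_rec <- i_rec + 1L
      out_t[i_rec] <- t_run
      out_th[i_rec, ] <- th
      out_des[i_rec, ] <- c(des$fe, des$rud)
      out_F[i_rec, ] <- forces
      if (any(abs(th) >= stops - 1e-9)) stop_hits <- stop_hits + 1L
    }

    # plant substeps with the commanded forces held
    tau_m <- drop(Rtrue %*% forces) / 1000
    for (s in seq_len(spc)) {
      tau_g <- gravity_torque_fast(th, orientation, mgd)
      acc <- (tau_m + tau_g - k * th - b * om) * inv_I * r2d
      om <- om + dt * acc
      th <- th + dt * om
      hit <- th > stops | th < -stops
      if (any(hit)) { th <- pmin(pmax(th, -stops), stops); om[hit] <- 0 }
    }
  }

  nm <- specimen$muscles$names
  rec <- data.frame(time_s = out_t[seq_len(i_rec)],
                    theta_fe_deg = out_th[seq_len(i_rec), 1],
                    theta_rud_deg = out_th[seq_len(i_rec), 2],
                    desired_fe_deg = out_des[seq_len(i_rec), 1],
                    desired_rud_deg = out_des[seq_len(i_rec), 2])
  Fd <- as.data.frame(out_F[seq_len(i_rec), , drop = FALSE])
  names(Fd) <- paste0("F_", nm, "_N")
  rec <- cbind(rec, Fd)
  rec$cycle <- pmin(floor(rec$time_s / period) + 1L, ncyc)
  structure(rec,
            class = c("simulation_record", "data.frame"),
            meta = list(specimen_id = specimen_id, motion = trajectory$name,
                        controller = controller, orientation = orientation,
                        n_cycles = ncyc, period = period, seed = seed,
                        sample_rate = sample_rate,
                        flagged = (stop_hits / max(i_rec, 1)) > 0.10,
                        stop_fraction = stop_hits / max(i_rec, 1),
                        qp_infeasible = infeasible_any))
}

# gravity torque on plain numeric state, mgd = m*g*d precomputed
gravity_torque_fast <- function(th, orientation, mgd) {
  f <- th[1] * pi / 180; r <- th[2] * pi / 180
  switch(orientation,
         vertical_up = mgd * c(sin(f) * cos(r), cos(f) * sin(r)),
         vertical_down = -mgd * c(sin(f) * cos(r), cos(f) * sin(r)),
         horizontal_palm_down = mgd * c(cos(f) * cos(r), -sin(f) * sin(r)))
}

#' Metadata of a simulation record
#' @param record a `simulation_record`.
#' @return The metadata list (specimen id, motion, controller, orientation,
#'   cycle structure, seed, instability flag).
#' @export
record_meta <- function(record) attr(record, "meta")

#' @export
print.simulation_record <- function(x, ...) {
  m <- record_meta(x)
  cat(sprintf("<simulation_record> %s | %s control | %s | specimen %s\n",
              m$motion, m$controller, m$orientation, m$specimen_id))
  cat(sprintf("  %d samples, %d cycle(s) of %g s%s\n", nrow(x), m$n_cycles,
              m$period, if (isTRUE(m$flagged)) "  [FLAGGED: unstable]" else ""))
  invisible(x)
}
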