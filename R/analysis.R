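# Outcome metrics computed from simulation records.

force_columns <- function(record) grep("^F_.*_N$", names(record), value = TRUE)

muscle_of_column <- function(cols) sub("^F_(.*)_N$", "\\1", cols)

#' Mean absolute kinematic tracking error
#'
#' Per-axis mean of `|measured - desired|` over all samples of all cycles.
#' For the planar motions the moving axis is labelled in-plane and the
#' orthogonal axis out-of-plane; complex motions report both axes without a
#' planar label.
#'
#' @param record a `simulation_record`.
#' @return A list of class `kinematic_error` with `fe` and `rud` (mean
#'   absolute errors, degrees), and `in_plane` / `out_of_plane` for planar
#'   motions (`NA` otherwise).
#' @export
kinematic_error <- function(record) {
  if (nrow(record) == 0) stop("kinematic_error: empty record")
  fe <- mean(abs(record$theta_fe_deg - record$desired_fe_deg))
  rud <- mean(abs(record$theta_rud_deg - record$desired_rud_deg))
  motion <- record_meta(record)$motion
  ip <- switch(motion, FE30 = fe, RUD10 = rud, NA_real_)
  op <- switch(motion, FE30 = rud, RUD10 = fe, NA_real_)
  structure(list(fe = fe, rud = rud, in_plane = ip, out_of_plane = op,
                 motion = motion),
            class = "kinematic_error")
}

#' @export
print.kinematic_error <- function(x, ...) {
  cat(sprintf("<kinematic_error> %s: FE %.3f deg, RUD %.3f deg\n",
              x$motion, x$fe, x$rud))
  invisible(x)
}

#' Muscle forces at kinematic waypoints
#'
#' Evaluates the six muscle forces as a function of joint kinematics: at
#' every 10 degrees in FE and every 5 degrees in RUD within the motion's
#' range, separately for each passage direction (ascending/descending
#' crossings are distinct mechanical states because of hysteresis), for each
#' cycle. Forces are linearly interpolated at the crossing instant; a
#' waypoint a cycle never crosses is simply absent from the table.
#'
#' @param record a `simulation_record`.
#' @param fe_step,rud_step waypoint spacing in degrees (defaults 10 and 5).
#' @return Long-format data frame with columns `cycle`, `axis` (`"FE"` or
#'   `"RUD"`), `waypoint_deg`, `direction` (`"asc"`/`"desc"`), `muscle`,
#'   `force_N`.
#' @export
waypoint_forces <- function(record, fe_step = 10, rud_step = 5) {
  if (nrow(record) == 0) stop("waypoint_forces: empty record")
  fcols <- force_columns(record)
  out <- list()
  for (ax in c("FE", "RUD")) {
    ang <- if (ax == "FE") record$theta_fe_deg else record$theta_rud_deg
    step <- if (ax == "FE") fe_step else rud_step
    des <- if (ax == "FE") record$desired_fe_deg else record$desired_rud_deg
    span <- max(abs(des))
    if (span < step / 2) next       # axis essentially stationary
    wps <- seq(-floor(span / step) * step, floor(span / step) * step, by = step)
    for (cy in unique(record$cycle)) {
      idx <- which(record$cycle == cy)
      a <- ang[idx]
      for (w in wps) {
        d <- a - w
        cross <- which(d[-length(d)] * d[-1] <= 0 & d[-length(d)] != d[-1])
        if (length(cross) == 0) next
        for (j in cross) {
          i1 <- idx[j]; i2 <- idx[j + 1]
          frac <- (w - ang[i1]) / (ang[i2] - ang[i1])
          if (!is.finite(frac)) frac <- 0
          fw <- as.numeric(record[i1, fcols]) +
            frac * (as.numeric(record[i2, fcols]) - as.numeric(record[i1, fcols]))
          # a tangency at the desired extremum is one passage, not two
          dir <- if (abs(w) >= span - 1e-9) "ext"
                 else if (ang[i2] >= ang[i1]) "asc" else "desc"
          out[[length(out) + 1]] <- data.frame(
            cycle = cy, axis = ax, waypoint_deg = w,
            direction = dir,
            muscle = muscle_of_column(fcols), force_N = fw)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(cycle = integer(), axis = character(),
                      waypoint_deg = numeric(), direction = character(),
                      muscle = character(), force_N = numeric()))
  res <- do.call(rbind, out)
  # one crossing per cycle x waypoint x direction: keep the first if the
  # trajectory grazes a waypoint across adjacent samples
  res <- res[!duplicated(res[c("cycle", "axis", "waypoint_deg", "direction", "muscle")]), ]
  rownames(res) <- NULL
  res
}

#' Cycle-to-cycle repeatability of muscle forces
#'
#' Sample standard deviation of each muscle's force across cycles at each
#' waypoint (matched passage direction), then the mean over waypoints as the
#' specimen-level summary. Cohort-level repeatability is the mean of the
#' specimen-level values across specimens.
#'
#' @param wp a waypoint table from [waypoint_forces()] (one record).
#' @return List with `per_waypoint` (data frame: axis, waypoint_deg,
#'   direction, muscle, sd_N, n_cycles) and `specimen_mean_sd` (scalar, N).
#' @export
repeatability <- function(wp) {
  if (nrow(wp) == 0) stop("repeatability: empty waypoint table")
  key <- interaction(wp$axis, wp$waypoint_deg, wp$direction, wp$muscle, drop = TRUE)
  ncyc <- tapply(wp$cycle, key, function(x) length(unique(x)))
  if (max(ncyc) < 2)
    stop("repeatability: need at least 2 cycles")
  sds <- tapply(wp$force_N, key, stats::sd)
  info <- wp[!duplicated(key), c("axis", "waypoint_deg", "direction", "muscle")]
  info <- info[match(names(sds), as.character(key[!duplicated(key)])), ]
  per <- cbind(info, sd_N = as.numeric(sds), n_cycles = as.integer(ncyc))
  per <- per[per$n_cycles >= 2, ]
  rownames(per) <- NULL
  list(per_waypoint = per, specimen_mean_sd = mean(per$sd_N))
}

#' Flexor- and extensor-group force time series
#'
#' Flexor group = FCR + FCU + APL; extensor group = ECRL + ECRB + ECU,
#' per sample.
#'
#' @param record a `simulation_record`.
#' @return Data frame `time_s`, `flexor_N`, `extensor_N`.
#' @export
group_forces <- function(record) {
  data.frame(time_s = record$time_s,
             flexor_N = record$F_FCR_N + record$F_FCU_N + record$F_APL_N,
             extensor_N = record$F_ECRL_N + record$F_ECRB_N + record$F_ECU_N)
}

#' Per-muscle peak and mean force over a motion
#'
#' The peak is the mean across cycles of the per-cycle maximum (robust to a
#' single outlying sample); the mean is the time-average over all recorded
#' samples.
#'
#' @param record a `simulation_record`.
#' @return Data frame with `muscle`, `peak_N`, `mean_N`.
#' @export
peak_mean_forces <- function(record) {
  fcols <- force_columns(record)
  peaks <- sapply(fcols, function(cl)
    mean(tapply(record[[cl]], record$cycle, max)))
  means <- sapply(fcols, function(cl) mean(record[[cl]]))
  data.frame(muscle = muscle_of_column(fcols),
             peak_N = as.numeric(peaks), mean_N = as.numeric(means))
}
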