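# Experiment orchestration: the full grid of cohort x motion x controller x
# orientation, with passive moment-arm estimation preceding every active
# simulation, and the cohort-level summaries.

#' Estimate controller inputs for one specimen
#'
#' Runs the passive FE and RUD sweeps under constant preload, estimates the
#' moment-arm matrix by the tendon excursion method, and returns the muscle
#' set the controllers should use (the specimen's muscle set with moment
#' arms replaced by the estimates).
#'
#' @param specimen a [specimen_model()].
#' @param fe_range,rud_range sweep half-amplitudes, degrees.
#' @param preload sweep tendon preload, N (default 10).
#' @return List with `muscles` (a [muscle_set()] carrying the estimated
#'   arms), `R_hat` (2 x 6, mm), and the two `passive_sweep_record`s.
#' @export
calibrate_specimen <- function(specimen, fe_range = 40, rud_range = 20,
                               preload = 10) {
  sw_fe <- passive_sweep(specimen, "FE", fe_range, preload)
  sw_rud <- passive_sweep(specimen, "RUD", rud_range, preload)
  R_hat <- estimate_moment_arms(sw_fe, sw_rud)
  ms <- specimen$muscles
  muscles <- muscle_set(R_hat, ms$pcsa, ms$f_lower, ms$specific_tension)
  list(muscles = muscles, R_hat = R_hat, sweep_fe = sw_fe, sweep_rud = sw_rud)
}

#' Run the full simulation experiment grid
#'
#' For every specimen in the cohort and every combination of motion,
#' controller and orientation: calibrate moment arms from passive sweeps,
#' run the cyclic motion, and compute the outcome metrics. Fully
#' reproducible from the seed (per-run noise seeds are derived from it and
#' the run index).
#'
#' @param cohort list of [specimen_model()]s (see [generate_cohort()]).
#' @param motions character vector of [motion_names()].
#' @param controllers subset of `c("hybrid", "cascade")`.
#' @param orientations subset of [orientations()].
#' @param cycles cycles per run (default 5).
#' @param period cycle period, s (default 4).
#' @param seed integer seed for measurement noise.
#' @param noise a [noise_config()].
#' @param hybrid_cfg,cascade_cfg controller configurations (defaults used
#'   when `NULL`).
#' @param out_dir if non-`NULL`, per-run CSVs, summary CSVs and a JSON run
#'   manifest are written there.
#' @param verbose print per-run progress to stderr.
#' @return An object of class `wrist_experiment`: list with `records`
#'   (nested by run id), `runs` (one-row-per-run data frame with kinematic
#'   errors, repeatability and flags), `error_table` (cohort mean and SD of
#'   the per-axis errors for each condition), `repeatability_table`, and
#'   `manifest`.
#' @export
run_experiment <- function(cohort, motions = c("FE30", "RUD10"),
                           controllers = "hybrid",
                           orientations = "vertical_up",
                           cycles = 5, period = 4, seed = 1,
                           noise = noise_config(),
                           hybrid_cfg = NULL, cascade_cfg = NULL,
                           out_dir = NULL, verbose = FALSE) {
  if (length(cohort) == 0 || length(motions) == 0 ||
      length(controllers) == 0 || length(orientations) == 0)
    stop("run_experiment: all factor lists must be non-empty")
  motions <- vapply(motions, function(m) match.arg(toupper(m), motion_names()), "")
  controllers <- vapply(controllers, function(ct) match.arg(ct, c("hybrid", "cascade")), "")
  orientations <- vapply(orientations, match_orientation, "")
  if (is.null(names(cohort))) names(cohort) <- paste0("S", seq_along(cohort))
  if (is.null(hybrid_cfg)) hybrid_cfg <- hybrid_config()
  if (is.null(cascade_cfg)) cascade_cfg <- cascade_config()

  calib <- lapply(cohort, calibrate_specimen)
  grid <- expand.grid(specimen = names(cohort), motion = motions,
                      controller = controllers, orientation = orientations,
                      stringsAsFactors = FALSE)
  records <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    run_seed <- (as.integer(seed) * 7919L + i) %% .Machine$integer.max
    if (verbose)
      message(sprintf("[%d/%d] %s %s %s %s", i, nrow(grid), g$specimen,
                      g$motion, g$controller, g$orientation))
    rec <- run_simulation(cohort[[g$specimen]],
                          trajectory_spec(g$motion, period = period, n_cycles = cycles),
                          controller = g$controller, orientation = g$orientation,
                          cfg = if (g$controller == "hybrid") hybrid_cfg else cascade_cfg,
                          muscles_ctrl = calib[[g$specimen]]$muscles,
                          noise = noise, seed = run_seed,
                          specimen_id = g$specimen)
    err <- kinematic_error(rec)
    rep_sd <- if (cycles >= 2) repeatability(waypoint_forces(rec))$specimen_mean_sd
              else NA_real_
    meta <- record_meta(rec)
    if (isTRUE(meta$flagged))
      warning(sprintf("run %s/%s/%s/%s flagged unstable (%.0f%% of samples at stops)",
                      g$specimen, g$motion, g$controller, g$orientation,
                      100 * meta$stop_fraction))
    records[[i]] <- rec
    rows[[i]] <- data.frame(g, seed = run_seed, err_fe = err$fe, err_rud = err$rud,
                            mean_force_sd = rep_sd,
                            max_sum_force = max(rowSums(rec[force_columns(rec)])),
                            flagged = isTRUE(meta$flagged))
  }
  runs <- do.call(rbind, rows)
  names(records) <- run_id(runs)
  rownames(runs) <- NULL

  res <- structure(list(records = records, runs = runs,
                        error_table = error_table(runs),
                        repeatability_table = repeatability_table(runs),
                        calibration = calib,
                        manifest = list(motions = unname(motions),
                                        controllers = unname(controllers),
                                        orientations = unname(orientations),
                                        n_specimens = length(cohort),
                                        cycles = cycles, period = period,
                                        seed = as.integer(seed),
                                        noise = unclass(noise))),
                   class = "wrist_experiment")
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

run_id <- function(runs) {
  paste(runs$specimen, runs$motion, runs$controller, runs$orientation, sep = "_")
}

#' @export
print.wrist_experiment <- function(x, ...) {
  cat(sprintf("<wrist_experiment> %d runs (%d flagged)\n", nrow(x$runs),
              sum(x$runs$flagged)))
  print(x$error_table, digits = 3)
  invisible(x)
}

# Cohort mean +/- SD of per-axis errors for each condition (Table-1 style).
error_table <- function(runs) {
  agg <- function(v, f) c(mean = mean(v), sd = stats::sd(v))
  key <- runs[c("motion", "controller", "orientation")]
  sp <- split(runs, interaction(key, drop = TRUE, lex.order = TRUE))
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(motion = d$motion[1], controller = d$controller[1],
               orientation = d$orientation[1], n = nrow(d),
               err_fe_mean = mean(d$err_fe), err_fe_sd = stats::sd(d$err_fe),
               err_rud_mean = mean(d$err_rud), err_rud_sd = stats::sd(d$err_rud))
  }))
  rownames(out) <- NULL
  out
}

repeatability_table <- function(runs) {
  key <- runs[c("motion", "controller", "orientation")]
  sp <- split(runs, interaction(key, drop = TRUE, lex.order = TRUE))
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(motion = d$motion[1], controller = d$controller[1],
               orientation = d$orientation[1], n = nrow(d),
               mean_force_sd_N = mean(d$mean_force_sd))
  }))
  rownames(out) <- NULL
  out
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(res$records))
    write_record_csv(res$records[[id]], file.path(out_dir, paste0(id, ".csv")))
  utils::write.csv(res$runs, file.path(out_dir, "runs.csv"), row.names = FALSE)
  utils::write.csv(res$error_table, file.path(out_dir, "error_table.csv"),
                   row.names = FALSE)
  utils::write.csv(res$repeatability_table,
                   file.path(out_dir, "repeatability_table.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Cohort group-force comparison across orientations
#'
#' For one motion run under several orientations, computes each specimen's
#' mean flexor- or extensor-group force at matched kinematic waypoints
#' (optionally restricted to a waypoint range), then compares orientations
#' with the paired nonparametric procedure of [compare_conditions()].
#'
#' @param experiment a `wrist_experiment` containing the motion under all
#'   requested orientations (same controller).
#' @param motion motion name (default `"FE30"`).
#' @param controller controller name (default `"hybrid"`).
#' @param group `"extensor"` or `"flexor"`.
#' @param axis waypoint axis, `"FE"` or `"RUD"`.
#' @param waypoints optional numeric vector: restrict to these waypoint
#'   angles (degrees); default uses all waypoints shared by every run.
#' @return List with `per_specimen` (matrix: specimens x orientations of
#'   mean group force, N) and `comparison` (a [compare_conditions()] result,
#'   or `NULL` when only one orientation is present).
#' @export
orientation_force_effect <- function(experiment, motion = "FE30",
                                     controller = "hybrid",
                                     group = c("extensor", "flexor"),
                                     axis = "FE", waypoints = NULL) {
  group <- match.arg(group)
  gm <- if (group == "flexor") c("FCR", "FCU", "APL") else c("ECRL", "ECRB", "ECU")
  runs <- experiment$runs
  sel <- runs$motion == motion & runs$controller == controller
  orients <- unique(runs$orientation[sel])
  specs <- unique(runs$specimen[sel])
  per <- matrix(NA_real_, length(specs), length(orients),
                dimnames = list(specs, orients))
  for (s in specs) for (o in orients) {
    idx <- which(sel & runs$specimen == s & runs$orientation == o)
    if (length(idx) != 1) next
    wp <- waypoint_forces(experiment$records[[idx]])
    wp <- wp[wp$axis == axis & wp$muscle %in% gm, ]
    if (!is.null(waypoints)) wp <- wp[wp$waypoint_deg %in% waypoints, ]
    # group force per (cycle, waypoint, direction) = sum over group muscles
    key <- interaction(wp$cycle, wp$waypoint_deg, wp$direction, drop = TRUE)
    per[s, o] <- mean(tapply(wp$force_N, key, sum))
  }
  comparison <- if (length(orients) >= 2 && !anyNA(per))
    compare_conditions(per) else NULL
  list(per_specimen = per, comparison = comparison)
}

#' Circumduction direction effect on muscle forces
#'
#' Pairs each specimen's clockwise and anticlockwise circumduction runs and
#' compares per-muscle peak and mean forces (Wilcoxon signed-rank), along
#' with the total muscle force summed over all six muscles.
#'
#' @param experiment a `wrist_experiment` containing `CCD_CW` and `CCD_ACW`
#'   runs for the same specimens and controller.
#' @param controller controller name (default `"hybrid"`).
#' @return List with `peak` and `mean` (data frames: muscle, cohort means in
#'   each direction, relative difference, Wilcoxon p) and `total_force`
#'   (cohort mean of the time-averaged sum of all six forces per direction,
#'   with relative difference and p).
#' @export
circumduction_effect <- function(experiment, controller = "hybrid") {
  runs <- experiment$runs
  specs <- unique(runs$specimen)
  get <- function(motion, s) {
    idx <- which(runs$motion == motion & runs$controller == controller &
                 runs$specimen == s)
    if (length(idx) != 1) stop("circumduction_effect: need exactly one ",
                               motion, " run per specimen")
    experiment$records[[idx]]
  }
  pm_cw <- lapply(specs, function(s) peak_mean_forces(get("CCD_CW", s)))
  pm_acw <- lapply(specs, function(s) peak_mean_forces(get("CCD_ACW", s)))
  muscles <- pm_cw[[1]]$muscle
  stat_tab <- function(field) {
    do.call(rbind, lapply(seq_along(muscles), function(j) {
      cw <- vapply(pm_cw, function(d) d[[field]][j], 0)
      acw <- vapply(pm_acw, function(d) d[[field]][j], 0)
      w <- wilcoxon_signed_rank(cw, acw)
      data.frame(muscle = muscles[j], cw_N = mean(cw), acw_N = mean(acw),
                 rel_diff = (mean(cw) - mean(acw)) /
                   mean(c(mean(cw), mean(acw))),
                 p = w$p)
    }))
  }
  tot_cw <- vapply(specs, function(s) {
    r <- get("CCD_CW", s); mean(rowSums(r[force_columns(r)]))
  }, 0)
  tot_acw <- vapply(specs, function(s) {
    r <- get("CCD_ACW", s); mean(rowSums(r[force_columns(r)]))
  }, 0)
  wtot <- wilcoxon_signed_rank(tot_cw, tot_acw)
  list(peak = stat_tab("peak_N"), mean = stat_tab("mean_N"),
       total_force = data.frame(cw_N = mean(tot_cw), acw_N = mean(tot_acw),
                                rel_diff = (mean(tot_cw) - mean(tot_acw)) /
                                  mean(c(mean(tot_cw), mean(tot_acw))),
                                p = wtot$p))
}
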