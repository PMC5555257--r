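# Config and data file interfaces: YAML specimen/controller configs,
# tidy CSV records, JSON run manifests.

#' Write / read a specimen configuration
#'
#' Serialises a [specimen_model()] to YAML and back. Keys and units:
#' `hand_mass_kg`, `com_distance_m`, `inertia_fe_kgm2`, `inertia_rud_kgm2`,
#' `passive_stiffness_Nm_per_deg` (FE, RUD), `passive_damping_Nms_per_deg`
#' (FE, RUD), `gravity_accel_m_s2`, and a `muscles` block with
#' `names`, `moment_arms_mm` (rows `FE`, `RUD`), `pcsa_cm2`,
#' `f_lower_N`, `specific_tension_N_cm2`.
#'
#' @param specimen a [specimen_model()].
#' @param path file path to write to / read from.
#' @return `read_specimen_config()` returns a `specimen_model`;
#'   `write_specimen_config()` returns `path` invisibly.
#' @export
write_specimen_config <- function(specimen, path) {
  stopifnot(inherits(specimen, "specimen_model"))
  m <- specimen$muscles
  obj <- list(
    hand_mass_kg = specimen$hand_mass,
    com_distance_m = specimen$com_distance,
    inertia_fe_kgm2 = specimen$inertia_fe,
    inertia_rud_kgm2 = specimen$inertia_rud,
    passive_stiffness_Nm_per_deg = as.numeric(specimen$passive_stiffness),
    passive_damping_Nms_per_deg = as.numeric(specimen$passive_damping),
    gravity_accel_m_s2 = specimen$gravity_accel,
    muscles = list(names = m$names,
                   moment_arms_mm = list(FE = as.numeric(m$R[1, ]),
                                         RUD = as.numeric(m$R[2, ])),
                   pcsa_cm2 = as.numeric(m$pcsa),
                   f_lower_N = as.numeric(m$f_lower),
                   specific_tension_N_cm2 = m$specific_tension))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_specimen_config
#' @export
read_specimen_config <- function(path) {
  obj <- yaml::read_yaml(path)
  ms <- muscle_set(R = rbind(obj$muscles$moment_arms_mm$FE,
                             obj$muscles$moment_arms_mm$RUD),
                   pcsa = obj$muscles$pcsa_cm2,
                   f_lower = obj$muscles$f_lower_N,
                   specific_tension = obj$muscles$specific_tension_N_cm2)
  specimen_model(muscles = ms,
                 hand_mass = obj$hand_mass_kg,
                 com_distance = obj$com_distance_m,
                 inertia_fe = obj$inertia_fe_kgm2,
                 inertia_rud = obj$inertia_rud_kgm2,
                 passive_stiffness = obj$passive_stiffness_Nm_per_deg,
                 passive_damping = obj$passive_damping_Nms_per_deg,
                 gravity_accel = obj$gravity_accel_m_s2)
}

#' Write / read a simulation record as tidy CSV
#'
#' Columns: `time_s`, `theta_fe_deg`, `theta_rud_deg`, `desired_fe_deg`,
#' `desired_rud_deg`, one force column per muscle (`F_FCR_N` ... `F_APL_N`)
#' and `cycle`. Metadata travels in a sidecar JSON written next to the CSV
#' (`<path>.meta.json`).
#'
#' @param record a `simulation_record`.
#' @param path CSV file path.
#' @return `read_record_csv()` returns a `simulation_record`;
#'   `write_record_csv()` returns `path` invisibly.
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  meta <- record_meta(record)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  df <- utils::read.csv(path)
  metapath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metapath)) jsonlite::read_json(metapath, simplifyVector = TRUE)
          else NULL
  structure(df, class = c("simulation_record", "data.frame"), meta = meta)
}

#' Write / read a passive sweep record as CSV
#'
#' Same dialect as the simulation-record CSV (angle and per-muscle force
#' columns) plus one excursion column per muscle (`exc_FCR_mm` ...).
#'
#' @param sweep a `passive_sweep_record`.
#' @param path CSV file path.
#' @return `read_sweep_csv()` returns a `passive_sweep_record`;
#'   `write_sweep_csv()` returns `path` invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "passive_sweep_record"))
  nm <- colnames(sweep$excursions)
  df <- data.frame(sample = seq_len(nrow(sweep$angles)),
                   axis = sweep$axis,
                   theta_fe_deg = sweep$angles$theta_fe,
                   theta_rud_deg = sweep$angles$theta_rud)
  fdf <- as.data.frame(sweep$forces); names(fdf) <- paste0("F_", nm, "_N")
  edf <- as.data.frame(sweep$excursions); names(edf) <- paste0("exc_", nm, "_mm")
  utils::write.csv(cbind(df, fdf, edf), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path)
  fcols <- grep("^F_.*_N$", names(df), value = TRUE)
  ecols <- grep("^exc_.*_mm$", names(df), value = TRUE)
  exc <- as.matrix(df[ecols]); colnames(exc) <- sub("^exc_(.*)_mm$", "\\1", ecols)
  forces <- as.matrix(df[fcols]); colnames(forces) <- colnames(exc)
  structure(list(angles = data.frame(theta_fe = df$theta_fe_deg,
                                     theta_rud = df$theta_rud_deg),
                 excursions = exc, forces = forces,
                 axis = as.character(df$axis[1]), preload = unname(forces[1, 1])),
            class = "passive_sweep_record")
}
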