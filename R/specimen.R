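#' The six wrist muscles
#'
#' Canonical muscle order used throughout the package: flexor carpi radialis
#' (FCR), flexor carpi ulnaris (FCU), extensor carpi radialis longus (ECRL),
#' extensor carpi radialis brevis (ECRB), extensor carpi ulnaris (ECU) and
#' abductor pollicis longus (APL).
#'
#' @return Character vector of the six muscle names, in canonical order.
#' @export
muscle_names <- function() c("FCR", "FCU", "ECRL", "ECRB", "ECU", "APL")

#' Muscle geometry and force bounds for the six wrist muscles
#'
#' Bundles the moment-arm matrix, physiological cross-sectional areas (PCSA)
#' and force bounds of the six primary wrist muscles. The upper force bound
#' of each muscle is always `pcsa * specific_tension` (maximal isometric
#' force); the lower bound is a small tonic force keeping tendons taut,
#' standing in for EMG-derived minimum activity.
#'
#' @param R 2 x 6 moment-arm matrix in millimetres. Row 1 is the FE axis,
#'   row 2 the RUD axis; a positive entry means the muscle's force produces a
#'   positive (flexion / ulnar) angle change. Columns follow [muscle_names()].
#' @param pcsa six physiological cross-sectional areas in cm^2.
#' @param f_lower six lower force bounds in newtons (default 2 N each).
#' @param specific_tension maximal force per unit PCSA, N/cm^2 (default 35).
#' @param arm_slope optional 2 x 6 matrix of moment-arm variation with the
#'   corresponding joint angle, mm/degree; zero (the default) gives a
#'   constant-moment-arm plant. Nonzero slopes are used to exercise the
#'   tendon-excursion moment-arm estimator on angle-dependent geometry.
#'
#' @return An object of class `muscle_set` with elements `names`, `R`,
#'   `pcsa`, `f_lower`, `f_upper`, `specific_tension`, `arm_slope`.
#' @examples
#' ms <- default_muscle_set()
#' ms$f_upper                      # pcsa * specific tension
#' @export
muscle_set <- function(R, pcsa, f_lower = rep(2, 6), specific_tension = 35,
                       arm_slope = NULL) {
  R <- as.matrix(R)
  if (!identical(dim(R), c(2L, 6L)))
    stop("muscle_set: R must be a 2 x 6 matrix (FE row, RUD row)")
  pcsa <- as.numeric(pcsa); f_lower <- as.numeric(f_lower)
  if (length(pcsa) != 6 || length(f_lower) != 6)
    stop("muscle_set: pcsa and f_lower must have length 6")
  if (!all(is.finite(R)) || !all(is.finite(pcsa)) || !all(is.finite(f_lower)))
    stop("muscle_set: non-finite parameter")
  if (any(pcsa <= 0)) stop("muscle_set: pcsa must be strictly positive")
  if (!is.finite(specific_tension) || specific_tension <= 0)
    stop("muscle_set: specific_tension must be strictly positive")
  f_upper <- pcsa * specific_tension
  if (any(f_lower < 0) || any(f_lower >= f_upper))
    stop("muscle_set: need 0 <= f_lower < f_upper = pcsa * specific_tension")
  if (qr(R)$rank < 2)
    stop("muscle_set: moment-arm matrix must have full row rank")
  if (is.null(arm_slope)) arm_slope <- matrix(0, 2, 6)
  arm_slope <- as.matrix(arm_slope)
  if (!identical(dim(arm_slope), c(2L, 6L)))
    stop("muscle_set: arm_slope must be a 2 x 6 matrix")
  nm <- muscle_names()
  dimnames(R) <- list(c("FE", "RUD"), nm)
  dimnames(arm_slope) <- dimnames(R)
  structure(list(names = nm, R = R, pcsa = stats::setNames(pcsa, nm),
                 f_lower = stats::setNames(f_lower, nm),
                 f_upper = stats::setNames(f_upper, nm),
                 specific_tension = specific_tension,
                 arm_slope = arm_slope),
            class = "muscle_set")
}

#' @export
print.muscle_set <- function(x, ...) {
  cat("<muscle_set> 6 muscles, specific tension", x$specific_tension, "N/cm^2\n")
  tab <- rbind(`arm FE (mm)` = x$R[1, ], `arm RUD (mm)` = x$R[2, ],
               `PCSA (cm^2)` = x$pcsa, `F min (N)` = x$f_lower,
               `F max (N)` = round(x$f_upper, 1))
  print(round(tab, 2))
  invisible(x)
}

#' Default muscle set
#'
#' Moment arms and PCSAs representative of the adult wrist, drawn from
#' standard anatomical literature ranges: flexors carry positive FE arms,
#' extensors negative; radial deviators carry negative RUD arms, ulnar
#' deviators positive. These are template values; specimen-to-specimen
#' variation is added by [generate_cohort()].
#'
#' @inheritParams muscle_set
#' @return A [muscle_set()].
#' @export
default_muscle_set <- function(specific_tension = 35) {
  muscle_set(
    R = rbind(FE  = c(FCR = 10, FCU = 14, ECRL = -7, ECRB = -12, ECU = -6, APL = 4),
              RUD = c(FCR = -8, FCU = 12, ECRL = -13, ECRB = -3, ECU = 14, APL = -15)),
    pcsa = c(FCR = 2.0, FCU = 3.4, ECRL = 2.2, ECRB = 2.7, ECU = 2.6, APL = 1.9),
    f_lower = rep(2, 6),
    specific_tension = specific_tension
  )
}

#' Specimen model: the complete plant parameterisation
#'
#' Everything the in-silico plant needs to stand in for one specimen: the
#' muscle set, hand-segment mass properties, passive joint stiffness and
#' damping, and gravity. The plant is a per-axis second-order rigid-body
#' model with linear passive elements; cross-axis inertial coupling is
#' neglected.
#'
#' @param muscles a [muscle_set()].
#' @param hand_mass hand-segment mass, kg.
#' @param com_distance distance from the wrist centre to the hand segment's
#'   centre of mass along the third-metacarpal axis, metres.
#' @param inertia_fe,inertia_rud hand-segment moments of inertia about the
#'   wrist FE and RUD axes, kg m^2.
#' @param passive_stiffness length-2 vector (FE, RUD) of linear passive
#'   joint stiffness, N m / degree.
#' @param passive_damping length-2 vector (FE, RUD) of passive damping,
#'   N m s / degree.
#' @param gravity_accel gravitational acceleration, m/s^2.
#'
#' @return An object of class `specimen_model`.
#' @seealso [default_specimen()], [read_specimen_config()]
#' @export
specimen_model <- function(muscles, hand_mass, com_distance,
                           inertia_fe, inertia_rud,
                           passive_stiffness, passive_damping,
                           gravity_accel = 9.81) {
  stopifnot(inherits(muscles, "muscle_set"))
  passive_stiffness <- rep_len(as.numeric(passive_stiffness), 2)
  passive_damping <- rep_len(as.numeric(passive_damping), 2)
  pos <- c(hand_mass, com_distance, inertia_fe, inertia_rud,
           passive_stiffness, passive_damping, gravity_accel)
  if (!all(is.finite(pos)) || any(pos <= 0))
    stop("specimen_model: masses, inertias, stiffnesses, dampings and gravity must be strictly positive")
  structure(list(muscles = muscles,
                 hand_mass = hand_mass, com_distance = com_distance,
                 inertia_fe = inertia_fe, inertia_rud = inertia_rud,
                 passive_stiffness = stats::setNames(passive_stiffness, c("FE", "RUD")),
                 passive_damping = stats::setNames(passive_damping, c("FE", "RUD")),
                 gravity_accel = gravity_accel),
            class = "specimen_model")
}

#' @export
print.specimen_model <- function(x, ...) {
  cat(sprintf(paste0("<specimen_model> hand %.3f kg, COM %.3f m, ",
                     "I = (%.4g, %.4g) kg m^2\n"),
              x$hand_mass, x$com_distance, x$inertia_fe, x$inertia_rud))
  cat(sprintf("  passive k = (%g, %g) N m/deg, b = (%g, %g) N m s/deg, g = %g m/s^2\n",
              x$passive_stiffness[1], x$passive_stiffness[2],
              x$passive_damping[1], x$passive_damping[2], x$gravity_accel))
  print(x$muscles)
  invisible(x)
}

#' Default specimen
#'
#' The template plant: a 0.4 kg hand segment with its centre of mass 0.07 m
#' distal to the wrist, 0.002 kg m^2 inertia per axis, lightly damped linear
#' passive stiffness representative of the mid-range passive wrist, and the
#' default muscle set. All values are configurable via [specimen_model()] or
#' a YAML config (see [read_specimen_config()]).
#'
#' @return A `specimen_model`.
#' @examples
#' default_specimen()
#' @export
default_specimen <- function() {
  specimen_model(
    muscles = default_muscle_set(),
    hand_mass = 0.4,
    com_distance = 0.07,
    inertia_fe = 0.002,
    inertia_rud = 0.002,
    passive_stiffness = c(0.008, 0.008),
    passive_damping = c(0.0006, 0.0006),
    gravity_accel = 9.81
  )
}
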