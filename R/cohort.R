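# Synthetic specimen cohort: the in-silico stand-in for a set of cadaveric
# specimens.

#' Cohort specification
#'
#' Describes how a cohort of synthetic specimens is drawn around a template:
#' each varied parameter is sampled from a log-normal distribution centred
#' on the template value with the given coefficient of variation (CoV), so
#' magnitudes jitter while moment-arm sign patterns are preserved. Upper
#' force bounds are recomputed from each specimen's sampled PCSA.
#'
#' @param n_specimens number of specimens (default 10).
#' @param template template [specimen_model()] (default [default_specimen()]).
#' @param jitter named list of CoV fractions in `[0, 0.5]`:
#'   `moment_arms`, `pcsa`, `hand_mass`, `com_distance` (defaults 0.12,
#'   0.15, 0.10, 0.08 — plausible anatomical inter-specimen variation).
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_specimens = 10, template = default_specimen(),
                        jitter = list(), seed = 1) {
  if (n_specimens < 1) stop("cohort_spec: n_specimens must be >= 1")
  stopifnot(inherits(template, "specimen_model"))
  jit <- utils::modifyList(
    list(moment_arms = 0.12, pcsa = 0.15, hand_mass = 0.10, com_distance = 0.08),
    jitter)
  jv <- unlist(jit[c("moment_arms", "pcsa", "hand_mass", "com_distance")])
  if (any(jv < 0) || any(jv > 0.5))
    stop("cohort_spec: jitter fractions must lie in [0, 0.5]")
  structure(list(n_specimens = as.integer(n_specimens), template = template,
                 jitter = jit, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d specimens, seed %d, CoV: arms %.2f, pcsa %.2f, mass %.2f, com %.2f\n",
              x$n_specimens, x$seed, x$jitter$moment_arms, x$jitter$pcsa,
              x$jitter$hand_mass, x$jitter$com_distance))
  invisible(x)
}

# Log-normal multiplier with mean 1 and coefficient of variation cv.
lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic specimen cohort
#'
#' Draws `n_specimens` plants around the template. Moment-arm magnitudes,
#' PCSAs, hand mass and centre-of-mass distance are each multiplied by
#' independent log-normal factors with the specified CoVs (mean 1, so the
#' cohort is centred on the template); moment-arm signs are preserved by
#' construction, and each specimen's upper force bounds are recomputed as
#' sampled PCSA times specific tension.
#'
#' @param spec a [cohort_spec()].
#' @return List of `n_specimens` [specimen_model()]s, named `S1`, `S2`, ...
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_specimens = 3, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  tpl <- spec$template; jit <- spec$jitter
  lapply(stats::setNames(seq_len(spec$n_specimens),
                         paste0("S", seq_len(spec$n_specimens))), function(i) {
    R <- tpl$muscles$R * matrix(lnorm_factor(12, jit$moment_arms), 2, 6)
    pcsa <- tpl$muscles$pcsa * lnorm_factor(6, jit$pcsa)
    ms <- muscle_set(R, pcsa, f_lower = tpl$muscles$f_lower,
                     specific_tension = tpl$muscles$specific_tension,
                     arm_slope = tpl$muscles$arm_slope)
    specimen_model(
      muscles = ms,
      hand_mass = tpl$hand_mass * lnorm_factor(1, jit$hand_mass),
      com_distance = tpl$com_distance * lnorm_factor(1, jit$com_distance),
      inertia_fe = tpl$inertia_fe, inertia_rud = tpl$inertia_rud,
      passive_stiffness = tpl$passive_stiffness,
      passive_damping = tpl$passive_damping,
      gravity_accel = tpl$gravity_accel)
  })
}
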