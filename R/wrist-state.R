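#' Wrist joint state
#'
#' A snapshot of the two rotational degrees of freedom of the wrist:
#' flexion-extension (FE, flexion positive) and radioulnar deviation
#' (RUD, ulnar deviation positive), with their angular velocities.
#' Sign conventions follow the ISB joint coordinate recommendations for
#' the wrist.
#'
#' @param theta_fe FE angle in degrees (flexion positive, extension negative).
#' @param theta_rud RUD angle in degrees (ulnar positive, radial negative).
#' @param omega_fe,omega_rud angular velocities in degrees/second.
#'
#' @return An object of class `wrist_state`.
#' @examples
#' wrist_state(30, -5)
#' @export
wrist_state <- function(theta_fe = 0, theta_rud = 0, omega_fe = 0, omega_rud = 0) {
  s <- list(theta_fe = as.numeric(theta_fe), theta_rud = as.numeric(theta_rud),
            omega_fe = as.numeric(omega_fe), omega_rud = as.numeric(omega_rud))
  class(s) <- "wrist_state"
  validate_wrist_state(s)
  s
}

#' @export
print.wrist_state <- function(x, ...) {
  cat(sprintf("<wrist_state> FE %+.2f deg (%+.1f deg/s), RUD %+.2f deg (%+.1f deg/s)\n",
              x$theta_fe, x$omega_fe, x$theta_rud, x$omega_rud))
  invisible(x)
}

# Anatomical stops of the plant (deg)
FE_STOP <- 90
RUD_STOP <- 45

validate_wrist_state <- function(s) {
  v <- unlist(s[c("theta_fe", "theta_rud", "omega_fe", "omega_rud")])
  if (!all(is.finite(v)))
    stop("wrist_state: angles and velocities must be finite")
  if (abs(s$theta_fe) > FE_STOP + 1e-9 || abs(s$theta_rud) > RUD_STOP + 1e-9)
    stop(sprintf("wrist_state: outside anatomical stops (|FE| <= %d, |RUD| <= %d deg)",
                 FE_STOP, RUD_STOP))
  invisible(s)
}

#' Hand orientations
#'
#' The three gravitational conditions under which motions are simulated:
#' hand vertically above the elbow (`"vertical_up"`), hand vertically below
#' the elbow (`"vertical_down"`), and forearm horizontal with the palm
#' facing down (`"horizontal_palm_down"`).
#'
#' @return Character vector of the three valid orientation names.
#' @examples
#' orientations()
#' @export
orientations <- function() {
  c("vertical_up", "vertical_down", "horizontal_palm_down")
}

match_orientation <- function(orientation) {
  match.arg(orientation, orientations())
}
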