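# Quadratic muscle-force distribution.

#' Muscle-force distribution problem
#'
#' The redundancy-resolution problem solved inside cascade control: find the
#' tendon tensions that realise a desired joint torque while minimising the
#' sum of squared muscle stresses, subject to physiologic force bounds and a
#' bound on the muscle impedance rho = sum of all tendon tensions.
#'
#' @param tau_desired desired joint torque, N m (length 1 or 2: one value
#'   per controlled axis).
#' @param R moment-arm matrix in mm, one row per axis, one column per muscle;
#'   must have full row rank.
#' @param pcsa physiological cross-sectional areas, cm^2 (one per muscle).
#' @param f_lower,f_upper force bounds, N.
#' @param rho_min,rho_max bounds on the sum of all tendon tensions, N
#'   (defaults 0 and 400: rho effectively unconstrained from above).
#' @return An object of class `force_distribution_problem`.
#' @seealso [solve_force_distribution()]
#' @export
force_distribution_problem <- function(tau_desired, R, pcsa, f_lower, f_upper,
                                       rho_min = 0, rho_max = 400) {
  R <- rbind(R)
  n <- ncol(R)
  pcsa <- as.numeric(pcsa); f_lower <- as.numeric(f_lower)
  f_upper <- as.numeric(f_upper); tau_desired <- as.numeric(tau_desired)
  if (length(tau_desired) != nrow(R))
    stop("force_distribution_problem: tau_desired must have one value per row of R")
  if (length(pcsa) != n || length(f_lower) != n || length(f_upper) != n)
    stop("force_distribution_problem: pcsa and bounds must match ncol(R)")
  if (any(pcsa <= 0)) stop("force_distribution_problem: pcsa must be positive")
  if (any(f_lower < 0) || any(f_lower > f_upper))
    stop("force_distribution_problem: inconsistent force bounds")
  if (rho_min < 0 || rho_min >= rho_max)
    stop("force_distribution_problem: need 0 <= rho_min < rho_max")
  if (sum(f_lower) > rho_max || sum(f_upper) < rho_min)
    stop("force_distribution_problem: force bounds incompatible with rho bounds")
  if (qr(R)$rank < nrow(R))
    stop("force_distribution_problem: R must have full row rank")
  structure(list(tau_desired = tau_desired, R = R, pcsa = pcsa,
                 f_lower = f_lower, f_upper = f_upper,
                 rho_min = rho_min, rho_max = rho_max),
            class = "force_distribution_problem")
}

#' Solve the muscle-force distribution QP
#'
#' Minimises the sum of squared muscle stresses `sum((F_i / pcsa_i)^2)`
#' subject to `R F = tau_desired` (moment arms converted mm -> m),
#' elementwise force bounds, and `rho_min <= sum(F) <= rho_max`. The
#' objective is strictly convex, so the minimiser is unique whenever the
#' constraints are feasible. If the torque equality cannot be met within the
#' bounds, the solver returns the bounded force vector whose achieved torque
#' is least-squares closest to the request and flags the result infeasible.
#'
#' @param problem a [force_distribution_problem()].
#' @return List with `forces` (N), `feasible` (logical: was the torque
#'   equality met), `tau_achieved` (N m), and `objective` (sum of squared
#'   stresses, N^2/cm^4).
#' @examples
#' pr <- force_distribution_problem(c(0.1, -0.05), default_muscle_set()$R,
#'                                  default_muscle_set()$pcsa,
#'                                  rep(2, 6), default_muscle_set()$f_upper)
#' solve_force_distribution(pr)
#' @export
solve_force_distribution <- function(problem) {
  stopifnot(inherits(problem, "force_distribution_problem"))
  p <- problem
  n <- ncol(p$R)
  Rm <- p$R / 1000                      # mm -> m
  C <- diag(2 / p$pcsa^2, n)
  A <- rbind(rep(1, n), rep(-1, n))
  b <- c(p$rho_max, -p$rho_min)

  sol <- tryCatch(
    pracma::quadprog(C, rep(0, n), A = A, b = b, Aeq = Rm, beq = p$tau_desired,
                     lb = p$f_lower, ub = p$f_upper),
    error = function(e) NULL)
  tol <- 1e-7 * max(1, max(abs(p$tau_desired)))
  if (!is.null(sol) && sol$eflag == 1 &&
      max(abs(Rm %*% sol$xmin - p$tau_desired)) <= tol &&
      all(sol$xmin >= p$f_lower - 1e-7) && all(sol$xmin <= p$f_upper + 1e-7)) {
    f <- pmin(pmax(sol$xmin, p$f_lower), p$f_upper)
    return(list(forces = f, feasible = TRUE,
                tau_achieved = drop(Rm %*% f),
                objective = sum((f / p$pcsa)^2)))
  }

  # torque equality infeasible within bounds: least-squares closest torque,
  # with a vanishing stress regulariser to keep the solution unique
  lambda <- 1e-9
  C2 <- 2 * (crossprod(Rm) + lambda * diag(1 / p$pcsa^2, n))
  d2 <- -2 * drop(crossprod(Rm, p$tau_desired))
  sol2 <- pracma::quadprog(C2, d2, A = A, b = b, lb = p$f_lower, ub = p$f_upper)
  f <- pmin(pmax(sol2$xmin, p$f_lower), p$f_upper)
  tau_ach <- drop(Rm %*% f)
  list(forces = f,
       feasible = max(abs(tau_ach - p$tau_desired)) <= 1e-6 * max(1, max(abs(p$tau_desired))),
       tau_achieved = tau_ach,
       objective = sum((f / p$pcsa)^2))
}
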