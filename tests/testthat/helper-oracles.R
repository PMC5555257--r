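# Independent oracles for the force-distribution solver.

# Dense 1-DOF grid-search oracle: two muscles, equality r1 F1 + r2 F2 = tau
# (arms in mm, tau in N m); scan F2 at `res` newton resolution.
grid_oracle <- function(tau, r, pcsa, lo, hi, rho_min = 0, rho_max = 400,
                        res = 0.01) {
  f2 <- seq(lo[2], hi[2], by = res)
  # candidates where a constraint boundary cuts the equality line exactly
  # (the constrained optimum need not fall on the lattice)
  cuts <- c((tau * 1000 - r[1] * lo[1]) / r[2],
            (tau * 1000 - r[1] * hi[1]) / r[2],
            (rho_max - tau * 1000 / r[1]) / (1 - r[2] / r[1]),
            (rho_min - tau * 1000 / r[1]) / (1 - r[2] / r[1]),
            lo[2], hi[2])
  f2 <- c(f2, cuts[is.finite(cuts) & cuts >= lo[2] & cuts <= hi[2]])
  f1 <- (tau * 1000 - r[2] * f2) / r[1]
  ok <- f1 >= lo[1] - 1e-12 & f1 <= hi[1] + 1e-12 &
    f1 + f2 >= rho_min - 1e-12 & f1 + f2 <= rho_max + 1e-12
  if (!any(ok)) return(NULL)
  obj <- (f1[ok] / pcsa[1])^2 + (f2[ok] / pcsa[2])^2
  i <- which.min(obj)
  list(forces = c(f1[ok][i], f2[ok][i]), objective = obj[i])
}

# KKT residual for a feasible solution of the full problem.
kkt_residual <- function(pr, sol, tol = 1e-7) {
  f <- sol$forces; n <- length(f)
  g <- 2 * f / pr$pcsa^2                       # objective gradient
  Rm <- pr$R / 1000
  A <- t(Rm)                                   # equality constraint gradients
  act <- NULL
  if (sum(f) >= pr$rho_max - 1e-6) act <- cbind(act, rep(1, n))
  if (sum(f) <= pr$rho_min + 1e-6) act <- cbind(act, rep(-1, n))
  low <- which(f <= pr$f_lower + 1e-6)
  up <- which(f >= pr$f_upper - 1e-6)
  B <- cbind(A, act,
             if (length(low)) -diag(n)[, low, drop = FALSE],
             if (length(up)) diag(n)[, up, drop = FALSE])
  lam <- stats::coef(stats::lm.fit(B, -g))
  lam[is.na(lam)] <- 0
  # inequality multipliers must be non-negative (complementary slackness)
  n_eq <- nrow(pr$R)
  viol <- pmax(0, -lam[-seq_len(n_eq)])
  max(abs(B %*% lam + g)) + sum(viol[viol > 1e-6])
}

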