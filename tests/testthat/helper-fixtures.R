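# Shared fixtures: small hand-built specimens and records, plus a memoised
# store for the heavier cohort simulations used by the acceptance checks.

# A specimen with simple round numbers for closed-form checks.
toy_specimen <- function(hand_mass = 0.4, com_distance = 0.07,
                         stiffness = 0.008, damping = 0.0006,
                         arm_slope = NULL) {
  ms <- muscle_set(R = rbind(c(15, 10, -12, -9, -6, 5),
                             c(-6, 11, -14, -4, 13, -15)),
                   pcsa = c(2, 3, 2.5, 2.5, 2.5, 2),
                   f_lower = rep(2, 6),
                   arm_slope = arm_slope)
  specimen_model(ms, hand_mass, com_distance, 0.002, 0.002,
                 stiffness, damping)
}

# Build a simulation_record by hand from plain vectors.
make_record <- function(time_s, fe, rud, des_fe, des_rud, forces,
                        motion = "FE30", n_cycles = 1,
                        period = max(time_s), controller = "hybrid",
                        orientation = "vertical_up") {
  if (is.null(dim(forces))) forces <- matrix(forces, length(time_s), 6)
  colnames(forces) <- paste0("F_", muscle_names(), "_N")
  rec <- data.frame(time_s = time_s, theta_fe_deg = fe, theta_rud_deg = rud,
                    desired_fe_deg = des_fe, desired_rud_deg = des_rud)
  rec <- cbind(rec, as.data.frame(forces))
  rec$cycle <- pmin(floor(time_s / period) + 1L, n_cycles)
  structure(rec, class = c("simulation_record", "data.frame"),
            meta = list(specimen_id = "T1", motion = motion,
                        controller = controller, orientation = orientation,
                        n_cycles = n_cycles, period = period, seed = NULL,
                        sample_rate = 1 / diff(time_s[1:2]),
                        flagged = FALSE, stop_fraction = 0,
                        qp_infeasible = FALSE))
}

# Exact-enumeration Wilcoxon signed-rank p-value (oracle, n <= 12, no ties).
enumerate_wilcoxon <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- drop(signs %*% r)
  switch(alternative,
         greater = mean(Vs >= V),
         less = mean(Vs <= V),
         two.sided = min(1, 2 * min(mean(Vs >= V), mean(Vs <= V))))
}

# --- memoised cohort experiments shared across acceptance checks ----------

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

std_cohort <- function() cached("cohort", generate_cohort(cohort_spec(10, seed = 1)))

fe30_experiment <- function() cached("fe30", {
  run_experiment(std_cohort(), motions = "FE30", controllers = "hybrid",
                 orientations = orientations(), cycles = 5, seed = 11)
})

rud10_experiment <- function() cached("rud10", {
  run_experiment(std_cohort(), motions = "RUD10", controllers = "hybrid",
                 orientations = c("vertical_up", "horizontal_palm_down"),
                 cycles = 5, seed = 12)
})

ccd_experiment <- function() cached("ccd", {
  run_experiment(std_cohort(), motions = c("CCD_CW", "CCD_ACW"),
                 controllers = "hybrid", orientations = "vertical_up",
                 cycles = 5, seed = 13)
})

cascade_experiment <- function() cached("cascade", {
  run_experiment(std_cohort(), motions = c("FE30", "CCD_CW"),
                 controllers = "cascade", orientations = "vertical_up",
                 cycles = 5, seed = 14)
})
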