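# Hybrid and cascade controller steps and closed-loop behaviour.

test_that("hybrid at zero error returns the co-contraction baseline", {
  ms <- default_muscle_set()
  cfg <- hybrid_config()
  st <- wrist_state(5, -3)
  out <- hybrid_step(st, st, rep(10, 6), ms, cfg, controller_memory("hybrid"))
  base <- out$forces
  # baseline is torque-free and sits at the requested mean level
  expect_equal(unname(drop(ms$R %*% base)), c(0, 0), tolerance = 1e-9)
  expect_equal(mean(base), cfg$baseline, tolerance = 1e-9)
  # repeating the step leaves the command unchanged (no correction)
  out2 <- hybrid_step(st, st, base, ms, cfg, out$memory)
  expect_equal(out2$forces, base, tolerance = 1e-9)
})

test_that("hybrid commands always stay inside the physiologic bounds", {
  ms <- default_muscle_set()
  cfg <- hybrid_config()
  mem <- controller_memory("hybrid")
  set.seed(5)
  for (i in 1:200) {
    des <- wrist_state(stats::runif(1, -60, 60), stats::runif(1, -30, 30))
    meas <- wrist_state(stats::runif(1, -60, 60), stats::runif(1, -30, 30),
                        stats::runif(1, -100, 100), stats::runif(1, -100, 100))
    out <- hybrid_step(des, meas, stats::runif(6, 0, 50), ms, cfg, mem)
    mem <- out$memory
    expect_true(all(out$forces >= ms$f_lower - 1e-9))
    expect_true(all(out$forces <= ms$f_upper + 1e-9))
  }
})

test_that("hybrid error-to-force mapping points the right way", {
  ms <- default_muscle_set()
  cfg <- hybrid_config(ki = 0, kd = 0)
  mem <- controller_memory("hybrid")
  # flexion shortfall: flexors (positive FE arms) must be commanded up
  out <- hybrid_step(wrist_state(10, 0), wrist_state(0, 0), rep(10, 6), ms,
                     cfg, mem)
  base <- hybrid_step(wrist_state(0, 0), wrist_state(0, 0), rep(10, 6), ms,
                      cfg, mem)$forces
  delta <- out$forces - base
  expect_true(all(delta[c("FCR", "FCU", "APL")] > 0))
  expect_true(all(delta[c("ECRL", "ECRB", "ECU")] < 0))
})

test_that("cascade at zero error with zero lower bounds commands zero force", {
  ms <- muscle_set(default_muscle_set()$R, default_muscle_set()$pcsa,
                   f_lower = rep(0, 6))
  sp <- specimen_model(ms, 0.4, 0.07, 0.002, 0.002, 0.008, 0.0006)
  cfg <- cascade_config(gravity_feedforward = FALSE)
  st <- wrist_state(0, 0)
  out <- cascade_step(st, st, rep(0, 6), ms, sp, "vertical_up", cfg,
                      controller_memory("cascade"))
  expect_equal(unname(out$forces), rep(0, 6), tolerance = 1e-9)
  expect_true(out$feasible)
})

test_that("cascade commands respect force bounds and the impedance cap", {
  sp <- default_specimen()
  ms <- sp$muscles
  cfg <- cascade_config()
  mem <- controller_memory("cascade")
  set.seed(8)
  for (i in 1:100) {
    des <- wrist_state(stats::runif(1, -40, 40), stats::runif(1, -15, 15))
    meas <- wrist_state(stats::runif(1, -40, 40), stats::runif(1, -15, 15))
    out <- cascade_step(des, meas, stats::runif(6, 0, 30), ms, sp,
                        sample(orientations(), 1), cfg, mem)
    mem <- out$memory
    expect_true(all(out$forces >= ms$f_lower - 1e-9))
    expect_true(all(out$forces <= ms$f_upper + 1e-9))
    expect_lte(sum(out$forces), cfg$rho_max + 1e-9)
    expect_gte(sum(out$forces), cfg$rho_min - 1e-9)
  }
})

test_that("holding neutral horizontally demands more extensor force than vertical", {
  sp <- default_specimen()
  cal <- calibrate_specimen(sp)
  hold <- function(orientation) {
    rec <- run_simulation(sp, trajectory_spec("FE30", amplitude_scale = 0,
                                              n_cycles = 1),
                          "cascade", orientation, muscles_ctrl = cal$muscles,
                          noise = noise_config(0, 0), settle_time = 2)
    gf <- group_forces(rec)
    mean(gf$extensor_N[rec$time_s > 2])
  }
  ext_h <- hold("horizontal_palm_down")
  expect_gt(ext_h, hold("vertical_up"))
  expect_gt(ext_h, hold("vertical_down"))
})

test_that("closed-loop runs are deterministic given the seed", {
  sp <- default_specimen()
  r1 <- run_simulation(sp, trajectory_spec("FE30", n_cycles = 1), "hybrid",
                       seed = 123)
  r2 <- run_simulation(sp, trajectory_spec("FE30", n_cycles = 1), "hybrid",
                       seed = 123)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_simulation(sp, trajectory_spec("FE30", n_cycles = 1), "hybrid",
                       seed = 124)
  expect_false(identical(r1$theta_fe_deg, r3$theta_fe_deg))
})

test_that("hybrid tracks FE-30 closely in the vertical-up orientation", {
  sp <- default_specimen()
  cal <- calibrate_specimen(sp)
  rec <- run_simulation(sp, trajectory_spec("FE30", n_cycles = 2), "hybrid",
                        "vertical_up", muscles_ctrl = cal$muscles, seed = 42)
  ke <- kinematic_error(rec)
  expect_lt(ke$in_plane, 1.0)
  expect_lt(ke$out_of_plane, 0.2)
  expect_false(record_meta(rec)$flagged)
})

test_that("an uncontrolled flexed hand falls through to the stop and is flagged", {
  # heavy hand held up, negligible passive stiffness: the inverted pendulum
  # falls onto the flexion stop and gravity pins it there
  sp <- toy_specimen(hand_mass = 2, stiffness = 1e-4)
  limp <- hybrid_config(kp = 0, ki = 0, kd = 0, baseline = 2.5)
  rec <- run_simulation(sp, trajectory_spec("FE30", n_cycles = 1), "hybrid",
                        "vertical_up", cfg = limp,
                        noise = noise_config(0, 0), settle_time = 0,
                        initial_state = wrist_state(30, 0))
  expect_true(record_meta(rec)$flagged)
  expect_gt(record_meta(rec)$stop_fraction, 0.10)
})
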