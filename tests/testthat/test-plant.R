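# Forward-dynamics plant: gravity moments, muscle torque mapping,
# integration, tendon excursions.

test_that("gravity torque matches the m*g*d closed forms", {
  sp <- toy_specimen()   # 0.4 kg, 0.07 m
  mgd <- 0.4 * 9.81 * 0.07

  # vertical at neutral: no moment
  expect_equal(unname(gravity_torque(wrist_state(0, 0), "vertical_up", sp)),
               c(0, 0), tolerance = 1e-12)
  expect_equal(unname(gravity_torque(wrist_state(0, 0), "vertical_down", sp)),
               c(0, 0), tolerance = 1e-12)

  # horizontal at neutral: full lever arm, flexion sense
  tq <- gravity_torque(wrist_state(0, 0), "horizontal_palm_down", sp)
  expect_equal(unname(tq[1]), mgd, tolerance = 1e-9)
  expect_gt(tq[1], 0)               # flexion direction: extensors counteract
  expect_equal(unname(tq[2]), 0, tolerance = 1e-12)

  # vertical-up flexed: m*g*d*sin(theta), destabilising (flexion sense)
  tq30 <- gravity_torque(wrist_state(30, 0), "vertical_up", sp)
  expect_equal(unname(tq30[1]), mgd * sin(pi / 6), tolerance = 1e-9)
  expect_gt(tq30[1], 0)

  # horizontal flexed: m*g*d*cos(theta)
  tqh <- gravity_torque(wrist_state(30, 0), "horizontal_palm_down", sp)
  expect_equal(unname(tqh[1]), mgd * cos(pi / 6), tolerance = 1e-9)
})

test_that("vertical-up gravity is the negation of vertical-down", {
  sp <- toy_specimen()
  for (st in list(wrist_state(25, -10), wrist_state(-40, 20), wrist_state(5, 5))) {
    expect_equal(gravity_torque(st, "vertical_up", sp),
                 -gravity_torque(st, "vertical_down", sp), tolerance = 1e-12)
  }
})

test_that("horizontal FE gravity moment dominates both verticals at neutral", {
  for (m in c(0.25, 0.4, 0.6)) for (d in c(0.05, 0.09)) {
    sp <- toy_specimen(hand_mass = m, com_distance = d)
    h <- abs(gravity_torque(wrist_state(0, 0), "horizontal_palm_down", sp)[1])
    u <- abs(gravity_torque(wrist_state(0, 0), "vertical_up", sp)[1])
    dn <- abs(gravity_torque(wrist_state(0, 0), "vertical_down", sp)[1])
    expect_gt(h, u); expect_gt(h, dn)
  }
})

test_that("muscle torque is the moment-arm map, linear, and rejects pushing", {
  ms <- default_muscle_set()
  expect_equal(unname(muscle_torque(rep(0, 6), ms)), c(0, 0))

  # single muscle: R column (15, 0) mm at 10 N -> 0.15 N m about FE
  ms1 <- muscle_set(rbind(c(15, 10, -12, -9, -6, 5), c(0, 11, -14, -4, 13, -15)),
                    pcsa = rep(2, 6))
  expect_equal(unname(muscle_torque(c(10, 0, 0, 0, 0, 0), ms1)), c(0.15, 0),
               tolerance = 1e-12)

  # antagonist cancellation: equal forces on +/-12 mm arms, zero RUD columns
  ms2 <- muscle_set(rbind(c(12, -12, 5, -5, 3, 3), c(0, 0, 4, 4, -4, -4)),
                    pcsa = rep(2, 6))
  expect_equal(unname(muscle_torque(c(10, 10, 0, 0, 0, 0), ms2)), c(0, 0),
               tolerance = 1e-12)

  # linearity
  f1 <- c(3, 7, 2, 8, 1, 4); f2 <- c(1, 0, 5, 2, 9, 3)
  expect_equal(muscle_torque(f1 + f2, ms),
               muscle_torque(f1, ms) + muscle_torque(f2, ms), tolerance = 1e-12)

  expect_error(muscle_torque(c(-1, 0, 0, 0, 0, 0), ms), "push")
})

test_that("step_dynamics holds equilibrium, integrates torque, clamps stops", {
  sp <- toy_specimen()
  # vertical, neutral, zero velocity, zero force: equilibrium
  st <- wrist_state(0, 0)
  for (i in 1:50) st <- step_dynamics(st, rep(0, 6), "vertical_up", sp)
  expect_equal(st$theta_fe, 0, tolerance = 1e-12)
  expect_equal(st$omega_rud, 0, tolerance = 1e-12)

  # constant torque, no passive/gravity: omega ~ (tau/I) * t
  sp2 <- toy_specimen(hand_mass = 1e-8, com_distance = 1e-8,
                      stiffness = 1e-10, damping = 1e-10)
  f <- c(10, 0, 0, 0, 0, 0)                 # FE arm 15 mm -> tau = 0.15 N m
  st <- wrist_state(0, 0); n <- 100; dt <- 1e-3
  for (i in 1:n) st <- step_dynamics(st, f, "vertical_up", sp2, dt)
  expect_equal(st$omega_fe, (0.15 / 0.002) * n * dt * 180 / pi,
               tolerance = 0.01)

  # anatomical stop: strong flexion drive ends clamped with zero velocity
  st <- wrist_state(85, 0, 500, 0)
  for (i in 1:200) st <- step_dynamics(st, c(60, 0, 0, 0, 0, 0), "vertical_up", sp)
  expect_equal(st$theta_fe, 90)
  expect_equal(st$omega_fe, 0)

  expect_error(step_dynamics(wrist_state(0, 0), rep(NaN, 6), "vertical_up", sp))
  expect_error(step_dynamics(wrist_state(0, 0), rep(0, 6), "vertical_up", sp,
                             dt = 0.5), "dt")
})

test_that("passive motion dissipates mechanical energy", {
  sp <- toy_specimen()
  mgd <- sp$hand_mass * sp$gravity_accel * sp$com_distance
  energy <- function(st, orientation) {
    deg <- pi / 180
    ke <- 0.5 * sp$inertia_fe * (st$omega_fe * deg)^2 +
      0.5 * sp$inertia_rud * (st$omega_rud * deg)^2
    pe_k <- 0.5 * (sp$passive_stiffness[1] * 180 / pi) * (st$theta_fe * deg)^2 +
      0.5 * (sp$passive_stiffness[2] * 180 / pi) * (st$theta_rud * deg)^2
    hgt <- cos(st$theta_fe * deg) * cos(st$theta_rud * deg)
    pe_g <- switch(orientation, vertical_up = mgd * hgt,
                   vertical_down = -mgd * hgt, horizontal_palm_down =
                     -mgd * sin(st$theta_fe * deg) * cos(st$theta_rud * deg))
    unname(ke + pe_k + pe_g)
  }
  for (orient in orientations()) {
    st <- wrist_state(35, -20, 40, 10)
    e0 <- e <- energy(st, orient)
    for (i in 1:2000) {
      st <- step_dynamics(st, rep(0, 6), orient, sp)
      e2 <- energy(st, orient)
      expect_lte(e2, e + 1e-6)     # discrete-step slack
      e <- e2
    }
    expect_lt(e, e0)               # net dissipation over the interval
  }
})

test_that("torque balance: finite-difference acceleration matches the torque sum", {
  sp <- toy_specimen()
  st <- wrist_state(20, -10, 15, -5)
  f <- c(8, 6, 7, 5, 9, 4)
  dt <- 1e-3
  st2 <- step_dynamics(st, f, "horizontal_palm_down", sp, dt)
  acc_fd <- c(st2$omega_fe - st$omega_fe, st2$omega_rud - st$omega_rud) / dt
  tau <- muscle_torque(f, sp$muscles) +
    gravity_torque(st, "horizontal_palm_down", sp) -
    sp$passive_stiffness * c(st$theta_fe, st$theta_rud) -
    sp$passive_damping * c(st$omega_fe, st$omega_rud)
  acc_expect <- unname(tau / c(sp$inertia_fe, sp$inertia_rud) * 180 / pi)
  expect_equal(acc_fd, acc_expect, tolerance = 1e-9)
})

test_that("tendon excursions follow the arc-length rule and mirror symmetry", {
  sp <- toy_specimen()
  ms <- sp$muscles
  expect_equal(unname(tendon_excursions(wrist_state(0, 0), ms)), rep(0, 6))

  # FCR: FE arm 15 mm, flexion 30 deg -> |excursion| = 15 * 30 * pi / 180
  exc <- tendon_excursions(wrist_state(30, 0), ms)
  expect_equal(abs(unname(exc["FCR"])), 15 * 30 * pi / 180, tolerance = 1e-12)
  # sign convention: moment arm is minus the excursion/angle slope
  expect_equal(unname(-exc["FCR"] / (30 * pi / 180)), 15, tolerance = 1e-12)

  # states mirrored about neutral give opposite excursions
  e1 <- tendon_excursions(wrist_state(20, -12), ms)
  e2 <- tendon_excursions(wrist_state(-20, 12), ms)
  expect_equal(e1, -e2, tolerance = 1e-12)

  # duality: d(excursion)/d(theta) = -R exactly for constant arms
  h <- 1e-6
  for (ax in 1:2) {
    stp <- if (ax == 1) wrist_state(h * 180 / pi, 0) else wrist_state(0, h * 180 / pi)
    grad <- tendon_excursions(stp, ms) / h
    expect_equal(unname(grad), unname(-ms$R[ax, ]), tolerance = 1e-6)
  }
})

test_that("wrist_state enforces finiteness and anatomical stops", {
  expect_error(wrist_state(NA, 0), "finite")
  expect_error(wrist_state(95, 0), "stops")
  expect_error(wrist_state(0, -50), "stops")
  expect_silent(wrist_state(90, 45))
})
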