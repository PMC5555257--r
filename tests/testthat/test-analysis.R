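# Outcome metrics: kinematic error, waypoint forces, repeatability,
# group forces, peak/mean forces.

test_that("kinematic error reproduces constant and sinusoidal closed forms", {
  tt <- seq(0, 4, by = 0.01)
  des <- 30 * sin(2 * pi * tt / 4)

  perfect <- make_record(tt, des, 0 * tt, des, 0 * tt, 5)
  expect_equal(kinematic_error(perfect)$fe, 0)
  expect_equal(kinematic_error(perfect)$rud, 0)

  offset <- make_record(tt, des + 2, 0 * tt, des, 0 * tt, 5)
  expect_equal(kinematic_error(offset)$in_plane, 2, tolerance = 1e-12)

  # sinusoidal error of amplitude a has mean |error| = 2a/pi
  a <- 1.7
  tt2 <- seq(0, 4, length.out = 40001)[-40001]   # uniform over whole periods
  sine <- make_record(tt2, 30 * sin(2 * pi * tt2 / 4) + a * sin(2 * pi * tt2 / 4 * 3),
                      0 * tt2, 30 * sin(2 * pi * tt2 / 4), 0 * tt2, 5)
  expect_equal(kinematic_error(sine)$in_plane, 2 * a / pi, tolerance = 1e-6)

  # axis-to-plane assignment follows the motion
  rud_rec <- make_record(tt, 0 * tt, des / 3 + 0.5, 0 * tt, des / 3,
                         5, motion = "RUD10")
  expect_equal(kinematic_error(rud_rec)$in_plane, 0.5, tolerance = 1e-12)
  expect_equal(kinematic_error(rud_rec)$out_of_plane, 0, tolerance = 1e-12)

  expect_error(kinematic_error(perfect[0, ]), "empty")
})

test_that("kinematic error is invariant to time reversal", {
  tt <- seq(0, 4, by = 0.01)
  des <- 30 * sin(2 * pi * tt / 4)
  meas <- des + stats::rnorm(length(tt), 0, 0.5)
  fwd <- make_record(tt, meas, 0 * tt, des, 0 * tt, 5)
  rev <- make_record(tt, rev(meas), 0 * tt, rev(des), 0 * tt, 5)
  expect_equal(kinematic_error(fwd)$fe, kinematic_error(rev)$fe)
})

test_that("FE-30 waypoints appear at 10-degree multiples, twice except extrema", {
  tt <- seq(0, 8, by = 0.01)
  des <- 30 * sin(2 * pi * tt / 4)
  rec <- make_record(tt, des, 0 * tt, des, 0 * tt, 5, n_cycles = 2, period = 4)
  wp <- waypoint_forces(rec)
  expect_setequal(unique(wp$waypoint_deg), seq(-30, 30, by = 10))
  cnt <- table(wp$waypoint_deg[wp$muscle == "FCR" & wp$cycle == 1])
  expect_true(all(cnt[c("-20", "-10", "0", "10", "20")] == 2))
  expect_true(all(cnt[c("-30", "30")] == 1))
})

test_that("waypoint interpolation is exact on force data linear in angle", {
  tt <- seq(0, 4, by = 0.01)
  ang <- 30 * sin(2 * pi * tt / 4)
  F <- matrix(rep(2 + 0.1 * ang, 6), ncol = 6)
  rec <- make_record(tt, ang, 0 * tt, ang, 0 * tt, F)
  wp <- waypoint_forces(rec)
  expect_equal(wp$force_N, 2 + 0.1 * wp$waypoint_deg, tolerance = 1e-9)
})

test_that("constant-force records give the constant at every waypoint", {
  tt <- seq(0, 4, by = 0.01)
  ang <- 30 * sin(2 * pi * tt / 4)
  rec <- make_record(tt, ang, 0 * tt, ang, 0 * tt, 7.25)
  wp <- waypoint_forces(rec)
  expect_true(all(wp$force_N == 7.25))
})

test_that("repeatability is the cross-cycle SD, with scaling homogeneity", {
  tt <- seq(0, 8, by = 0.01)
  ang <- 30 * sin(2 * pi * tt / 4)
  # identical cycles: all SDs zero
  rec <- make_record(tt, ang, 0 * tt, ang, 0 * tt, 5, n_cycles = 2, period = 4)
  rp <- repeatability(waypoint_forces(rec))
  expect_true(all(rp$per_waypoint$sd_N == 0))
  expect_equal(rp$specimen_mean_sd, 0)

  # cycles at F+1 and F-1: SD = sqrt(2) at every waypoint
  F2 <- matrix(ifelse(tt < 4, 6, 4), length(tt), 6)
  rec2 <- make_record(tt, ang, 0 * tt, ang, 0 * tt, F2, n_cycles = 2, period = 4)
  rp2 <- repeatability(waypoint_forces(rec2))
  expect_equal(unique(round(rp2$per_waypoint$sd_N, 10)), round(sqrt(2), 10))

  # scaling all forces by c scales all SDs by |c|
  rec3 <- make_record(tt, ang, 0 * tt, ang, 0 * tt, 3 * F2,
                      n_cycles = 2, period = 4)
  rp3 <- repeatability(waypoint_forces(rec3))
  expect_equal(rp3$specimen_mean_sd, 3 * rp2$specimen_mean_sd, tolerance = 1e-9)

  # single cycle is an error
  rec1 <- make_record(seq(0, 4, by = 0.01), ang[tt <= 4], 0, ang[tt <= 4], 0, 5)
  expect_error(repeatability(waypoint_forces(rec1)), "2 cycles")
})

test_that("group forces partition the six muscles into flexors and extensors", {
  tt <- seq(0, 1, by = 0.1)
  F <- matrix(1, length(tt), 6)
  rec <- make_record(tt, 0 * tt, 0 * tt, 0 * tt, 0 * tt, F)
  gf <- group_forces(rec)
  expect_true(all(gf$flexor_N == 3) && all(gf$extensor_N == 3))

  F2 <- matrix(stats::runif(length(tt) * 6), length(tt), 6)
  rec2 <- make_record(tt, 0 * tt, 0 * tt, 0 * tt, 0 * tt, F2)
  gf2 <- group_forces(rec2)
  expect_equal(gf2$flexor_N + gf2$extensor_N, rowSums(F2), tolerance = 1e-12)
  # zeroing APL removes exactly the APL series from the flexor sum
  F3 <- F2; F3[, 6] <- 0
  rec3 <- make_record(tt, 0 * tt, 0 * tt, 0 * tt, 0 * tt, F3)
  expect_equal(group_forces(rec3)$flexor_N, gf2$flexor_N - F2[, 6],
               tolerance = 1e-12)
})

test_that("peak and mean forces match constants and the triangular pulse", {
  tt <- seq(0, 4, length.out = 401)
  rec <- make_record(tt, 0 * tt, 0 * tt, 0 * tt, 0 * tt, 6.5)
  pm <- peak_mean_forces(rec)
  expect_true(all(pm$peak_N == 6.5) && all(pm$mean_N == 6.5))

  # triangular pulse of height h over fraction phi of the cycle: mean = h*phi/2
  h <- 10; phi <- 0.25
  pulse <- pmax(0, h * (1 - abs(tt - 1) / (phi * 4 / 2)))
  F <- matrix(rep(pulse, 6), ncol = 6)
  rec2 <- make_record(tt, 0 * tt, 0 * tt, 0 * tt, 0 * tt, F)
  pm2 <- peak_mean_forces(rec2)
  expect_equal(pm2$mean_N[1], h * phi / 2, tolerance = 0.01)
  expect_equal(pm2$peak_N[1], h, tolerance = 1e-9)
  expect_true(all(pm2$peak_N >= pm2$mean_N))
})
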