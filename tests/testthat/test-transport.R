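# Transport: flow profile, body forces, wall corrections, trajectory
# integration and the velocity observable.

test_that("parabolic flow profile: maximum, no-slip and mean", {
  H <- 50e-6
  expect_equal(fluid_velocity(H / 2, 1e-3, H), 1.5e-3)
  expect_equal(fluid_velocity(0, 1e-3, H), 0)
  expect_equal(fluid_velocity(H, 1e-3, H), 0)
  # height-average equals vbar (midpoint rule)
  n <- 20000
  hh <- (seq_len(n) - 0.5) * H / n
  expect_equal(mean(fluid_velocity(hh, 1e-3, H)), 1e-3,
               tolerance = 1e-6)
  expect_error(fluid_velocity(-1e-6, 1e-3, H), "outside")
})

test_that("gravity/buoyancy force matches hand evaluations", {
  expect_equal(gravity_buoyancy(1e-6, 1000, 1000), 0)
  # 6.25 um CHO cell in 1017.5 kg/m3 medium: 3.27e-13 N downward
  expect_equal(gravity_buoyancy(6.25e-6, 1050, 1017.5), -3.266e-13,
               tolerance = 1e-3)
  # 5 um PSS in water: 2.57e-13 N downward
  expect_equal(gravity_buoyancy(5e-6, 1050, 1000), -2.566e-13,
               tolerance = 1e-3)
})

test_that("lift force sign convention and mid-channel null", {
  H <- 50e-6
  expect_identical(lift_force(H / 2, 5e-6, 1e-3, 1e-3, H), 0)
  expect_gt(lift_force(10e-6, 5e-6, 1e-3, 1e-3, H), 0)
  expect_lt(lift_force(40e-6, 5e-6, 1e-3, 1e-3, H), 0)
  # symmetric magnitudes about mid-channel
  expect_equal(lift_force(10e-6, 5e-6, 1e-3, 1e-3, H),
               -lift_force(40e-6, 5e-6, 1e-3, 1e-3, H))
  expect_warning(lift_force(5e-6, 5e-6, 1e-3, 1e-3, H), "contact")
  # alternative closure plugs in
  f <- lift_force(10e-6, 5e-6, 1e-3, 1e-3, H, form = lift_clearance_sq)
  expect_equal(f, 6 * 0.31 * 1e-3 * 1e-3 * (5e-6)^3 / (5e-6)^2)
})

test_that("wall drag correction: limits, symmetry and series", {
  H <- 50e-6
  expect_equal(wall_drag_lambda(H / 2, H * 1e-4, H), 1, tolerance = 1e-3)
  expect_equal(wall_drag_lambda(15e-6, 4e-6, H),
               wall_drag_lambda(H - 15e-6, 4e-6, H))
  # approaches either wall monotonically
  hh <- seq(6e-6, 25e-6, length.out = 40)
  lam <- vapply(hh, wall_drag_lambda, numeric(1), r = 5e-6, H = H)
  expect_true(all(diff(lam) < 0))
  # small-ratio regime matches the 9/8 first-order coefficient
  xi <- 0.02
  lam1 <- wall_drag_lambda(5e-6 / xi, 5e-6, 1)  # far from the top wall
  expect_equal(lam1 - 1, 9 / 8 * xi, tolerance = 0.05)
  expect_error(wall_drag_lambda(4e-6, 5e-6, H), "overlap")
})

test_that("overdamped numbers are small for the reference device", {
  p <- transport_params(cho_medium(), r = 6.25e-6, vbar = 1000e-6)
  nums <- expect_silent(check_overdamped(p))
  expect_lt(nums["reynolds"], 0.1)
  expect_lt(nums["stokes"], 0.1)
})

test_that("equilibrium height sits below mid-channel in the operating
           band and responds to density", {
  # reference CHO cell: equilibrium in the lower half-channel with an
  # advection velocity inside the 800-1200 um/s operating band
  p <- transport_params(cho_medium(), r = 6.25e-6, vbar = 1000e-6)
  he <- equilibrium_height(p)
  expect_gt(he, 6.25e-6)
  expect_lt(he, 25e-6)
  v_eq <- fluid_velocity(he, 1000e-6, 50e-6)
  expect_gt(v_eq, 800e-6)
  expect_lt(v_eq, 1200e-6)
  # at the root, lift balances weight
  bal <- lift_force(he, p$r, p$vbar, p$medium$viscosity, p$H, p$C) +
    gravity_buoyancy(p$r, p$rho_p, p$medium$density)
  expect_lt(abs(bal), 1e-18)
  # a denser particle settles lower
  pd <- transport_params(dep_medium(78, 0.17, density = 1000),
                         r = 6.25e-6, rho_p = 1200, vbar = 1000e-6)
  expect_lt(equilibrium_height(pd), he)
  # neutral buoyancy rides at mid-channel
  pn <- transport_params(dep_medium(78, 0.17, density = 1050),
                         r = 6.25e-6, rho_p = 1050, vbar = 1000e-6)
  expect_equal(equilibrium_height(pn), 25e-6)
})

test_that("trajectories: null actuation keeps height and velocity", {
  fg <- default_field()
  p <- transport_params(cho_medium(), r = 6.25e-6, re_kcm = 0,
                        vbar = 1000e-6)
  tr <- simulate_trajectory(p, fg)
  expect_false(tr$captured)
  expect_lt(abs(tr$vdiff), 1e-3 * tr$vi)
  expect_lt(max(abs(tr$path$h_m - tr$entry_h)), 0.1e-6)
})

test_that("pDEP slows cells down and nDEP speeds them up", {
  fg <- default_field()
  pv <- transport_params(cho_medium(), r = 6.25e-6, re_kcm = 0.353,
                         vbar = 1000e-6)
  tv <- simulate_trajectory(pv, fg)
  expect_gt(tv$vdiff, 0)      # vo < vi
  pn <- transport_params(cho_medium(), r = 5.5e-6, re_kcm = -0.199,
                         vbar = 1000e-6)
  tn <- simulate_trajectory(pn, fg)
  expect_lt(tn$vdiff, 0)      # vo > vi
  # the nDEP cell rises over the electrodes
  over <- tn$path$x_m > fg$x_e1 & tn$path$x_m < fg$x_e2 + 100e-6
  expect_gt(max(tn$path$h_m[over]), tn$entry_h)
})

test_that("vdiff is monotone in Re{Kcm} and decreases with faster entry", {
  fg <- default_field()
  ks <- seq(-0.5, 1, length.out = 10)
  vd <- vapply(ks, function(k) {
    p <- transport_params(cho_medium(), r = 6e-6, re_kcm = k,
                          vbar = 1000e-6)
    simulate_trajectory(p, fg, entry_h = 11e-6, n_out = 150)$vdiff
  }, numeric(1))
  expect_true(all(diff(vd) > 0))
  # incoming velocity is strictly monotone in entry height on the
  # lower half-channel (the vi -> height root-find is well posed), and
  # in this lift closure the pDEP response grows with entry height
  # (the near-wall lift stiffens faster than the DEP force)
  p <- transport_params(cho_medium(), r = 6e-6, re_kcm = 0.3,
                        vbar = 1000e-6)
  t1 <- simulate_trajectory(p, fg, entry_h = 9e-6)
  t2 <- simulate_trajectory(p, fg, entry_h = 14e-6)
  expect_gt(t2$vi, t1$vi)
  expect_gt(t2$vdiff, t1$vdiff)
})

test_that("symmetric null: no gravity contrast, no lift, no DEP leaves
           the height exactly constant", {
  fg <- default_field()
  med <- dep_medium(78, 0.17, density = 1050)
  p <- transport_params(med, r = 6e-6, rho_p = 1050, re_kcm = 0,
                        vbar = 1000e-6, C = 0)
  tr <- simulate_trajectory(p, fg, entry_h = 12e-6)
  expect_lt(max(abs(tr$path$h_m - 12e-6)), 1e-12)
  expect_lt(abs(tr$vdiff) / tr$vi, 1e-9)
})

test_that("strong pDEP capture is flagged", {
  # without the diverging near-wall lift (C = 0) a strong pDEP pull
  # drives the cell into floor contact
  fg <- default_field()
  p <- transport_params(cho_medium(), r = 7.5e-6, re_kcm = 1,
                        vbar = 400e-6, C = 0)
  tr <- suppressWarnings(simulate_trajectory(p, fg, entry_h = 9e-6))
  expect_true(tr$captured)
})

test_that("adaptive integration matches the fixed fine-step oracle", {
  fg <- default_field()
  p <- transport_params(cho_medium(), r = 6.25e-6, re_kcm = 0.353,
                        vbar = 1000e-6)
  tr <- simulate_trajectory(p, fg, entry_h = 11e-6)
  dx_adaptive <- diff(tr$path$x_m[1:2])
  ref <- rk4_trajectory(p, fg, entry_h = 11e-6,
                        x_start = fg$x[1], x_end = max(fg$x),
                        dx = dx_adaptive / 100)
  expect_equal(tr$vdiff, ref$vdiff, tolerance = 5e-3)
  expect_equal(tr$vi, ref$vi, tolerance = 1e-3)
})

test_that("trajectory CSV export has the documented columns", {
  fg <- default_field()
  p <- transport_params(cho_medium(), r = 6e-6, re_kcm = 0.2,
                        vbar = 1000e-6)
  tr <- simulate_trajectory(p, fg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("t_s", "x_m", "h_m", "vx_m_per_s"))
  expect_true(all(diff(df$t_s) > 0))
})
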