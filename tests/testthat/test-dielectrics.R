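# Dielectric models: complex permittivity, Clausius-Mossotti factor,
# shelled-sphere reduction, spectra, crossovers and sensitivity bands.

test_that("complex permittivity matches hand-evaluated values", {
  # lossless medium: purely real
  e <- complex_permittivity(78, 0, 1e6)
  expect_equal(Re(e), 78 * EPS0)
  expect_identical(Im(e), 0)
  # hand evaluations of eps0*er - j sigma/omega
  e1 <- complex_permittivity(78, 0.17, 6e6)
  expect_equal(Re(e1), 6.906e-10, tolerance = 1e-3)
  expect_equal(Im(e1), -4.509e-9, tolerance = 1e-3)
  e2 <- complex_permittivity(2.5, 2.548e-4, 1e6)
  expect_equal(Re(e2), 2.214e-11, tolerance = 1e-3)
  expect_equal(Im(e2), -4.055e-11, tolerance = 1e-3)
  expect_error(complex_permittivity(78, 0.1, 0), "frequency")
  expect_error(complex_permittivity(78, 0.1, -5), "frequency")
})

test_that("Clausius-Mossotti factor limits and the PSS working point", {
  em <- complex_permittivity(78, 0.1, 1e6)
  expect_equal(clausius_mossotti(em, em), 0 + 0i)
  # perfect-conductor and void limits
  expect_equal(Re(clausius_mossotti(em * 1e12, em)), 1, tolerance = 1e-9)
  expect_equal(Re(clausius_mossotti(em * 1e-12, em)), -0.5,
               tolerance = 1e-9)
  # 15.7 um PSS in DI water at 1 MHz sits near the nDEP plateau
  pss <- pss_sphere(15.7e-6 / 2)
  di <- dep_medium(78, 5.5e-6, density = 1000)
  k <- re_kcm_at(pss, di, 1e6)
  expect_equal(k, -0.4751, tolerance = 1e-3)
  expect_equal(round(k, 1), -0.5)
})

test_that("shell reduction is exact in degenerate limits", {
  ei <- complex_permittivity(60, 0.5, 1e6)
  es <- complex_permittivity(10, 1e-6, 1e6)
  expect_equal(shell_reduce(ei, ei, 4e-6, 5e-6), ei)
  expect_equal(shell_reduce(ei, es, 5e-6, 5e-6), ei)
})

test_that("nucleus-stage reduction reproduces the frozen oracle value", {
  # independently evaluated equivalent conductivity of the viable
  # nucleoplasm+envelope stage at 6 MHz: 0.1371 S/m
  cv <- dep_preset("cho_viable")
  e_np <- complex_permittivity(cv$eps_n, cv$sigma_n, 6e6)
  e_ne <- complex_permittivity(cv$eps_ne, cv$sigma_ne, 6e6)
  e1 <- shell_reduce(e_np, e_ne, cv$r_n - cv$d_n, cv$r_n)
  expect_equal(-Im(e1) * 2 * pi * 6e6, 0.13708, tolerance = 1e-3)
})

test_that("double-shell CHO models give the frozen Re{Kcm} at 6 MHz", {
  m <- cho_medium()
  # frozen from an independent evaluation of the reduction chain
  expect_equal(re_kcm_at(dep_preset("cho_viable"), m, 6e6),
               0.35310, tolerance = 1e-4)
  expect_equal(re_kcm_at(dep_preset("cho_nonviable"), m, 6e6),
               -0.19876, tolerance = 1e-4)
  # all compartments identical collapses to that homogeneous sphere
  cell <- double_shell_cell(6.25e-6, sigma_mem = 0.5, sigma_ne = 0.5,
                            sigma_cyt = 0.5, sigma_n = 0.5,
                            eps_mem = 60, eps_ne = 60, eps_cyt = 60,
                            eps_n = 60)
  expect_equal(particle_permittivity(cell, 2e6),
               complex_permittivity(60, 0.5, 2e6), tolerance = 1e-12)
})

test_that("spectra respect the CMF bound and the high-frequency limit", {
  m <- cho_medium()
  f <- default_frequency_grid(200)
  for (preset in c("cho_viable", "cho_nonviable")) {
    sp <- cmf_spectrum(dep_preset(preset), m, f)
    expect_true(all(Re(sp$kcm) >= -0.5 - 1e-9))
    expect_true(all(Re(sp$kcm) <= 1 + 1e-9))
  }
  # random physical double-shell models stay within [-0.5, 1]
  set.seed(42)
  for (i in 1:1000) {
    r_cell <- runif(1, 3e-6, 10e-6)
    cell <- double_shell_cell(
      r_cell, d_n = 40e-9, d_mem = 5e-9,
      sigma_mem = 10^runif(1, -7, -3), sigma_ne = 10^runif(1, -4, -1),
      sigma_cyt = runif(1, 0.05, 1.5), sigma_n = runif(1, 0.1, 2),
      eps_mem = runif(1, 2, 20), eps_ne = runif(1, 5, 30),
      eps_cyt = runif(1, 40, 80), eps_n = runif(1, 40, 150))
    med <- dep_medium(runif(1, 20, 80), runif(1, 1e-4, 1))
    k <- re_kcm_at(cell, med, 10^runif(1, 4, 9))
    expect_gte(k, -0.5 - 1e-9)
    expect_lte(k, 1 + 1e-9)
  }
  # f -> infinity limit matches the pure-permittivity contrast
  cell <- dep_preset("cho_viable")
  k_inf <- re_kcm_at(cell, m, 1e10)
  # equivalent permittivity at 10 GHz is conductivity-free to ~1e-3
  ep <- particle_permittivity(cell, 1e10)
  lim <- Re((ep - 78 * EPS0) / (ep + 2 * 78 * EPS0))
  expect_equal(k_inf, lim, tolerance = 1e-3)
})

test_that("homogeneous-sphere CMF reaches its closed-form limits", {
  # low-frequency limit: conductivity contrast
  sph <- pss_sphere(5e-6, rel_permittivity = 2.5, k_surf = 1e-9)
  med <- dep_medium(78, 1e-3)
  sp <- sph$conductivity; sm <- 1e-3
  low <- (sp - sm) / (sp + 2 * sm)
  expect_equal(re_kcm_at(sph, med, 10), low, tolerance = 1e-3)
  high <- (2.5 - 78) / (2.5 + 2 * 78)
  expect_equal(re_kcm_at(sph, med, 1e10), high, tolerance = 1e-3)
})

test_that("viable cells are pDEP and non-viable nDEP at 6 MHz, with a
           crossover in between", {
  m <- cho_medium()
  expect_gt(re_kcm_at(dep_preset("cho_viable"), m, 6e6), 0)
  expect_lt(re_kcm_at(dep_preset("cho_nonviable"), m, 6e6), 0)
  sp <- cmf_spectrum(dep_preset("cho_viable"), m)
  expect_true(length(sp$crossovers_hz) >= 1)
  # crossover root is a true sign change to the stated tolerance
  f0 <- sp$crossovers_hz[1]
  expect_lt(abs(re_kcm_at(dep_preset("cho_viable"), m, f0)), 1e-4)
  expect_error(cmf_spectrum(dep_preset("cho_viable"), m, numeric(0)),
               "empty")
})

test_that("sensitivity bands cover the nominal spectrum and reproduce
           the published parameter ranges", {
  m <- cho_medium()
  cell <- dep_preset("cho_viable")
  f <- default_frequency_grid(50)
  b0 <- sensitivity_band(cell, m, f, "sigma_cyt", fraction = 0)
  expect_equal(b0$lower, b0$nominal)
  expect_equal(b0$upper, b0$nominal)
  b <- sensitivity_band(cell, m, f, "sigma_cyt")
  expect_true(all(b$lower <= b$nominal + 1e-12))
  expect_true(all(b$upper >= b$nominal - 1e-12))
  # +/-20% endpoints: sigma_cyt 0.424-0.636 S/m, r_cell 5-7.5 um
  expect_equal(b$values, c(0.424, 0.636))
  br <- sensitivity_band(cell, m, f, "r_cell")
  expect_equal(br$values * 1e6, c(5, 7.5))
  expect_error(sensitivity_band(cell, m, f, "not_a_field"), "unknown")
})

test_that("presets round-trip through YAML and spectra through CSV", {
  p <- dep_preset("pss_10um")
  expect_s3_class(p, "pss_sphere")
  expect_equal(p$radius, 5e-6)
  expect_equal(p$conductivity, 2 * 1e-9 / 5e-6)
  expect_error(dep_preset("no_such_preset"), "unknown preset")
  sp <- cmf_spectrum(dep_preset("cho_viable"), cho_medium(),
                     default_frequency_grid(20))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, csv)
  df <- read.csv(csv)
  expect_named(df, c("frequency_hz", "re_kcm", "im_kcm"))
  expect_equal(df$re_kcm, Re(sp$kcm))
})
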