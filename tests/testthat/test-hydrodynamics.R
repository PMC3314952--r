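test_that("s20,w correction is the identity in water at 20 C and monotone in viscosity", {
  rho20 <- water_density(293.15)
  eta20 <- water_viscosity(293.15)
  expect_equal(standardize_s20w(1.45, 293.15, rho20, eta20, 0.73), 1.45)
  expect_gt(standardize_s20w(1.45, 293.15, rho20, eta20 * 1.2, 0.73), 1.45)

  # water at 10 C: factor is the viscosity ratio adjusted by buoyancy
  rho10 <- water_density(283.15)
  eta10 <- water_viscosity(283.15)
  got <- standardize_s20w(1.0, 283.15, rho10, eta10, 0.73)
  hand <- (eta10 / eta20) * (1 - 0.73 * rho20) / (1 - 0.73 * rho10)
  expect_equal(got, hand)
  expect_error(standardize_s20w(1, 293.15, 1.5, eta20, 0.73), "float")
})

test_that("Svedberg friction matches direct arithmetic and scales inversely with s", {
  f <- svedberg_friction(1.45, 10600, 0.73)
  expect_equal(f, 3.29e-8, tolerance = 0.005)
  expect_equal(svedberg_friction(2.9, 10600, 0.73), f / 2)
  expect_error(svedberg_friction(1.45, 10600, 1.1), "float")
})

test_that("the Stokes reference sphere has the anhydrous volume", {
  sph <- stokes_sphere(10600, 0.73)
  expect_equal(sph$r0_A, 14.5, tolerance = 0.005)
  expect_equal(sph$f0_g_s, 2.74e-8, tolerance = 0.005)
  # R0 ~ M^(1/3) at fixed vbar; f0 linear in R0
  expect_equal(stokes_sphere(8 * 10600, 0.73)$r0_A, 2 * sph$r0_A)
  expect_equal(stokes_sphere(8 * 10600, 0.73)$f0_g_s, 2 * sph$f0_g_s)
})

test_that("a perfect sphere returns f/f0 = 1 and Rh = R0 exactly", {
  sph <- stokes_sphere(10600, 0.73)
  f_sphere <- 6 * pi * (water_viscosity(293.15) / 100) * (sph$r0_A * 1e-8)
  hr <- hydrodynamic_radius(f_sphere, sph$f0_g_s, sph$r0_A)
  expect_equal(hr$f_ratio, 1, tolerance = 1e-10)
  expect_equal(hr$rh_A, sph$r0_A, tolerance = 1e-10)
  expect_warning(hydrodynamic_radius(0.9 * sph$f0_g_s, sph$f0_g_s, sph$r0_A),
                 "unphysical")
})

test_that("the measured chain reproduces the native protein's hydrodynamics", {
  rec <- sedimentation_chain(1.45, 293.15, water_density(293.15),
                             water_viscosity(293.15), 0.73, 10600)
  expect_equal(rec$f_ratio, 1.21, tolerance = 0.05)
  expect_equal(rec$rh_A, 17.8, tolerance = 0.05)
})

test_that("Rh decreases monotonically with s20,w at fixed mass and vbar", {
  s <- seq(0.8, 2.0, by = 0.2)
  rh <- vapply(s, function(si) {
    # high s values cross f/f0 = 1 and legitimately warn; only order matters here
    suppressWarnings(
      sedimentation_chain(si, 293.15, water_density(293.15),
                          water_viscosity(293.15), 0.73, 10600)$rh_A)
  }, numeric(1))
  expect_true(all(diff(rh) < 0))
})

test_that("the cgs chain agrees with an SI recomputation", {
  s <- 1.45e-13                       # s
  M_si <- 10.600                      # kg/mol
  rho_si <- water_density(293.15) * 1000   # kg/m^3
  vbar_si <- 0.73e-3                  # m^3/kg
  f_si <- M_si * (1 - vbar_si * rho_si) / (6.02214076e23 * s)  # kg/s
  f_cgs <- svedberg_friction(1.45, 10600, 0.73)
  expect_equal(f_si * 1000, f_cgs, tolerance = 1e-12)

  eta_si <- water_viscosity(293.15) * 1e-3   # Pa s
  r0_si <- (3 * M_si * vbar_si / (4 * pi * 6.02214076e23))^(1 / 3)  # m
  sph <- stokes_sphere(10600, 0.73)
  expect_equal(r0_si * 1e10, sph$r0_A, tolerance = 1e-12)
  expect_equal(6 * pi * eta_si * r0_si * 1000, sph$f0_g_s, tolerance = 1e-12)
})

test_that("empirical radius predictions follow the chain-length power laws", {
  expect_equal(wilkins_rh(94, "folded"), 17.7, tolerance = 0.005)
  expect_equal(wilkins_rh(94, "denatured"), 29.4, tolerance = 0.005)
  expect_equal(wilkins_rh(1, "folded"), 4.75)
  expect_error(wilkins_rh(94, "molten"))
  expect_error(wilkins_rh(0, "folded"), ">= 1")
})

test_that("compaction metrics report ratio and percent change", {
  cm <- compaction_metrics(24.6, 34.0)
  expect_equal(cm$ratio, 0.724, tolerance = 1e-3)
  expect_equal(cm$percent_more_compact, 27.6, tolerance = 1e-2)
  expect_equal(compaction_metrics(20, 20)$percent_more_compact, 0)
  exp_rec <- compaction_metrics((26.1 + 24.6) / 2, 17.8)
  expect_equal(exp_rec$ratio, 1.42, tolerance = 0.01)
})
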