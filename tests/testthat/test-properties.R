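test_that("Stokes-Einstein diffusivity matches hand evaluation and scales as 1/mu", {
  # kB*T/(6*pi*mu*r0) at 310 K, 0.38 nm, evaluated independently
  expect_equal(diffusivity(water_fluid, default_solute), 5.975307e-10,
               tolerance = 1e-6)
  expect_equal(diffusivity(gut_fluid(10), default_solute), 5.975307e-14,
               tolerance = 1e-6)
  # exact reciprocal scaling in viscosity
  expect_equal(diffusivity(gut_fluid(0.01), default_solute),
               diffusivity(water_fluid, default_solute) / 10)
  # strictly decreasing in viscosity
  mus <- c(0.001, 0.01, 0.1, 1, 10)
  Ds <- vapply(mus, function(m) diffusivity(gut_fluid(m), default_solute),
               numeric(1))
  expect_true(all(diff(Ds) < 0))
})

test_that("mass-transfer coefficient matches the Sherwood correlation", {
  K <- mass_transfer_coefficient(default_geometry, water_fluid, default_solute)
  expect_equal(K, 1.359948e-7, tolerance = 1e-6)
  expect_gte(K, 1e-7)  # fast-transfer regime at watery viscosity
  # halving the correlation diameter raises K by 2^(1/3)
  geo_half_d <- gut_geometry(diameter_d = 0.018)
  expect_equal(mass_transfer_coefficient(geo_half_d, water_fluid, default_solute),
               2^(1 / 3) * K)
})

test_that("K * mu^(2/3) is constant across the viscosity range", {
  mus <- exp(seq(log(1e-3), log(10), length.out = 9))
  Ks <- vapply(mus, function(m) {
    mass_transfer_coefficient(default_geometry, gut_fluid(m), default_solute)
  }, numeric(1))
  scaled <- Ks * mus^(2 / 3)
  expect_equal(max(scaled) / min(scaled), 1, tolerance = 1e-12)
})

test_that("Re, Sc, Sh are definitionally consistent with K", {
  expect_equal(reynolds(default_geometry, water_fluid), 6.12, tolerance = 1e-10)
  expect_equal(schmidt(water_fluid, default_solute), 1673.554, tolerance = 1e-6)
  # Sh * D / d == K for a spread of viscosities and geometries
  for (mu in c(0.001, 0.05, 2)) {
    for (d in c(0.018, 0.036)) {
      geo <- gut_geometry(diameter_d = d)
      fl <- gut_fluid(mu)
      K <- mass_transfer_coefficient(geo, fl, default_solute)
      Sh <- sherwood(geo, fl, default_solute)
      expect_equal(Sh * diffusivity(fl, default_solute) / geo$diameter_d, K,
                   tolerance = 1e-12)
    }
  }
})

test_that("emptying rate and half-time interconvert exactly", {
  expect_equal(gamma_from_half_time(3600), log(2) / 3600)
  expect_equal(gamma_from_half_time(3600), 1.925e-4, tolerance = 1e-3)
  expect_equal(gamma_from_half_time(120), 5.776e-3, tolerance = 1e-3)
  for (t in c(120, 1800, 3600, 7200)) {
    expect_equal(half_time_from_gamma(gamma_from_half_time(t)), t)
  }
  expect_error(gamma_from_half_time(-1), "half_time")
  expect_error(gamma_from_half_time(0), "half_time")
})

test_that("characteristic times reproduce the regime-axis anchors", {
  # t_half = 1 h with the standard geometry sits at tau_emptying ~ 3.2
  g <- characteristic_times(default_geometry, water_fluid, default_solute,
                            emptying = gut_emptying(half_time = 3600))
  expect_equal(g$tau_emptying, 3.228, tolerance = 1e-3)
  # 2 min half-time anchors the fast-emptying end near 100
  g2 <- characteristic_times(default_geometry, water_fluid, default_solute,
                             emptying = gut_emptying(half_time = 120))
  expect_equal(g2$tau_emptying, 96.8, tolerance = 1e-2)
  # watery chyme: tau_transfer ~ 3.0 with the d = 2 r_m convention
  expect_equal(g$tau_transfer, 3.0399, tolerance = 1e-4)
  expect_equal(g$k_a, k_a_water, tolerance = 1e-6)
  # no emptying at all
  g0 <- characteristic_times(default_geometry, water_fluid, default_solute,
                             emptying = gut_emptying(gamma = 0))
  expect_equal(g0$tau_emptying, 0)
})

test_that("kinetic groups use the meal molar concentration and flag absence", {
  kin <- gut_kinetics(vmax = 9, km = 9)
  g <- characteristic_times(default_geometry, water_fluid, default_solute,
                            emptying = gut_emptying(half_time = 1200),
                            kinetics = kin, meal_mass = 50, meal_volume = 0.5)
  gs0 <- 50 / (180 * 0.5)             # mol/L
  expect_equal(g$ref_conc_gs0, gs0)
  expect_equal(g$km_scaled, 0.009 / gs0)
  expect_equal(g$tau_reaction, t_res * kin$vmax / gs0)
  # Km equal to the reference concentration normalises to exactly 1
  kin1 <- gut_kinetics(vmax = 9, km = gs0 * 1000)
  g1 <- characteristic_times(default_geometry, water_fluid, default_solute,
                             kinetics = kin1, ref_conc_gs0 = gs0)
  expect_equal(g1$km_scaled, 1)
  # without kinetics the reaction groups are NA and model 3 refuses to run
  gna <- characteristic_times(default_geometry, water_fluid, default_solute,
                              emptying = gut_emptying(half_time = 3600))
  expect_true(is.na(gna$tau_reaction))
  expect_error(simulate_dimensionless(3, gna), "kinetics not provided")
})

test_that("tau_transfer is invariant to solute energy content and input scale", {
  # linearity: the transfer group only sees geometry/fluid/solute radius
  g1 <- characteristic_times(default_geometry, water_fluid, default_solute,
                             meal_mass = 50)
  g2 <- characteristic_times(default_geometry, water_fluid, default_solute,
                             meal_mass = 500)
  expect_identical(g1$tau_transfer, g2$tau_transfer)
})

test_that("group calculators are pure and deterministic", {
  a <- characteristic_times(default_geometry, gut_fluid(0.37), default_solute,
                            emptying = gut_emptying(half_time = 1234),
                            kinetics = gut_kinetics(3.3, 7.7))
  b <- characteristic_times(default_geometry, gut_fluid(0.37), default_solute,
                            emptying = gut_emptying(half_time = 1234),
                            kinetics = gut_kinetics(3.3, 7.7))
  expect_identical(unclass(a), unclass(b))
})

test_that("domain errors name the offending field", {
  expect_error(gut_fluid(-1), "viscosity_mu")
  expect_error(gut_fluid(1e3), "viscosity_mu")
  expect_error(gut_geometry(length_L = 0), "length_L")
  expect_error(gut_solute(molecular_radius_r0 = 1e-7), "molecular_radius_r0")
  expect_error(gut_kinetics(vmax = -2), "vmax")
  expect_error(gut_emptying(half_time = -60), "half_time")
})
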