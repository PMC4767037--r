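test_that("Model 1 tracks the characteristics closed form across viscosities", {
  g500 <- build_grid(default_geometry, n_cells = 500)
  for (mu in c(0.001, 0.2)) {
    fl <- gut_fluid(mu)
    sim <- simulate_model1(50, default_geometry, fl, default_solute, g500,
                          horizon = 10800)
    k_a <- absorption_rate_constant(default_geometry, fl, default_solute)
    orc <- model1_closed_form(sim$times, k_a, default_geometry,
                              sim$params_echo$l0)
    expect_lt(max(abs(sim$fraction_absorbed - orc)), 0.01)
  }
})

test_that("Model 1 conserves mass and absorbs monotonically", {
  sim <- simulate_model1(50, grid = default_grid)
  expect_lt(mass_balance_report(sim)$max_residual, 1e-6)
  expect_true(all(diff(sim$absorbed) >= -1e-12))
  expect_true(all(diff(sim$exited) >= -1e-12))
  expect_true(all(sim$fraction_absorbed >= 0 & sim$fraction_absorbed <= 1))
  expect_equal(sim$negative_clip_count, 0)
})

test_that("without a transfer sink the bolus simply transits and exits", {
  # vanishing surface factor turns absorption off; everything must leave
  # once the slug tail has advected past L (run two residence times)
  geo <- gut_geometry(surface_factor_f = 1e-12)
  sim <- simulate_model1(50, geo, gut_fluid(1), default_solute,
                         build_grid(geo, 100), horizon = 2 * t_res)
  expect_lt(tail(sim$fraction_absorbed, 1), 1e-6)
  expect_equal(tail(sim$exited, 1), 50, tolerance = 1e-5)
  expect_lt(tail(sim$luminal_glucose, 1), 1e-3)
})

test_that("Models 1-2 are invariant to input mass and bolus extent", {
  fr <- function(mass, l0) {
    tail(simulate_model1(mass, grid = coarse_grid, l0 = l0,
                         horizon = 7200)$fraction_absorbed, 1)
  }
  expect_equal(fr(50, 0.049), fr(500, 0.049), tolerance = 1e-8)
  expect_equal(fr(50, 0.049), fr(50, 0.5), tolerance = 1e-6)
  em <- gut_emptying(half_time = 1800)
  fr2 <- function(mass) {
    tail(simulate_model2(mass, em, grid = coarse_grid,
                         horizon = 7200)$fraction_absorbed, 1)
  }
  expect_equal(fr2(50), fr2(7), tolerance = 1e-8)
})

test_that("Model 2 agrees with the entry-time quadrature oracle", {
  g500 <- build_grid(default_geometry, n_cells = 500)
  for (th in c(900, 3600)) {
    em <- gut_emptying(half_time = th)
    sim <- simulate_model2(50, em, grid = g500)
    orc <- model2_quadrature(sim$times, k_a_water, em$gamma,
                             default_geometry, sim$params_echo$l0)
    expect_lt(max(abs(sim$fraction_absorbed - orc)), 0.01)
  }
})

test_that("Model 2 starts empty and degenerates to Model 1 for fast emptying", {
  em <- gut_emptying(half_time = 1800)
  sim <- simulate_model2(50, em, grid = coarse_grid)
  expect_equal(sim$fraction_absorbed[1], 0)
  expect_equal(sim$stomach_glucose[1], 50)
  expect_lt(mass_balance_report(sim)$max_residual, 1e-6)
  # one-second half-time is effectively an instantaneous bolus
  fast <- simulate_model2(50, gut_emptying(half_time = 1), grid = coarse_grid)
  bolus <- simulate_model1(50, grid = coarse_grid)
  expect_equal(tail(fast$fraction_absorbed, 1),
               tail(bolus$fraction_absorbed, 1), tolerance = 0.01)
})

test_that("absorption at 3 h rises with emptying rate and with transfer rate", {
  f_at <- function(th, mu) {
    tail(simulate_model2(50, gut_emptying(half_time = th), default_geometry,
                         gut_fluid(mu), default_solute, coarse_grid,
                         10800)$fraction_absorbed, 1)
  }
  expect_gt(f_at(900, 0.001), f_at(3600, 0.001))   # faster emptying wins
  expect_gt(f_at(1800, 0.001), f_at(1800, 0.1))    # lower viscosity wins
})

test_that("Model 3 conserves mass and matches the characteristics oracle", {
  em <- gut_emptying(half_time = 1200)
  kin <- gut_kinetics(vmax = 9, km = 9)
  sim <- simulate_model3(50, em, kin, grid = default_grid)
  expect_lt(mass_balance_report(sim)$max_residual, 1e-5)
  orc <- model3_characteristics(10800, kin, k_a_water, em$gamma,
                                default_geometry, default_solute,
                                l0 = sim$params_echo$l0)
  expect_lt(abs(tail(sim$fraction_absorbed, 1) - orc), 0.02)
})

test_that("Model 3 collapses onto Model 2 when hydrolysis is instantaneous", {
  em <- gut_emptying(half_time = 1800)
  gs0 <- 50 / (180 * 0.5)
  vmax_fast <- 150 * gs0 / t_res / (1e-3 / 60)   # tau_R = 150 in mM/min
  s3 <- simulate_model3(50, em, gut_kinetics(vmax_fast, 9),
                        grid = coarse_grid)
  s2 <- simulate_model2(50, em, grid = coarse_grid)
  expect_equal(tail(s3$fraction_absorbed, 1), tail(s2$fraction_absorbed, 1),
               tolerance = 0.02)
})

test_that("negligible hydrolysis leaves all glucose unabsorbed", {
  em <- gut_emptying(half_time = 1200)
  sim <- simulate_model3(50, em, gut_kinetics(vmax = 1e-9, km = 9),
                         grid = coarse_grid)
  expect_lt(tail(sim$fraction_absorbed, 1), 1e-6)
  # starch is all accounted for between stomach, lumen and exit
  expect_lt(mass_balance_report(sim)$max_residual, 1e-5)
  expect_equal(tail(sim$stomach_starch + sim$luminal_starch +
                      sim$exited_starch, 1), 50, tolerance = 1e-4)
})

test_that("dimensional and dimensionless runs are the same solution", {
  em <- gut_emptying(half_time = 1800)
  groups <- characteristic_times(default_geometry, water_fluid,
                                 default_solute, em)
  l0 <- 0.049
  # Model 2, mapped onto tau = t * u / L with identical resolution
  dim2 <- simulate_model2(50, em, default_geometry, water_fluid,
                          default_solute, coarse_grid, 10800, l0 = l0)
  nd2 <- simulate_dimensionless(2, groups, n_cells = 100,
                                horizon_tau = 10800 / t_res,
                                xi0 = l0 / default_geometry$length_L,
                                n_out = 181)
  f_dim <- approx(dim2$times / t_res, dim2$fraction_absorbed,
                  xout = nd2$times)$y
  expect_lt(max(abs(f_dim - nd2$fraction_absorbed)), 0.005)
  # Model 1 likewise
  dim1 <- simulate_model1(50, default_geometry, water_fluid, default_solute,
                          coarse_grid, 10800, l0 = l0)
  nd1 <- simulate_dimensionless(1, groups, n_cells = 100,
                                horizon_tau = 10800 / t_res,
                                xi0 = l0 / default_geometry$length_L,
                                n_out = 181)
  f_dim1 <- approx(dim1$times / t_res, dim1$fraction_absorbed,
                   xout = nd1$times)$y
  expect_lt(max(abs(f_dim1 - nd1$fraction_absorbed)), 0.005)
})

test_that("dimensionless limits behave as the regime analysis predicts", {
  # no transfer: pure advection, nothing absorbed
  nd <- simulate_dimensionless(1, list(tau_transfer = 0), n_cells = 100)
  expect_equal(tail(nd$fraction_absorbed, 1), 0, tolerance = 1e-10)
  # strong transfer and emptying: essentially complete absorption by tau = 1
  nd2 <- simulate_dimensionless(2, list(tau_transfer = 100,
                                        tau_emptying = 100), n_cells = 100)
  expect_gt(tail(nd2$fraction_absorbed, 1), 0.99)
  # missing required group is a configuration error
  expect_error(simulate_dimensionless(2, list(tau_transfer = 1)),
               "tau_emptying")
})

test_that("solution is grid-converged at the default resolution", {
  em <- gut_emptying(half_time = 1800)
  f285 <- tail(simulate_model2(50, em, grid = default_grid)$fraction_absorbed, 1)
  f570 <- tail(simulate_model2(
    50, em, grid = build_grid(default_geometry, 570))$fraction_absorbed, 1)
  expect_lt(abs(f570 - f285), 0.005)
})

test_that("mass-balance report is exact for a zero-input run", {
  sim <- simulate_model1(0, grid = coarse_grid, horizon = 3600)
  mb <- mass_balance_report(sim)
  expect_equal(mb$residuals, rep(0, length(sim$times)), tolerance = 1e-12)
  expect_equal(mb$max_residual, 0, tolerance = 1e-12)
})

test_that("simulation object methods expose the run coherently", {
  sim <- simulate_model2(50, gut_emptying(half_time = 1800),
                         grid = coarse_grid, horizon = 3600)
  df <- as.data.frame(sim)
  expect_named(df, c("time_s", "stomach_g", "luminal_g", "absorbed_g",
                     "exited_g", "fraction_absorbed", "kcal_per_min"))
  expect_equal(nrow(df), length(sim$times))
  s <- summary(sim)
  expect_equal(s$final_fraction_absorbed, tail(sim$fraction_absorbed, 1))
  expect_output(print(sim), "Model 2")
  # calorie rate equals the kcal conversion of the instantaneous mass rate
  k_a <- sim$params_echo$k_a
  expect_equal(sim$absorbed_kcal_rate,
               kcal_conversion(k_a * sim$luminal_glucose, default_solute))
})
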