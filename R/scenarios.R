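#' Convert a glucose mass rate to a calorie absorption rate
#'
#' 1 g of glucose carries 4 kcal, so `kcal/min = (g/s) * 60 * kcal_per_gram`.
#'
#' @param mass_rate mass absorption rate (g/s); vectorised.
#' @param solute a [gut_solute()].
#' @return calorie rate (kcal/min).
#' @export
kcal_conversion <- function(mass_rate, solute = gut_solute()) {
  if (any(mass_rate < 0)) stop("field 'mass_rate' must be non-negative",
                               call. = FALSE)
  mass_rate * 60 * solute$kcal_per_gram
}

#' Literature gastric-emptying meals
#'
#' A packaged table of published liquid-meal gastric-emptying measurements
#' (half-time, calorific content, viscosity class, measurement method), used
#' to overlay real meals on the regime maps. Values are as reported in the
#' source studies; `kcal = NA` where the study did not report energy content.
#'
#' @return a data.frame with columns `meal_label`, `half_time_min`, `kcal`,
#'   `viscosity_class`, `method`.
#' @export
literature_meals <- function() {
  path <- system.file("extdata", "literature_meals.csv", package = "gutsim",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.log_space <- function(range, n) exp(seq(log(range[1]), log(range[2]),
                                         length.out = n))

#' Viscosity sweep of Model 1
#'
#' Runs the bolus model over log-spaced viscosities (default 20 points from
#' 1 mPa s, water, to 10 Pa s, honey-like) and collects the absorbed-mass
#' curves, the total at the horizon, the final calorie absorption rate, and
#' the dimensionless absorbed-vs-`tau_transfer` relation.
#'
#' @param n_points number of viscosities.
#' @param mu_range viscosity range (Pa s), swept log-uniformly.
#' @param horizon simulation horizon (s).
#' @param mass glucose input (g).
#' @param geometry,solute,grid as in [simulate_model1()].
#' @return an object of class `gut_sweep` with elements `mu`,
#'   `tau_transfer`, `fraction_absorbed`, `absorbed_g`, `kcal_per_min_final`,
#'   `times`, `curves` (time x viscosity absorbed-mass matrix) and a config
#'   echo in `metadata`.
#' @export
viscosity_sweep <- function(n_points = 20, mu_range = c(1e-3, 10),
                            horizon = 10800, mass = 50,
                            geometry = gut_geometry(),
                            solute = gut_solute(),
                            grid = NULL) {
  stopifnot(length(mu_range) == 2, all(mu_range > 0), n_points >= 2)
  if (is.null(grid)) grid <- build_grid(geometry)
  mu <- .log_space(sort(mu_range), n_points)
  runs <- lapply(mu, function(m) {
    tryCatch(
      simulate_model1(mass, geometry, gut_fluid(m), solute, grid, horizon),
      error = function(e) stop(sprintf("viscosity sweep failed at mu = %g Pa s: %s",
                                       m, conditionMessage(e)), call. = FALSE)
    )
  })
  tres <- geometry$length_L / geometry$mean_velocity_u
  tau_t <- vapply(mu, function(m) {
    absorption_rate_constant(geometry, gut_fluid(m), solute) * tres
  }, numeric(1))
  frac <- vapply(runs, function(r) utils::tail(r$fraction_absorbed, 1),
                 numeric(1))
  structure(
    list(
      axes = list(mu = mu),
      mu = mu,
      tau_transfer = tau_t,
      fraction_absorbed = frac,
      absorbed_g = frac * mass,
      kcal_per_min_final = vapply(runs, function(r)
        utils::tail(r$absorbed_kcal_rate, 1), numeric(1)),
      times = runs[[1]]$times,
      curves = vapply(runs, function(r) r$absorbed,
                      numeric(length(runs[[1]]$times))),
      response = frac,
      metadata = list(kind = "viscosity_sweep", n_points = n_points,
                      mu_range = mu_range, horizon = horizon, mass = mass,
                      n_cells = grid$n)
    ),
    class = "gut_sweep"
  )
}

#' Gastric-emptying half-time sweep of Model 2
#'
#' @param half_times vector of emptying half-times (s).
#' @param mu luminal viscosity (Pa s).
#' @inheritParams viscosity_sweep
#' @return a `gut_sweep` with stomach and absorption curves per half-time.
#' @export
emptying_sweep <- function(half_times = c(900, 1800, 3600),
                           mu = 0.001, horizon = 10800, mass = 50,
                           geometry = gut_geometry(),
                           solute = gut_solute(),
                           grid = NULL) {
  stopifnot(all(half_times > 0))
  if (is.null(grid)) grid <- build_grid(geometry)
  fluid <- gut_fluid(mu)
  runs <- lapply(half_times, function(th) {
    tryCatch(
      simulate_model2(mass, gut_emptying(half_time = th), geometry, fluid,
                      solute, grid, horizon),
      error = function(e) stop(sprintf("emptying sweep failed at t_half = %g s: %s",
                                       th, conditionMessage(e)), call. = FALSE)
    )
  })
  frac <- vapply(runs, function(r) utils::tail(r$fraction_absorbed, 1),
                 numeric(1))
  nt <- length(runs[[1]]$times)
  structure(
    list(
      axes = list(half_time = half_times),
      half_time = half_times,
      fraction_absorbed = frac,
      times = runs[[1]]$times,
      stomach_curves = vapply(runs, function(r) r$stomach_glucose, numeric(nt)),
      curves = vapply(runs, function(r) r$absorbed, numeric(nt)),
      response = frac,
      metadata = list(kind = "emptying_sweep", half_times = half_times,
                      mu = mu, horizon = horizon, mass = mass,
                      n_cells = grid$n)
    ),
    class = "gut_sweep"
  )
}

#' Emptying-vs-transfer regime map (dimensionless Model 2)
#'
#' Sweeps `tau_emptying` and `tau_transfer` on a log-log grid and records
#' the fraction of glucose absorbed after one residence time (`tau = 1` by
#' default). The resulting surface separates emptying-limited,
#' transfer-limited, doubly limited and saturated regimes.
#'
#' @param tau_emptying_range,tau_transfer_range axis ranges (defaults: the
#'   physiological spans 0.5-100 and 0.1-100).
#' @param n_grid grid points per axis (>= 5).
#' @param horizon_tau evaluation time in residence-time units.
#' @param n_cells dimensionless grid cells.
#' @param overlay_meals if `TRUE`, attach the packaged literature meals
#'   mapped to `tau_emptying` through the default geometry.
#' @return a `gut_sweep`; `response` is an `n_grid x n_grid` matrix with
#'   `tau_emptying` on rows and `tau_transfer` on columns.
#' @export
regime_map <- function(tau_emptying_range = c(0.5, 100),
                       tau_transfer_range = c(0.1, 100),
                       n_grid = 9, horizon_tau = 1,
                       n_cells = 120, overlay_meals = FALSE) {
  stopifnot(n_grid >= 5, all(tau_emptying_range > 0),
            all(tau_transfer_range > 0))
  tau_e <- .log_space(sort(tau_emptying_range), n_grid)
  tau_t <- .log_space(sort(tau_transfer_range), n_grid)
  resp <- matrix(NA_real_, n_grid, n_grid,
                 dimnames = list(tau_emptying = signif(tau_e, 4),
                                 tau_transfer = signif(tau_t, 4)))
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      sim <- tryCatch(
        simulate_dimensionless(2, list(tau_transfer = tau_t[j],
                                       tau_emptying = tau_e[i]),
                               n_cells = n_cells, horizon_tau = horizon_tau),
        error = function(e) stop(sprintf(
          "regime map failed at tau_e = %g, tau_t = %g: %s",
          tau_e[i], tau_t[j], conditionMessage(e)), call. = FALSE)
      )
      resp[i, j] <- utils::tail(sim$fraction_absorbed, 1)
    }
  }
  overlay <- NULL
  if (overlay_meals) {
    meals <- literature_meals()
    geo <- gut_geometry()
    tres <- geo$length_L / geo$mean_velocity_u
    meals$tau_emptying <- log(2) / (meals$half_time_min * 60) * tres
    overlay <- meals
  }
  structure(
    list(
      axes = list(tau_emptying = tau_e, tau_transfer = tau_t),
      tau_emptying = tau_e, tau_transfer = tau_t,
      response = resp,
      overlay = overlay,
      metadata = list(kind = "regime_map", n_grid = n_grid,
                      horizon_tau = horizon_tau, n_cells = n_cells,
                      tau_emptying_range = tau_emptying_range,
                      tau_transfer_range = tau_transfer_range)
    ),
    class = "gut_sweep"
  )
}

#' Reaction regime maps (dimensionless Model 3)
#'
#' One emptying-vs-transfer map per `tau_reaction` value. At large
#' `tau_reaction` starch hydrolyses essentially on entry and each slice
#' collapses onto the glucose-only map of [regime_map()].
#'
#' @param tau_R_values characteristic reaction times to slice over.
#' @param km_scaled scaled Michaelis constant `Km / Gs0`.
#' @param volume_ratio meal-to-gut volume ratio (see
#'   [simulate_dimensionless()]).
#' @inheritParams regime_map
#' @return a `gut_sweep`; `response` is a list of matrices, one per
#'   `tau_R_values` entry.
#' @export
reaction_regime_map <- function(tau_R_values = c(1, 5, 25),
                                tau_emptying_range = c(0.5, 100),
                                tau_transfer_range = c(0.1, 100),
                                n_grid = 9, horizon_tau = 1,
                                n_cells = 120,
                                km_scaled = 9 / 555.6,
                                volume_ratio = 5e-4 / 2.900947e-3) {
  stopifnot(all(tau_R_values > 0), n_grid >= 5)
  tau_e <- .log_space(sort(tau_emptying_range), n_grid)
  tau_t <- .log_space(sort(tau_transfer_range), n_grid)
  slices <- lapply(tau_R_values, function(tr) {
    resp <- matrix(NA_real_, n_grid, n_grid,
                   dimnames = list(tau_emptying = signif(tau_e, 4),
                                   tau_transfer = signif(tau_t, 4)))
    for (i in seq_len(n_grid)) {
      for (j in seq_len(n_grid)) {
        sim <- simulate_dimensionless(
          3, list(tau_transfer = tau_t[j], tau_emptying = tau_e[i],
                  tau_reaction = tr, km_scaled = km_scaled),
          n_cells = n_cells, horizon_tau = horizon_tau,
          volume_ratio = volume_ratio
        )
        resp[i, j] <- utils::tail(sim$fraction_absorbed, 1)
      }
    }
    resp
  })
  names(slices) <- paste0("tau_R=", signif(tau_R_values, 4))
  structure(
    list(
      axes = list(tau_R = tau_R_values, tau_emptying = tau_e,
                  tau_transfer = tau_t),
      tau_R = tau_R_values, tau_emptying = tau_e, tau_transfer = tau_t,
      response = slices,
      metadata = list(kind = "reaction_regime_map",
                      tau_R_values = tau_R_values, n_grid = n_grid,
                      horizon_tau = horizon_tau, n_cells = n_cells,
                      km_scaled = km_scaled, volume_ratio = volume_ratio)
    ),
    class = "gut_sweep"
  )
}

#' @export
print.gut_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep: %s\n", x$metadata$kind))
  for (nm in names(x$axes)) {
    ax <- x$axes[[nm]]
    cat(sprintf("  %s: %d values in [%.4g, %.4g]\n", nm, length(ax),
                min(ax), max(ax)))
  }
  r <- x$response
  if (is.list(r)) r <- unlist(r)
  cat(sprintf("  response: %d values, range [%.4g, %.4g]\n",
              length(r), min(r), max(r)))
  invisible(x)
}

#' Long-format view of a sweep
#'
#' @param x a `gut_sweep`.
#' @param row.names,optional,... ignored.
#' @return a data.frame with one row per grid point.
#' @export
as.data.frame.gut_sweep <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  kind <- x$metadata$kind
  if (kind == "viscosity_sweep") {
    data.frame(mu_Pa_s = x$mu, tau_transfer = x$tau_transfer,
               fraction_absorbed = x$fraction_absorbed,
               absorbed_g = x$absorbed_g,
               kcal_per_min_final = x$kcal_per_min_final)
  } else if (kind == "emptying_sweep") {
    data.frame(half_time_s = x$half_time,
               fraction_absorbed = x$fraction_absorbed)
  } else if (kind == "regime_map") {
    expand <- expand.grid(tau_emptying = x$tau_emptying,
                          tau_transfer = x$tau_transfer)
    expand$fraction_absorbed <- as.vector(x$response)
    expand
  } else {
    do.call(rbind, lapply(seq_along(x$tau_R), function(k) {
      e <- expand.grid(tau_emptying = x$tau_emptying,
                       tau_transfer = x$tau_transfer)
      e$tau_R <- x$tau_R[k]
      e$fraction_absorbed <- as.vector(x$response[[k]])
      e
    }))
  }
}
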