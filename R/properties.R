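#' Stokes-Einstein diffusivity
#'
#' Diffusivity of a small solute in the luminal fluid,
#' `D = kB * T / (6 * pi * mu * r0)`. Inversely proportional to viscosity,
#' which is what couples food rheology to the absorption rate.
#'
#' @param fluid a [gut_fluid()].
#' @param solute a [gut_solute()].
#' @return diffusivity (m^2/s).
#' @examples
#' diffusivity(gut_fluid(0.001), gut_solute())  # ~5.98e-10 m2/s for glucose
#' @export
diffusivity <- function(fluid, solute) {
  stopifnot(inherits(fluid, "gut_fluid"), inherits(solute, "gut_solute"))
  BOLTZMANN_K * fluid$temperature_T /
    (6 * pi * fluid$viscosity_mu * solute$molecular_radius_r0)
}

#' Overall luminal mass-transfer coefficient
#'
#' Laminar-tube Sherwood correlation `Sh = 1.62 (Re Sc d/L)^(1/3)`
#' rearranged to `K = 1.62 (u D^2 / (L d))^(1/3)`. Epithelial and blood-side
#' resistances are neglected (assumed fast), so K is the luminal
#' film coefficient and scales as `mu^(-2/3)` through the diffusivity.
#'
#' @inheritParams diffusivity
#' @param geometry a [gut_geometry()].
#' @return mass-transfer coefficient K (m/s).
#' @examples
#' mass_transfer_coefficient(gut_geometry(), gut_fluid(0.001), gut_solute())
#' @export
mass_transfer_coefficient <- function(geometry, fluid, solute) {
  stopifnot(inherits(geometry, "gut_geometry"))
  D <- diffusivity(fluid, solute)
  1.62 * (geometry$mean_velocity_u * D^2 /
            (geometry$length_L * geometry$diameter_d))^(1 / 3)
}

#' Reynolds, Schmidt and Sherwood numbers
#'
#' `Re = rho u d / mu`, `Sc = mu / (rho D)`, `Sh = 1.62 (Re Sc d/L)^(1/3)`.
#' By construction `Sh * D / d` equals [mass_transfer_coefficient()].
#'
#' @inheritParams mass_transfer_coefficient
#' @return a number.
#' @export
reynolds <- function(geometry, fluid) {
  stopifnot(inherits(geometry, "gut_geometry"), inherits(fluid, "gut_fluid"))
  fluid$density_rho * geometry$mean_velocity_u * geometry$diameter_d /
    fluid$viscosity_mu
}

#' @rdname reynolds
#' @export
schmidt <- function(fluid, solute) {
  fluid$viscosity_mu / (fluid$density_rho * diffusivity(fluid, solute))
}

#' @rdname reynolds
#' @export
sherwood <- function(geometry, fluid, solute) {
  1.62 * (reynolds(geometry, fluid) * schmidt(fluid, solute) *
            geometry$diameter_d / geometry$length_L)^(1 / 3)
}

#' Convert between emptying half-time and rate constant
#'
#' `gamma = ln(2) / t_half`; the two functions are exact inverses.
#'
#' @param half_time emptying half-time (s).
#' @param gamma first-order emptying rate constant (1/s).
#' @return rate constant (1/s) or half-time (s).
#' @export
gamma_from_half_time <- function(half_time) {
  .check_positive(half_time, "half_time")
  log(2) / half_time
}

#' @rdname gamma_from_half_time
#' @export
half_time_from_gamma <- function(gamma) {
  .check_positive(gamma, "gamma")
  log(2) / gamma
}

#' Volumetric absorption rate constant 2fK/r_m
#'
#' First-order rate constant for glucose removal from the lumen: the film
#' coefficient K times the amplified surface-to-volume ratio of the tube.
#' @inheritParams mass_transfer_coefficient
#' @return rate constant (1/s).
#' @export
absorption_rate_constant <- function(geometry, fluid, solute) {
  2 * geometry$surface_factor_f *
    mass_transfer_coefficient(geometry, fluid, solute) / geometry$radius_rm
}

#' Characteristic times and dimensionless groups
#'
#' Scales every transport/kinetic rate by the mean intestinal residence time
#' `L/u`:
#' \itemize{
#'   \item `tau_transfer = (2 f K / r_m) * (L/u)` - absorption vs transit;
#'   \item `tau_emptying = gamma * (L/u)` - gastric emptying vs transit;
#'   \item `tau_reaction = (L/u) * Vmax / Gs0` - hydrolysis vs transit;
#'   \item `km_scaled = Km / Gs0` - Michaelis constant scaled by the meal.
#' }
#' `Gs0` is the molar concentration of the meal,
#' `meal_mass / (molar_mass * meal_volume)`; the meal volume is explicit
#' because the reference concentration is what makes `tau_reaction` and
#' `km_scaled` dimensionless.
#'
#' @inheritParams mass_transfer_coefficient
#' @param emptying a [gut_emptying()], or `NULL` (then `tau_emptying = NA`).
#' @param kinetics a [gut_kinetics()], or `NULL` (then `tau_reaction` and
#'   `km_scaled` are `NA`).
#' @param meal_mass meal mass (g). Default 50.
#' @param meal_volume meal volume (L). Default 0.5.
#' @param ref_conc_gs0 reference molar concentration (mol/L); overrides the
#'   meal-derived value when supplied.
#' @return an object of class `dimensionless_groups` with fields `reynolds`,
#'   `schmidt`, `sherwood`, `tau_transfer`, `tau_emptying`, `tau_reaction`,
#'   `km_scaled`, plus `K`, `D`, `k_a`, `residence_time` and the reference
#'   concentration as attributes of record.
#' @examples
#' characteristic_times(gut_geometry(), gut_fluid(0.001), gut_solute(),
#'                      emptying = gut_emptying(half_time = "1 h"))
#' @export
characteristic_times <- function(geometry, fluid, solute,
                                 emptying = NULL, kinetics = NULL,
                                 meal_mass = 50, meal_volume = 0.5,
                                 ref_conc_gs0 = NULL) {
  stopifnot(inherits(geometry, "gut_geometry"))
  tres <- geometry$length_L / geometry$mean_velocity_u
  D <- diffusivity(fluid, solute)
  K <- mass_transfer_coefficient(geometry, fluid, solute)
  k_a <- 2 * geometry$surface_factor_f * K / geometry$radius_rm
  tau_e <- if (is.null(emptying)) NA_real_ else emptying$gamma * tres
  if (is.null(ref_conc_gs0)) {
    .check_positive(meal_mass, "meal_mass")
    .check_positive(meal_volume, "meal_volume")
    ref_conc_gs0 <- meal_mass / (solute$molar_mass * meal_volume)
  }
  .check_positive(ref_conc_gs0, "ref_conc_gs0")
  if (is.null(kinetics)) {
    tau_r <- NA_real_
    km_sc <- NA_real_
  } else {
    stopifnot(inherits(kinetics, "gut_kinetics"))
    tau_r <- tres * kinetics$vmax / ref_conc_gs0
    km_sc <- kinetics$km / ref_conc_gs0
  }
  structure(
    list(
      reynolds = reynolds(geometry, fluid),
      schmidt = schmidt(fluid, solute),
      sherwood = sherwood(geometry, fluid, solute),
      tau_transfer = k_a * tres,
      tau_emptying = tau_e,
      tau_reaction = tau_r,
      km_scaled = km_sc,
      D = D, K = K, k_a = k_a,
      residence_time = tres,
      ref_conc_gs0 = ref_conc_gs0
    ),
    class = "dimensionless_groups"
  )
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("Transport chain:\n")
  cat(sprintf("  D   = %.4g m2/s   K = %.4g m/s   k_a = 2fK/r_m = %.4g 1/s\n",
              x$D, x$K, x$k_a))
  cat(sprintf("  Re  = %.4g   Sc = %.4g   Sh = %.4g\n",
              x$reynolds, x$schmidt, x$sherwood))
  cat("Characteristic times (residence time", sprintf("%.0f s):\n",
      x$residence_time))
  cat(sprintf("  tau_transfer = %.4g   tau_emptying = %.4g\n",
              x$tau_transfer, x$tau_emptying))
  cat(sprintf("  tau_reaction = %.4g   Km'' = %.4g  (Gs0 = %.4g mol/L)\n",
              x$tau_reaction, x$km_scaled, x$ref_conc_gs0))
  invisible(x)
}
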