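#' Small-intestine geometry
#'
#' Geometry of the plug-flow small intestine: tube length, radius, the
#' diameter used in the laminar Sherwood correlation, the mucosal surface
#' amplification factor (plicae circulares, villi and the absorbing fraction
#' of microvilli), and the mean axial velocity of chyme.
#'
#' By default the correlation diameter is twice the radius. The two are
#' independently overridable because published compartmental models are not
#' always consistent about which length scale enters the correlation; keeping
#' `diameter_d` explicit makes that choice visible rather than implicit.
#'
#' @param length_L tube length (m). Default 2.85 m.
#' @param radius_rm tube radius (m). Default 0.018 m.
#' @param surface_factor_f dimensionless surface-area amplification.
#'   Default 12 (3x plicae circulares, 10x villi, 20x microvilli of which
#'   ~2% participate in glucose uptake, i.e. 3 * 4).
#' @param mean_velocity_u mean axial velocity (m/s). Default 1.7e-4 m/s.
#' @param diameter_d diameter used in the Sherwood correlation (m).
#'   Default `2 * radius_rm`.
#' @return an object of class `gut_geometry`.
#' @examples
#' g <- gut_geometry()
#' g$length_L / g$mean_velocity_u   # mean residence time, ~16765 s
#' @export
gut_geometry <- function(length_L = 2.85,
                         radius_rm = 0.018,
                         surface_factor_f = 12,
                         mean_velocity_u = 1.7e-4,
                         diameter_d = 2 * radius_rm) {
  length_L <- parse_quantity(length_L, "length", "length_L")
  radius_rm <- parse_quantity(radius_rm, "length", "radius_rm")
  diameter_d <- parse_quantity(diameter_d, "length", "diameter_d")
  .check_positive(length_L, "length_L")
  .check_positive(radius_rm, "radius_rm")
  .check_positive(diameter_d, "diameter_d")
  .check_positive(surface_factor_f, "surface_factor_f")
  .check_positive(mean_velocity_u, "mean_velocity_u")
  structure(
    list(
      length_L = length_L, radius_rm = radius_rm, diameter_d = diameter_d,
      surface_factor_f = surface_factor_f, mean_velocity_u = mean_velocity_u
    ),
    class = "gut_geometry"
  )
}

#' Luminal fluid properties
#'
#' Bulk properties of the chyme treated as a Newtonian fluid of constant
#' viscosity. Viscosity is the single food-controllable parameter of the
#' transport chain: it sets the Stokes-Einstein diffusivity and hence the
#' luminal mass-transfer coefficient.
#'
#' @param viscosity_mu dynamic viscosity (Pa s), or a string such as
#'   `"5 mPa.s"`. Supported range 1e-4 to 1e2 Pa s (water to beyond honey).
#' @param density_rho density (kg/m^3). Default 1000.
#' @param temperature_T absolute temperature (K). Default 310 (body).
#' @return an object of class `gut_fluid`.
#' @export
gut_fluid <- function(viscosity_mu = 0.001,
                      density_rho = 1000,
                      temperature_T = 310) {
  viscosity_mu <- parse_quantity(viscosity_mu, "viscosity", "viscosity_mu")
  .check_positive(viscosity_mu, "viscosity_mu")
  if (viscosity_mu < 1e-4 || viscosity_mu > 1e2) {
    stop("field 'viscosity_mu' outside supported regime [1e-4, 1e2] Pa s",
         call. = FALSE)
  }
  .check_positive(density_rho, "density_rho")
  .check_positive(temperature_T, "temperature_T")
  structure(
    list(viscosity_mu = viscosity_mu, density_rho = density_rho,
         temperature_T = temperature_T),
    class = "gut_fluid"
  )
}

#' Solute (nutrient) properties
#'
#' @param molecular_radius_r0 hydrodynamic radius of the diffusing molecule
#'   (m). Default 0.38 nm (glucose).
#' @param molar_mass molar mass (g/mol). Default 180 (glucose).
#' @param kcal_per_gram calorific value (kcal/g). Default 4 (glucose).
#' @return an object of class `gut_solute`.
#' @export
gut_solute <- function(molecular_radius_r0 = 0.38e-9,
                       molar_mass = 180,
                       kcal_per_gram = 4) {
  molecular_radius_r0 <- parse_quantity(molecular_radius_r0, "length",
                                        "molecular_radius_r0")
  .check_positive(molecular_radius_r0, "molecular_radius_r0")
  if (molecular_radius_r0 >= 1e-8) {
    stop("field 'molecular_radius_r0' must be below 1e-8 m (small molecule)",
         call. = FALSE)
  }
  .check_positive(molar_mass, "molar_mass")
  .check_positive(kcal_per_gram, "kcal_per_gram", strict = FALSE)
  structure(
    list(molecular_radius_r0 = molecular_radius_r0, molar_mass = molar_mass,
         kcal_per_gram = kcal_per_gram),
    class = "gut_solute"
  )
}

#' Gastric-emptying parameters
#'
#' First-order (exponential) emptying of a liquid meal with no lag phase.
#' Either the rate constant `gamma` or the half-time may be given; the other
#' is derived through `t_half = ln(2) / gamma`.
#'
#' @param half_time emptying half-time in seconds, or a string with units
#'   (`"30 min"`, `"1 h"`).
#' @param gamma first-order rate constant (1/s). `gamma = 0` means no
#'   emptying (contents stay in the stomach forever).
#' @return an object of class `gut_emptying` with both fields populated.
#' @examples
#' gut_emptying(half_time = "30 min")$gamma   # ~3.85e-4 s^-1
#' @export
gut_emptying <- function(half_time = NULL, gamma = NULL) {
  if (is.null(half_time) && is.null(gamma)) {
    stop("one of 'half_time' or 'gamma' must be supplied", call. = FALSE)
  }
  if (!is.null(half_time)) {
    half_time <- parse_quantity(half_time, "time", "half_time")
    .check_positive(half_time, "half_time")
    g <- gamma_from_half_time(half_time)
    if (!is.null(gamma) && abs(gamma - g) > 1e-12 * max(g, 1e-300)) {
      stop("inconsistent 'gamma' and 'half_time': gamma must equal ln(2)/half_time",
           call. = FALSE)
    }
    gamma <- g
  } else {
    .check_positive(gamma, "gamma", strict = FALSE)
    half_time <- if (gamma > 0) half_time_from_gamma(gamma) else Inf
  }
  structure(list(gamma = gamma, half_time = half_time),
            class = "gut_emptying")
}

#' Michaelis-Menten kinetics for luminal starch hydrolysis
#'
#' Amylase is assumed in excess so hydrolysis is limited by substrate
#' bioaccessibility; the rate law is `Vmax * S / (Km + S)` on molar starch
#' concentration (expressed as anhydroglucose equivalents).
#'
#' @param vmax maximal rate, in mM/min (the customary unit; a string such as
#'   `"9 mM/min"` is also accepted).
#' @param km Michaelis constant, in mM. Default 9 mM.
#' @return an object of class `gut_kinetics` with fields in SI
#'   (`vmax` in mol L^-1 s^-1, `km` in mol/L) plus the as-given values.
#' @export
gut_kinetics <- function(vmax, km = 9) {
  vmax_si <- if (is.character(vmax)) {
    parse_quantity(vmax, "rate", "vmax")
  } else {
    .check_positive(vmax, "vmax")
    .mM_per_min_to_molar_per_s(vmax)
  }
  km_si <- if (is.character(km)) {
    parse_quantity(km, "concentration", "km")
  } else {
    .check_positive(km, "km")
    .mM_to_molar(km)
  }
  .check_positive(vmax_si, "vmax")
  .check_positive(km_si, "km")
  structure(
    list(vmax = vmax_si, km = km_si,
         vmax_mM_min = vmax_si / (1e-3 / 60), km_mM = km_si / 1e-3),
    class = "gut_kinetics"
  )
}

#' @export
print.gut_geometry <- function(x, ...) {
  cat("Small-intestine geometry:\n")
  cat(sprintf("  length L        %.4g m\n", x$length_L))
  cat(sprintf("  radius r_m      %.4g m\n", x$radius_rm))
  cat(sprintf("  diameter d      %.4g m (Sherwood correlation)\n", x$diameter_d))
  cat(sprintf("  surface factor  %.4g\n", x$surface_factor_f))
  cat(sprintf("  mean velocity   %.4g m/s (residence time %.0f s)\n",
              x$mean_velocity_u, x$length_L / x$mean_velocity_u))
  invisible(x)
}

#' @export
print.gut_fluid <- function(x, ...) {
  cat(sprintf("Luminal fluid: mu = %.4g Pa s, rho = %.4g kg/m3, T = %.4g K\n",
              x$viscosity_mu, x$density_rho, x$temperature_T))
  invisible(x)
}

#' @export
print.gut_emptying <- function(x, ...) {
  cat(sprintf("Gastric emptying: gamma = %.4g 1/s (half-time %.4g min)\n",
              x$gamma, x$half_time / 60))
  invisible(x)
}

#' @export
print.gut_kinetics <- function(x, ...) {
  cat(sprintf("Hydrolysis kinetics: Vmax = %.4g mM/min, Km = %.4g mM\n",
              x$vmax_mM_min, x$km_mM))
  invisible(x)
}
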