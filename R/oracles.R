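#' Closed-form absorbed fraction for a glucose bolus (Model 1 oracle)
#'
#' Grid-free solution of the advection-absorption equation along
#' characteristics. A fluid parcel starting at `z0 in [0, l0]` is absorbed at
#' rate `k_a` until it exits at `(L - z0)/u`; averaging over the bolus gives
#' a piecewise closed form. Shares no code with the PDE solver, so agreement
#' between the two is evidence against a common discretisation bug.
#'
#' @param t time (s); vectorised.
#' @param k_a volumetric absorption rate constant 2fK/r_m (1/s).
#' @param geometry a [gut_geometry()].
#' @param l0 bolus extent (m).
#' @return fraction of the input absorbed at each `t`.
#' @examples
#' model1_closed_form(10800, 1.813e-4, gut_geometry())  # ~0.859
#' @export
model1_closed_form <- function(t, k_a, geometry = gut_geometry(),
                               l0 = .default_l0(0.5)) {
  stopifnot(all(t >= 0), k_a >= 0)
  if (k_a == 0) return(rep(0, length(t)))
  u <- geometry$mean_velocity_u
  L <- geometry$length_L
  T1 <- (L - l0) / u   # first exit (parcel starting at z0 = l0)
  T2 <- L / u          # last exit  (parcel starting at z0 = 0)
  a <- k_a
  vapply(t, function(ti) {
    if (ti <= T1) {
      1 - exp(-a * ti)
    } else if (ti < T2) {
      zstar <- L - u * ti
      1 - (zstar * exp(-a * ti) +
             (u / a) * (exp(-a * T1) - exp(-a * ti))) / l0
    } else {
      1 - (u / a) * (exp(-a * T1) - exp(-a * T2)) / l0
    }
  }, numeric(1))
}

#' Entry-time quadrature absorbed fraction (Model 2 oracle)
#'
#' Superposes exponentially emptied parcels: a parcel entering the intestine
#' at time `s` has been absorbed for `min(t - s, (L - l0)/u)` by time `t`.
#' While no parcel has exited, the double exponential integrates in closed
#' form; afterwards the entry-time integral is evaluated by adaptive
#' quadrature. Independent of the PDE discretisation.
#'
#' @inheritParams model1_closed_form
#' @param gamma gastric emptying rate constant (1/s).
#' @return fraction of the input absorbed at each `t`.
#' @examples
#' model2_quadrature(10800, 1.813e-4, log(2) / 1800)  # ~0.747
#' @export
model2_quadrature <- function(t, k_a, gamma, geometry = gut_geometry(),
                              l0 = .default_l0(0.5)) {
  stopifnot(all(t >= 0), k_a >= 0, gamma >= 0)
  if (gamma == 0 || k_a == 0) return(rep(0, length(t)))
  u <- geometry$mean_velocity_u
  T1 <- (geometry$length_L - l0) / u
  a <- k_a
  closed <- function(ti) {
    # int_0^ti gamma e^(-gamma s) (1 - e^(-a (ti - s))) ds, no exits yet
    if (abs(gamma - a) < 1e-14 * a) {
      (1 - exp(-gamma * ti)) - gamma * ti * exp(-gamma * ti)
    } else {
      (1 - exp(-gamma * ti)) -
        gamma / (gamma - a) * (exp(-a * ti) - exp(-gamma * ti))
    }
  }
  vapply(t, function(ti) {
    if (ti <= T1) {
      closed(ti)
    } else {
      # parcels entering before ti - T1 have exited with fraction 1 - e^(-a T1)
      part1 <- (1 - exp(-a * T1)) * (1 - exp(-gamma * (ti - T1)))
      part2 <- stats::integrate(
        function(s) gamma * exp(-gamma * s) * (1 - exp(-a * (ti - s))),
        lower = ti - T1, upper = ti, rel.tol = 1e-10
      )$value
      part1 + part2
    }
  }, numeric(1))
}

#' Per-parcel characteristics oracle for starch digestion (Model 3)
#'
#' Follows discrete entry-time parcels along their characteristics. Each
#' parcel enters at `l0` with starch concentration `gamma * Ss(s) / (A u)`
#' (the flux balance of injection against advection, which is what the
#' plug-flow source converges to), then obeys the local ODEs
#' `dS/dt = -MM(S)`, `dG/dt = MM(S) - k_a G` for its residence
#' `(L - l0)/u` (or until `t`). The absorbed fraction is the mass-weighted
#' parcel deficit `1 - (S + G)/S0`. Integrated with a hand-rolled vectorised
#' RK4 - deliberately not the solver's integrator.
#'
#' @inheritParams model2_quadrature
#' @param kinetics a [gut_kinetics()].
#' @param starch_mass input starch (g); cancels out of the fraction but sets
#'   the entry concentration.
#' @param parcel_count number of entry-time parcels (>= 100).
#' @param solute a [gut_solute()] (for the molar mass).
#' @param n_steps_min minimum RK4 steps; raised automatically when the
#'   linear-regime rate `Vmax/Km` would otherwise be under-resolved.
#' @return fraction of the input absorbed at time `t` (scalar `t`).
#' @export
model3_characteristics <- function(t, kinetics, k_a, gamma,
                                   geometry = gut_geometry(),
                                   solute = gut_solute(),
                                   starch_mass = 50,
                                   parcel_count = 500,
                                   l0 = .default_l0(0.5),
                                   n_steps_min = 800) {
  stopifnot(inherits(kinetics, "gut_kinetics"),
            length(t) == 1L, t >= 0, parcel_count >= 100)
  if (gamma == 0 || t == 0) return(0)
  u <- geometry$mean_velocity_u
  A <- pi * geometry$radius_rm^2
  T1 <- (geometry$length_L - l0) / u
  mw <- solute$molar_mass
  vmax <- kinetics$vmax
  km <- kinetics$km

  edges <- seq(0, t, length.out = parcel_count + 1)
  s_mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- exp(-gamma * edges[-length(edges)]) - exp(-gamma * edges[-1])  # mass fraction per parcel
  # entry concentration (mol/L): emptying flux over volumetric throughput
  S0 <- gamma * starch_mass * exp(-gamma * s_mid) / (A * u) / (mw * 1000)
  dur <- pmin(t - s_mid, T1)

  n_steps <- max(n_steps_min, ceiling(3 * max(dur) * vmax / km))
  n_steps <- min(n_steps, 2e5)
  h <- dur / n_steps    # per-parcel step
  S <- S0
  G <- rep(0, parcel_count)
  mm <- function(s) vmax * pmax(s, 0) / (km + pmax(s, 0))
  for (i in seq_len(n_steps)) {
    k1s <- -mm(S);                 k1g <- mm(S) - k_a * G
    S2 <- S + h / 2 * k1s;         G2 <- G + h / 2 * k1g
    k2s <- -mm(S2);                k2g <- mm(S2) - k_a * G2
    S3 <- S + h / 2 * k2s;         G3 <- G + h / 2 * k2g
    k3s <- -mm(S3);                k3g <- mm(S3) - k_a * G3
    S4 <- S + h * k3s;             G4 <- G + h * k3g
    k4s <- -mm(S4);                k4g <- mm(S4) - k_a * G4
    S <- S + h / 6 * (k1s + 2 * k2s + 2 * k3s + k4s)
    G <- G + h / 6 * (k1g + 2 * k2g + 2 * k3g + k4g)
    S <- pmax(S, 0)
  }
  absfrac <- ifelse(S0 > 0, 1 - (S + G) / S0, 0)
  sum(w * absfrac)
}
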