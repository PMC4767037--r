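#' @export
print.gut_simulation <- function(x, ...) {
  unit_t <- if (x$dimensionless) "tau" else "s"
  cat(sprintf("Gut simulation (Model %d%s)\n", x$model,
              if (x$dimensionless) ", dimensionless" else ""))
  cat(sprintf("  horizon: %g %s   grid: %d cells   input: %g %s\n",
              max(x$times), unit_t, x$grid$n, x$input_mass,
              if (x$dimensionless) "(mass fraction)" else "g"))
  cat(sprintf("  fraction absorbed at horizon: %.4f\n",
              utils::tail(x$fraction_absorbed, 1)))
  cat(sprintf("  max mass-balance residual: %.3g\n",
              mass_balance_report(x)$max_residual))
  invisible(x)
}

#' @export
summary.gut_simulation <- function(object, ...) {
  mb <- mass_balance_report(object)
  out <- list(
    model = object$model,
    dimensionless = object$dimensionless,
    horizon = max(object$times),
    input_mass = object$input_mass,
    final_fraction_absorbed = utils::tail(object$fraction_absorbed, 1),
    final_stomach = utils::tail(object$stomach_glucose +
                                  object$stomach_starch, 1),
    final_luminal = utils::tail(object$luminal_glucose +
                                  object$luminal_starch, 1),
    final_exited = utils::tail(object$exited, 1),
    max_mass_balance_residual = mb$max_residual,
    negative_clip_count = object$negative_clip_count
  )
  class(out) <- "summary.gut_simulation"
  out
}

#' @export
print.summary.gut_simulation <- function(x, ...) {
  cat(sprintf("Model %d simulation summary%s\n", x$model,
              if (x$dimensionless) " (dimensionless)" else ""))
  for (nm in c("horizon", "input_mass", "final_fraction_absorbed",
               "final_stomach", "final_luminal", "final_exited",
               "max_mass_balance_residual")) {
    cat(sprintf("  %-28s %.6g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Time series of a simulation as a data frame
#'
#' Columns mirror the CSV export: time, stomach, luminal, absorbed, exited
#' masses (g, or mass fractions for dimensionless runs), the absorbed
#' fraction and the calorie absorption rate.
#'
#' @param x a `gut_simulation`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data.frame.
#' @export
as.data.frame.gut_simulation <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    time_s = x$times,
    stomach_g = x$stomach_glucose + x$stomach_starch,
    luminal_g = x$luminal_glucose + x$luminal_starch,
    absorbed_g = x$absorbed,
    exited_g = x$exited,
    fraction_absorbed = x$fraction_absorbed,
    kcal_per_min = x$absorbed_kcal_rate
  )
}

#' Plot a gut simulation
#'
#' Base-graphics overview: stomach, luminal, absorbed and exited mass
#' against time.
#'
#' @param x a `gut_simulation`.
#' @param which `"mass"` (compartment masses) or `"fraction"` (absorbed
#'   fraction only).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot.gut_simulation <- function(x, which = c("mass", "fraction"), ...) {
  which <- match.arg(which)
  tu <- if (x$dimensionless) "tau" else "time (s)"
  if (which == "fraction") {
    graphics::plot(x$times, x$fraction_absorbed, type = "l",
                   xlab = tu, ylab = "fraction absorbed", ylim = c(0, 1), ...)
  } else {
    m <- cbind(stomach = x$stomach_glucose + x$stomach_starch,
               luminal = x$luminal_glucose + x$luminal_starch,
               absorbed = x$absorbed,
               exited = x$exited)
    graphics::matplot(x$times, m, type = "l", lty = 1, col = 1:4,
                      xlab = tu,
                      ylab = if (x$dimensionless) "mass fraction" else "mass (g)",
                      ...)
    graphics::legend("right", colnames(m), col = 1:4, lty = 1, bty = "n")
  }
  invisible(x)
}
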