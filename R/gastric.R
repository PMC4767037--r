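#' Stomach contents under exponential emptying
#'
#' The stomach is a perfectly mixed reservoir that only meters delivery:
#' contents decay as `M(t) = M0 * exp(-gamma * t)` (liquid meal, no lag
#' phase, no secretion volume). Closed form - no integration involved.
#'
#' @param t time since ingestion (s); vectorised, must be non-negative.
#' @param initial_mass mass at t = 0 (g).
#' @param emptying a [gut_emptying()].
#' @return remaining stomach mass (g), same length as `t`.
#' @examples
#' e <- gut_emptying(half_time = 1800)
#' stomach_mass_at(c(0, 1800, 3600), 50, e)   # 50, 25, 12.5
#' @export
stomach_mass_at <- function(t, initial_mass, emptying) {
  stopifnot(inherits(emptying, "gut_emptying"))
  if (any(t < 0)) stop("field 't' must be non-negative", call. = FALSE)
  .check_positive(initial_mass, "initial_mass", strict = FALSE)
  initial_mass * exp(-emptying$gamma * t)
}

#' Gastric emptying flux
#'
#' Mass flux delivered to the duodenum, `gamma * M(t)`; its integral over
#' all time is the ingested mass.
#'
#' @inheritParams stomach_mass_at
#' @return emptying flux (g/s), same length as `t`.
#' @export
emptying_flux <- function(t, initial_mass, emptying) {
  emptying$gamma * stomach_mass_at(t, initial_mass, emptying)
}
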