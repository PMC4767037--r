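#' Spatial grid for the method-of-lines intestine solver
#'
#' Uniform finite-volume grid over the intestine `[0, L]`. The cross-section
#' `A = pi * r_m^2` is attached so that luminal mass and concentration
#' interconvert as `mass = conc * A * dz` per cell.
#'
#' @param geometry a [gut_geometry()].
#' @param n_cells number of cells (>= 50; resolution below that cannot
#'   represent the entering bolus).
#' @param rel_tol,abs_tol integrator tolerances (abs_tol is in concentration
#'   units, g/m^3).
#' @return an object of class `gut_grid`: `centers`, `dz`, `n`, `area`,
#'   `volume`, tolerances and geometry echo.
#' @examples
#' g <- build_grid(gut_geometry(), n_cells = 285)
#' g$dz            # 0.01 m
#' g$area * gut_geometry()$length_L  # total luminal volume ~2.9e-3 m3
#' @export
build_grid <- function(geometry, n_cells = 285,
                       rel_tol = 1e-8, abs_tol = 1e-12) {
  stopifnot(inherits(geometry, "gut_geometry"))
  if (!is.numeric(n_cells) || n_cells != round(n_cells) || n_cells < 50) {
    stop("configuration error: 'n_cells' must be an integer >= 50",
         call. = FALSE)
  }
  for (tl in c(rel_tol = rel_tol, abs_tol = abs_tol)) {
    if (!is.numeric(tl) || tl <= 0 || tl >= 1e-2) {
      stop("configuration error: tolerances must lie in (0, 1e-2)",
           call. = FALSE)
    }
  }
  n_cells <- as.integer(n_cells)
  dz <- geometry$length_L / n_cells
  structure(
    list(
      centers = (seq_len(n_cells) - 0.5) * dz,
      dz = dz, n = n_cells,
      area = pi * geometry$radius_rm^2,
      volume = pi * geometry$radius_rm^2 * geometry$length_L,
      rel_tol = rel_tol, abs_tol = abs_tol,
      geometry = geometry
    ),
    class = "gut_grid"
  )
}

#' Initial bolus concentration profile
#'
#' Places `mass` grams uniformly over `[0, l0]` (the entering bolus sits at
#' the proximal end, `l0` being its radius), i.e. concentration
#' `mass / (A * l0)` with the cell straddling `l0` partially filled so the
#' discrete total mass is exact.
#'
#' @param mass bolus mass (g).
#' @param l0 bolus extent from the intestinal entrance (m), in `(0, L)`.
#' @param grid a [build_grid()] result.
#' @return concentration vector (g/m^3), one value per cell.
#' @export
initial_bolus <- function(mass, l0, grid) {
  stopifnot(inherits(grid, "gut_grid"))
  .check_positive(mass, "mass", strict = FALSE)
  L <- grid$geometry$length_L
  if (!is.numeric(l0) || l0 <= 0 || l0 >= L) {
    stop(sprintf("field 'l0' must lie strictly inside (0, %g) m", L),
         call. = FALSE)
  }
  conc0 <- mass / (grid$area * l0)
  # overlap of each cell [z_i - dz/2, z_i + dz/2] with [0, l0]
  lo <- grid$centers - grid$dz / 2
  hi <- grid$centers + grid$dz / 2
  overlap <- pmax(0, pmin(hi, l0) - lo)
  conc0 * overlap / grid$dz
}

# index of the cell containing axial position z (source injection point)
.cell_index <- function(z, grid) {
  i <- findInterval(z, c(0, grid$centers + grid$dz / 2), rightmost.closed = TRUE)
  min(max(i, 1L), grid$n)
}
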