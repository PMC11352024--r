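#' Fluid properties of hemolymph
#'
#' Bundles the dynamic viscosity and mass density of the working fluid.
#' Defaults are the literature values used throughout the package: a
#' hemolymph viscosity of 1.3e-3 Pa s and density of 1.02e3 kg/m^3.
#'
#' @param viscosity Dynamic viscosity in Pa s. Must be positive.
#' @param density Mass density in kg/m^3. Must be positive.
#'
#' @return An object of class `fluid_properties`: a named list with elements
#'   `viscosity` and `density`.
#' @export
#'
#' @examples
#' fluid_properties()
#' fluid_properties(viscosity = 1e-3, density = 1000) # water-like
fluid_properties <- function(viscosity = 1.3e-3, density = 1.02e3) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L || !is.finite(viscosity) ||
      viscosity <= 0) {
    abort_veinflow("`viscosity` must be a single positive number.",
                   class = "veinflow_invalid_fluid_error")
  }
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    abort_veinflow("`density` must be a single positive number.",
                   class = "veinflow_invalid_fluid_error")
  }
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties>\n")
  cat("  viscosity:", format(x$viscosity), "Pa s\n")
  cat("  density:  ", format(x$density), "kg/m^3\n")
  invisible(x)
}

#' Hydraulic resistance of a cylindrical conduit (Poiseuille's law)
#'
#' For fully developed laminar flow in a circular pipe, the frictional
#' pressure loss is proportional to the volumetric flow rate,
#' \eqn{\Delta p = r q}, with hydraulic resistance
#' \eqn{r = 128 \mu l / (\pi d^4)}. The steep inverse fourth-power
#' dependence on the lumen diameter is what makes constricted veins
#' expensive to perfuse.
#'
#' @param length Conduit length in metres (vectorised, each >= 0).
#' @param diameter Inner (lumen) diameter in metres (vectorised, each > 0).
#' @param viscosity Dynamic viscosity in Pa s (> 0).
#'
#' @return Hydraulic resistance(s) in Pa s/m^3.
#' @export
#'
#' @examples
#' # the extra crossvein of D. cyrtoloma: l = 0.62 mm, d = 7.4 um
#' poiseuille_resistance(6.2e-4, 7.4e-6)
poiseuille_resistance <- function(length, diameter, viscosity = 1.3e-3) {
  if (!is.numeric(length) || !is.numeric(diameter) ||
      any(!is.finite(length)) || any(!is.finite(diameter))) {
    abort_veinflow("`length` and `diameter` must be finite numerics.",
                   class = "veinflow_invalid_geometry_error")
  }
  if (any(length < 0)) {
    abort_veinflow("`length` must be non-negative.",
                   class = "veinflow_invalid_geometry_error")
  }
  if (any(diameter <= 0)) {
    abort_veinflow("`diameter` must be strictly positive.",
                   class = "veinflow_invalid_geometry_error")
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0) {
    abort_veinflow("`viscosity` must be a single positive number.",
                   class = "veinflow_invalid_geometry_error")
  }
  128 * viscosity * length / (pi * diameter^4)
}

#' Reynolds number of pipe flow
#'
#' \eqn{Re = \rho v d / \mu}. For hemolymph creeping through wing veins at
#' velocities of order 100 um/s in lumens of order 10 um, Re stays below
#' 1e-3, so inertia (and with it every minor loss at bends and junctions)
#' is negligible against viscous friction.
#'
#' @param props A [fluid_properties()] object.
#' @param velocity Mean flow speed in m/s (>= 0).
#' @param diameter Pipe diameter in metres (> 0).
#'
#' @return The dimensionless Reynolds number.
#' @export
#'
#' @examples
#' reynolds_number(fluid_properties(), velocity = 1e-4, diameter = 1e-5)
reynolds_number <- function(props, velocity, diameter) {
  stopifnot(inherits(props, "fluid_properties"))
  if (!is.numeric(velocity) || any(velocity < 0)) {
    abort_veinflow("`velocity` must be non-negative.",
                   class = "veinflow_invalid_geometry_error")
  }
  if (!is.numeric(diameter) || any(diameter <= 0)) {
    abort_veinflow("`diameter` must be positive.",
                   class = "veinflow_invalid_geometry_error")
  }
  props$density * velocity * diameter / props$viscosity
}

#' Multiplicative uncertainty bounds on computed hydraulic resistance
#'
#' Because \eqn{r \propto l / d^4}, relative measurement errors in length
#' and especially diameter propagate strongly into the resistance. With a
#' relative diameter error `e_d` and length error `e_l`, the computed
#' resistance can range between `(1/(1 + e_d))^4 (1 - e_l)` and
#' `(1/(1 - e_d))^4 (1 + e_l)` times the true value. The image-analysis
#' errors for the wing measurements (20% on diameter, 1.4% on length)
#' give the often-quoted 0.48-2.5x band.
#'
#' @param diameter_rel_error Relative diameter error, in `[0, 1)`.
#' @param length_rel_error Relative length error, in `[0, 1)`.
#'
#' @return A tibble with one row: `low_factor`, `high_factor`.
#' @export
#'
#' @examples
#' resistance_uncertainty_bounds(0.20, 0.014)
resistance_uncertainty_bounds <- function(diameter_rel_error,
                                          length_rel_error = 0) {
  for (e in list(diameter_rel_error, length_rel_error)) {
    if (!is.numeric(e) || length(e) != 1L || e < 0 || e >= 1) {
      abort_veinflow("Relative errors must be single numbers in [0, 1).",
                     class = "veinflow_invalid_geometry_error")
    }
  }
  tibble::tibble(
    low_factor  = (1 / (1 + diameter_rel_error))^4 * (1 - length_rel_error),
    high_factor = (1 / (1 - diameter_rel_error))^4 * (1 + length_rel_error)
  )
}
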