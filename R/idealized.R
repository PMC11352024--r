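#' Specification of an idealized microchannel circuit
#'
#' A four-section ladder circuit abstracting the crossvein-bearing part of
#' the wing (fourth to seventh vein sections): two rails of four full
#' channels each, three rungs made of two half-length connecting channels
#' joined at midpoint nodes, an extra-crossvein resistor bridging the
#' fourth and fifth rung midpoints, and a posterior-crossvein resistor
#' bridging the fifth and sixth. Full channels are 2 mm long, connecting
#' halves 1 mm, all with a uniform 10 um diameter, so every full channel
#' has the reference resistance `R` and every half `0.5 R`.
#'
#' Variants redistribute resistance the way the real wing does:
#' \describe{
#'   \item{`uniform`}{all channels at their geometric values.}
#'   \item{`asymmetric`}{fifth base-rail channel set to `0.2 R` and sixth
#'     edge-rail channel to `200 R` -- the extreme resistances found in the
#'     fourth-to-seventh sections of the measured wing.}
#'   \item{`asymmetric_highC`}{additionally the fourth and fifth
#'     connecting halves at `10 R` (initial position), reflecting the
#'     connecting veins' roughly tenfold resistance relative to the extra
#'     crossvein.}
#' }
#'
#' @param variant One of `"uniform"`, `"asymmetric"`, `"asymmetric_highC"`.
#' @param unit_length_mm Full channel length in mm.
#' @param half_length_mm Connecting-half length in mm.
#' @param diameter_um Channel diameter in um.
#' @param fluid A [fluid_properties()].
#' @param inflow Boundary inflow in m^3/s.
#'
#' @return An `idealized_spec` object; element `R` holds the reference
#'   resistance in Pa s/m^3.
#' @export
#'
#' @examples
#' idealized_spec("uniform")
idealized_spec <- function(variant = c("uniform", "asymmetric",
                                       "asymmetric_highC"),
                           unit_length_mm = 2, half_length_mm = 1,
                           diameter_um = 10,
                           fluid = fluid_properties(),
                           inflow = 12e-15) {
  variant <- match.arg(variant)
  R <- poiseuille_resistance(unit_length_mm * 1e-3, diameter_um * 1e-6,
                             fluid$viscosity)
  half_mult <- if (variant == "asymmetric_highC") 10 else
    half_length_mm / unit_length_mm
  structure(
    list(variant = variant,
         unit_length_mm = unit_length_mm,
         half_length_mm = half_length_mm,
         diameter_um = diameter_um,
         fluid = fluid, inflow = inflow,
         R = R,
         rail_mult = c(
           E4 = 1, E5 = 1,
           E6 = if (variant == "uniform") 1 else 200,
           E7 = 1, B4 = 1,
           B5 = if (variant == "uniform") 1 else 0.2,
           B6 = 1, B7 = 1),
         # resistance of a connecting half at its initial 1 mm length,
         # in units of R
         half_mult = half_mult),
    class = "idealized_spec")
}

#' @export
print.idealized_spec <- function(x, ...) {
  cat("<idealized_spec> variant:", x$variant, "\n")
  cat("  R =", format(x$R), "Pa s/m^3 (", x$unit_length_mm, "mm x",
      x$diameter_um, "um channel )\n")
  invisible(x)
}

#' Build an idealized circuit as a hydraulic network
#'
#' @param spec An [idealized_spec()].
#'
#' @return A `hydraulic_network` with 12 nodes and 16 channels; remove the
#'   crossvein resistor with [ablate()].
#' @export
#'
#' @examples
#' net <- build_idealized(idealized_spec("uniform"))
#' sol <- solve_nodal(ablate(net, "ECV"))
#' tidy(sol)[tidy(sol)$id == "PCV", "flow_fraction"]
build_idealized <- function(spec = idealized_spec()) {
  stopifnot(inherits(spec, "idealized_spec"))
  R <- spec$R
  hm <- spec$half_mult
  rl <- spec$rail_mult
  channels <- tibble::tribble(
    ~id, ~node_a, ~node_b, ~resistance,
    "E4", "IN", "e1", rl[["E4"]] * R,
    "E5", "e1", "e2", rl[["E5"]] * R,
    "E6", "e2", "e3", rl[["E6"]] * R,
    "E7", "e3", "OUT", rl[["E7"]] * R,
    "B4", "IN", "b1", rl[["B4"]] * R,
    "B5", "b1", "b2", rl[["B5"]] * R,
    "B6", "b2", "b3", rl[["B6"]] * R,
    "B7", "b3", "OUT", rl[["B7"]] * R,
    "C4_E", "e1", "A", hm * R,
    "C4_B", "A", "b1", hm * R,
    "C5_E", "e2", "X", hm * R,
    "C5_B", "X", "b2", hm * R,
    "C6_E", "e3", "Y", 0.5 * R,
    "C6_B", "Y", "b3", 0.5 * R,
    "ECV", "A", "X", R,
    "PCV", "X", "Y", R
  )
  hydraulic_network(channels, inlet = "IN", outlet = "OUT",
                    inflow = spec$inflow, fluid = spec$fluid)
}

#' Sweep the crossvein resistor's connection positions in an idealized circuit
#'
#' Moves the crossvein resistor's inlet-side connection along the fourth
#' rung (base-side fraction `u`) and its outlet-side connection along the
#' fifth rung (fraction `v`), with the posterior-crossvein junction fixed
#' at the fifth rung's midpoint. Connecting segments and the crossvein
#' keep fixed diameters, so their resistances scale with length: the two
#' rungs are modelled as parallel segments one full channel length apart,
#' and the crossvein length is the straight-line distance between its
#' connections. Each position's total loss is normalized by the
#' crossvein-free loss of the same variant.
#'
#' @inheritParams build_idealized
#' @param u_grid,v_grid Numeric vectors of fractions in (0, 1); the
#'   initial position is `(0.5, 0.5)`.
#'
#' @return A `sweep_surface` tibble with columns `u`, `v`, `total_loss`,
#'   `norm_loss`.
#' @export
#'
#' @examples
#' surf <- sweep_idealized(idealized_spec("uniform"),
#'                         u_grid = c(0.25, 0.5, 0.75),
#'                         v_grid = c(0.25, 0.5, 0.75))
#' glance(surf)
sweep_idealized <- function(spec = idealized_spec(),
                            u_grid = seq(0.05, 0.95, by = 0.05),
                            v_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(spec, "idealized_spec"),
            all(u_grid > 0 & u_grid < 1), all(v_grid > 0 & v_grid < 1))
  base <- build_idealized(spec)
  reference <- solve_nodal(ablate(base, "ECV"))$total_loss

  R <- spec$R
  L <- spec$unit_length_mm              # rung length and rail spacing (mm)
  per_mm <- spec$half_mult * R / spec$half_length_mm
  ecv_per_mm <- R / spec$unit_length_mm

  fixed <- base$channels[!base$channels$id %in%
                           c("C4_E", "C4_B", "C5_E", "C5_B", "ECV"), ]
  nodes <- c(base$nodes, "P")
  ni <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  fa <- unname(ni[fixed$node_a]); fb <- unname(ni[fixed$node_b])
  fr <- fixed$resistance
  inlet_i <- ni[[base$inlet]]; outlet_i <- ni[[base$outlet]]
  iA <- ni[["A"]]; iX <- ni[["X"]]; iP <- ni[["P"]]
  ie1 <- ni[["e1"]]; ib1 <- ni[["b1"]]; ie2 <- ni[["e2"]]; ib2 <- ni[["b2"]]

  cell_loss <- function(u, v) {
    r_c4e <- per_mm * L * (1 - u)
    r_c4b <- per_mm * L * u
    r_ecv <- ecv_per_mm * sqrt(L^2 + (L * u - L * v)^2)
    if (abs(v - 0.5) < 1e-12) {
      ea <- c(fa, ie1, iA, ie2, iX, iA)
      eb <- c(fb, iA, ib1, iX, ib2, iX)
      rr <- c(fr, r_c4e, r_c4b, per_mm * L / 2, per_mm * L / 2, r_ecv)
      p_sol <- tryCatch(
        conductance_pressures(ea, eb, rr, n - 1L, inlet_i, outlet_i,
                              base$inflow),
        error = function(e) rep(NA_real_, n - 1L))
      return(p_sol[inlet_i])
    }
    if (v < 0.5) {
      ea <- c(fa, ie1, iA, ie2, iX, iP, iA)
      eb <- c(fb, iA, ib1, iX, iP, ib2, iP)
      rr <- c(fr, r_c4e, r_c4b, per_mm * L / 2,
              per_mm * L * (0.5 - v), per_mm * L * v, r_ecv)
    } else {
      ea <- c(fa, ie1, iA, ie2, iP, iX, iA)
      eb <- c(fb, iA, ib1, iP, iX, ib2, iP)
      rr <- c(fr, r_c4e, r_c4b, per_mm * L * (1 - v),
              per_mm * L * (v - 0.5), per_mm * L / 2, r_ecv)
    }
    p_sol <- tryCatch(
      conductance_pressures(ea, eb, rr, n, inlet_i, outlet_i, base$inflow),
      error = function(e) rep(NA_real_, n))
    p_sol[inlet_i]
  }

  grid <- tidyr::expand_grid(u = u_grid, v = v_grid)
  grid$total_loss <- purrr::map2_dbl(grid$u, grid$v, cell_loss)
  grid$norm_loss <- grid$total_loss / reference
  new_sweep_surface(grid, axes = c("v", "u"), reference_loss = reference)
}

#' Valley steepness of an idealized sweep surface
#'
#' The extra normalized loss paid for moving the outlet-side connection a
#' distance `delta` off the posterior-crossvein junction at a fixed
#' inlet-side position: a scalar summary of how sharply the loss valley
#' rises, used to compare resistance-distribution variants.
#'
#' @param spec An [idealized_spec()].
#' @param u Fixed inlet-side fraction.
#' @param delta Offset of the outlet-side connection from the junction.
#'
#' @return `norm_loss(u, 0.5 + delta) - norm_loss(u, 0.5)`.
#' @export
valley_steepness <- function(spec, u = 0.5, delta = 0.2) {
  surf <- sweep_idealized(spec, u_grid = u, v_grid = c(0.5, 0.5 + delta))
  surf$norm_loss[surf$v == 0.5 + delta] - surf$norm_loss[surf$v == 0.5]
}
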