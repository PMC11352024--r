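#' Linear allometric scaling factor from a wing area ratio
#'
#' Under isometry a wing whose area is `area_ratio` times larger is
#' `sqrt(area_ratio)` times longer in every linear dimension. The Hawaiian
#' fly's wing area is 8.3 times the common fruit fly's, giving k = 2.9 at
#' two significant figures; volumes (and with them masses and volumetric
#' flow rates) scale as k^3.
#'
#' @param area_ratio Positive wing area ratio.
#'
#' @return The linear scaling factor k.
#' @export
#'
#' @examples
#' scaling_factor(8.3)
scaling_factor <- function(area_ratio) {
  if (!is.numeric(area_ratio) || any(area_ratio <= 0)) {
    abort_veinflow("`area_ratio` must be positive.",
                   class = "veinflow_invalid_geometry_error")
  }
  sqrt(area_ratio)
}

#' Isometric wing mass prediction
#'
#' Scales a reference wing mass by k^3. With the common fruit fly's wing
#' at 2.7 ug and k = 2.9, the Hawaiian fly's wing (without the extra
#' crossvein) comes to about 65 ug. The full-precision k = sqrt(8.3)
#' gives 64.6 ug; pass the rounded k explicitly to follow the
#' two-significant-figure convention.
#'
#' @param reference_mass Reference wing mass in ug.
#' @param k Linear scaling factor.
#'
#' @return Predicted wing mass in ug.
#' @export
#'
#' @examples
#' isometric_wing_mass(2.7, 2.9)
#' isometric_wing_mass(2.7, scaling_factor(8.3))
isometric_wing_mass <- function(reference_mass, k) {
  if (!is.numeric(reference_mass) || any(reference_mass <= 0) ||
      !is.numeric(k) || any(k <= 0)) {
    abort_veinflow("`reference_mass` and `k` must be positive.",
                   class = "veinflow_invalid_geometry_error")
  }
  reference_mass * k^3
}

#' Mass of a crossvein: internal hemolymph plus cuticle wall
#'
#' The vein is a cylindrical shell: the lumen volume
#' `pi/4 * inner_d^2 * length` filled with hemolymph, and the wall volume
#' `pi/4 * (outer_d^2 - inner_d^2) * length` of wing cuticle.
#'
#' @param length Vein length in metres.
#' @param inner_d,outer_d Inner and outer diameters in metres
#'   (`outer_d >= inner_d > 0`).
#' @param rho_hemolymph Hemolymph density in kg/m^3 (default 1.02e3).
#' @param rho_cuticle Wing cuticle density in kg/m^3 (default 1150).
#'
#' @return A tibble with one row: `lumen_mass_ug`, `wall_mass_ug`,
#'   `total_mass_ug`.
#' @export
#'
#' @examples
#' # the measured extra crossvein: 0.62 mm long, 7.4 um lumen, 37 um outer
#' crossvein_mass(0.62e-3, 7.4e-6, 37e-6)
crossvein_mass <- function(length, inner_d, outer_d,
                           rho_hemolymph = 1.02e3, rho_cuticle = 1150) {
  if (!is.numeric(length) || any(length < 0)) {
    abort_veinflow("`length` must be non-negative.",
                   class = "veinflow_invalid_geometry_error")
  }
  if (!is.numeric(inner_d) || !is.numeric(outer_d) || any(inner_d <= 0) ||
      any(outer_d < inner_d)) {
    abort_veinflow("Diameters must satisfy outer_d >= inner_d > 0.",
                   class = "veinflow_invalid_geometry_error")
  }
  kg_to_ug <- 1e9
  lumen <- pi / 4 * inner_d^2 * length * rho_hemolymph * kg_to_ug
  wall <- pi / 4 * (outer_d^2 - inner_d^2) * length * rho_cuticle * kg_to_ug
  tibble::tibble(lumen_mass_ug = lumen, wall_mass_ug = wall,
                 total_mass_ug = lumen + wall)
}

#' Crossvein mass as a percentage of wing mass
#'
#' @param ecv_total_mass Crossvein mass in ug.
#' @param wing_mass Wing mass in ug (> 0).
#'
#' @return `100 * ecv_total_mass / wing_mass`.
#' @export
#'
#' @examples
#' mass_increase_percent(0.77 + 0.028, 65)
mass_increase_percent <- function(ecv_total_mass, wing_mass) {
  if (!is.numeric(wing_mass) || any(wing_mass <= 0)) {
    abort_veinflow("`wing_mass` must be positive.",
                   class = "veinflow_invalid_geometry_error")
  }
  100 * ecv_total_mass / wing_mass
}

#' The full allometry and mass budget of the extra crossvein
#'
#' Combines the scaling and mass operations into the cost side of the
#' crossvein's cost-benefit account: the isometrically predicted wing
#' mass, the crossvein's hemolymph and wall mass from its measured
#' geometry, and the relative wing-mass increase its presence entails.
#'
#' @param area_ratio Wing area ratio (default 8.3).
#' @param reference_wing_mass_ug Reference (common fruit fly) wing mass.
#' @param k Scaling factor; `NULL` (default) uses `sqrt(area_ratio)` at
#'   full precision, or pass the printed 2.9 convention explicitly.
#' @param veins Vein geometry table containing an `ECV` row, by default
#'   [cyrtoloma_veins()].
#' @param rho_hemolymph,rho_cuticle Densities in kg/m^3.
#' @param inflow_pl_s Boundary inflow in pl/s, used for the k^3-scaled
#'   reference-flow consistency value.
#'
#' @return A one-row tibble: `k`, `wing_mass_ug`, `lumen_mass_ug`,
#'   `wall_mass_ug`, `ecv_mass_ug`, `mass_increase_percent`,
#'   `reference_flow_pl_s`.
#' @export
#'
#' @examples
#' allometry_report()
#' allometry_report(k = 2.9)
allometry_report <- function(area_ratio = 8.3, reference_wing_mass_ug = 2.7,
                             k = NULL, veins = cyrtoloma_veins(),
                             rho_hemolymph = 1.02e3, rho_cuticle = 1150,
                             inflow_pl_s = 12) {
  if (is.null(k)) k <- scaling_factor(area_ratio)
  ecv <- veins[veins$vein_id == "ECV", ]
  if (nrow(ecv) != 1) {
    abort_veinflow("`veins` must contain exactly one ECV row.",
                   class = "veinflow_missing_id_error")
  }
  wing <- isometric_wing_mass(reference_wing_mass_ug, k)
  mass <- crossvein_mass(ecv$length_mm * 1e-3,
                         ecv$inner_diameter_mm * 1e-3,
                         ecv$outer_diameter_mm * 1e-3,
                         rho_hemolymph, rho_cuticle)
  tibble::tibble(
    k = k,
    wing_mass_ug = wing,
    lumen_mass_ug = mass$lumen_mass_ug,
    wall_mass_ug = mass$wall_mass_ug,
    ecv_mass_ug = mass$total_mass_ug,
    mass_increase_percent = mass_increase_percent(mass$total_mass_ug, wing),
    reference_flow_pl_s = inflow_pl_s / k^3
  )
}
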