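test_that("linear scaling factor is the square root of the area ratio", {
  expect_equal(scaling_factor(8.3), sqrt(8.3))
  expect_equal(round(scaling_factor(8.3), 1), 2.9)
  expect_equal(scaling_factor(1), 1)
  expect_equal(scaling_factor(4), 2)
  expect_error(scaling_factor(-1), class = "veinflow_invalid_geometry_error")
})

test_that("isometric wing mass scales with the cube of the length factor", {
  expect_equal(isometric_wing_mass(2.7, 1), 2.7)
  expect_equal(isometric_wing_mass(2.7, sqrt(8.3)), 2.7 * 8.3^1.5)
  expect_equal(isometric_wing_mass(2.7, sqrt(8.3)), 64.6, tolerance = 0.001)
  # the printed-rounding convention k = 2.9 lands on 65 ug
  expect_equal(isometric_wing_mass(2.7, 2.9), 65, tolerance = 0.02)
})

test_that("crossvein mass splits into hemolymph lumen and cuticle wall", {
  m <- crossvein_mass(0.62e-3, 7.4e-6, 37e-6)
  # forward computation from the rounded measured inputs, against the
  # reported 2.8e-2 ug lumen and 0.77 ug wall (5% input-rounding slack)
  expect_equal(m$lumen_mass_ug, 2.8e-2, tolerance = 0.05)
  expect_equal(m$wall_mass_ug, 0.77, tolerance = 0.05)
  expect_equal(m$total_mass_ug, m$lumen_mass_ug + m$wall_mass_ug)

  # degenerate geometries
  expect_equal(crossvein_mass(0.62e-3, 1e-5, 1e-5)$wall_mass_ug, 0)
  expect_equal(crossvein_mass(0, 7.4e-6, 37e-6)$total_mass_ug, 0)
  expect_error(crossvein_mass(1e-3, 2e-5, 1e-5),
               class = "veinflow_invalid_geometry_error")

  # linear in length and density; lumen/wall labels only interchangeable
  # at equal densities
  m2 <- crossvein_mass(1.24e-3, 7.4e-6, 37e-6)
  expect_equal(m2$total_mass_ug, 2 * m$total_mass_ug)
  meq <- crossvein_mass(1e-3, 1e-5, 2e-5, rho_hemolymph = 1000,
                        rho_cuticle = 1000)
  swapped <- crossvein_mass(1e-3, sqrt(2e-5^2 - 1e-5^2), 2e-5,
                            rho_hemolymph = 1000, rho_cuticle = 1000)
  expect_equal(meq$total_mass_ug, swapped$total_mass_ug, tolerance = 1e-12)
})

test_that("the crossvein costs about a percent of wing mass", {
  expect_equal(mass_increase_percent(0.77 + 0.028, 65), 1.23, tolerance = 0.01)
  expect_equal(mass_increase_percent(0, 65), 0)
  expect_error(mass_increase_percent(1, 0),
               class = "veinflow_invalid_geometry_error")

  rep <- allometry_report()
  expect_equal(signif(rep$mass_increase_percent, 2), 1.2)
  # the k^3-scaled inflow implies the common fly's reference rate
  expect_equal(rep$reference_flow_pl_s, 12 / 8.3^1.5)
  expect_equal(rep$reference_flow_pl_s, 0.49, tolerance = 0.03)
  # printed-k convention stays at 1.2% too
  expect_equal(signif(allometry_report(k = 2.9)$mass_increase_percent, 2), 1.2)
})
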