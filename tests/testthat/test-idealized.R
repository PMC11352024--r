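test_that("the uniform circuit reproduces its exact flow shares and losses", {
  spec <- idealized_spec("uniform")
  net <- build_idealized(spec)
  R <- spec$R
  Q <- spec$inflow

  without <- solve_nodal(ablate(net, "ECV"))
  q0 <- stats::setNames(without$channels$flow, without$channels$id)
  expect_equal(abs(q0[["PCV"]]) / Q, 0.25, tolerance = 1e-12)
  expect_equal(without$total_loss, 1.875 * R * Q, tolerance = 1e-12)
  # without the crossvein the fourth rung carries nothing (mirror symmetry)
  expect_equal(unname(abs(q0[c("C4_E", "C4_B")])) / Q, c(0, 0),
               tolerance = 1e-12)
  # edge- and base-rail flows are mirror images channel by channel
  for (i in 4:7) {
    expect_equal(q0[[paste0("E", i)]], q0[[paste0("B", i)]],
                 tolerance = 1e-12)
  }

  with_ecv <- solve_nodal(net)
  q1 <- stats::setNames(with_ecv$channels$flow, with_ecv$channels$id)
  expect_equal(abs(q1[["ECV"]]) / Q, 2 / 7, tolerance = 1e-12)
  expect_equal(abs(q1[["PCV"]]) / Q, 2 / 7, tolerance = 1e-12)
  # the fifth connecting resistor loses its flow entirely
  expect_equal(unname(abs(q1[c("C5_E", "C5_B")])) / Q, c(0, 0),
               tolerance = 1e-12)
  expect_equal(with_ecv$total_loss, (12 / 7) * R * Q, tolerance = 1e-12)
  expect_equal(reduction_percent(without$total_loss, with_ecv$total_loss),
               100 * 6 / 70, tolerance = 1e-12)
})

test_that("variant circuits apply their resistance redistributions", {
  R <- idealized_spec("uniform")$R
  asym <- build_idealized(idealized_spec("asymmetric"))
  r <- stats::setNames(asym$channels$resistance, asym$channels$id)
  expect_equal(r[["B5"]], 0.2 * R)
  expect_equal(r[["E6"]], 200 * R)
  expect_equal(r[["C4_E"]], 0.5 * R)

  high <- build_idealized(idealized_spec("asymmetric_highC"))
  rh <- stats::setNames(high$channels$resistance, high$channels$id)
  expect_equal(rh[["C4_E"]], 10 * R)
  expect_equal(rh[["C5_B"]], 10 * R)
  expect_equal(rh[["C6_B"]], 0.5 * R)  # sixth rung unchanged
  expect_equal(rh[["B5"]], 0.2 * R)
})

test_that("uniform position sweep is symmetric with its minimum at the initial position", {
  grid <- seq(0.1, 0.9, by = 0.1)
  surf <- sweep_idealized(idealized_spec("uniform"), grid, grid)
  df <- tidy(surf)
  expect_true(all(is.finite(df$norm_loss)))
  am <- attr(surf, "argmin")
  expect_equal(c(am$u, am$v), c(0.5, 0.5))

  key <- function(u, v) paste(round(u * 1000), round(v * 1000))
  mir <- stats::setNames(df$norm_loss, key(df$u, df$v))
  expect_equal(unname(mir[key(1 - df$u, 1 - df$v)]), df$norm_loss,
               tolerance = 1e-10)
})

test_that("the outlet-side minimum stays at the crossvein junction in all variants", {
  grid <- seq(0.1, 0.9, by = 0.2)
  for (variant in c("uniform", "asymmetric", "asymmetric_highC")) {
    surf <- sweep_idealized(idealized_spec(variant), grid,
                            v_grid = seq(0.1, 0.9, by = 0.1))
    df <- tidy(surf)
    for (u in unique(df$u)) {
      prof <- df[df$u == u, ]
      expect_equal(prof$v[which.min(prof$norm_loss)], 0.5)
    }
  }
})

test_that("resistance asymmetry steepens the valley", {
  s_uni <- valley_steepness(idealized_spec("uniform"))
  s_asym <- valley_steepness(idealized_spec("asymmetric"))
  s_high <- valley_steepness(idealized_spec("asymmetric_highC"))
  expect_gt(s_uni, 0)
  expect_lt(s_uni, s_asym)
  expect_lt(s_asym, s_high)
})
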