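test_that("the calibrated geometry reproduces the measured crossvein length", {
  geom <- reposition_geometry()
  expect_equal(veinflow:::ecv_length_mm(geom, geom$a_actual, geom$p_actual),
               0.62, tolerance = 1e-12)
  expect_error(reposition_geometry(ecv_length_actual = 0.01),
               class = "veinflow_invalid_geometry_error")
})

test_that("repositioning at the actual connection fractions recovers the wing model", {
  base <- build_cyrtoloma_network()
  repos <- reposition_network(base, a = 0.486, p = 0.506)
  # sub-segment lengths differ from the rounded printed ones by < 1%, so the
  # total loss must agree to well within that
  expect_equal(solve_nodal(repos)$total_loss, solve_nodal(base)$total_loss,
               tolerance = 5e-3)
})

test_that("splitting conserves vein length and drops the transfer segment at contiguity", {
  base <- build_cyrtoloma_network()
  geom <- reposition_geometry()

  at_junction <- reposition_network(base, geom, a = 0.3, p = geom$x_pcv)
  expect_false("V_C_5_T" %in% at_junction$channels$id)
  expect_equal(nrow(at_junction$channels), 25)

  for (p in c(0.2, 0.85)) {
    net <- reposition_network(base, geom, a = 0.3, p = p)
    expect_true("V_C_5_T" %in% net$channels$id)
    ch <- net$channels
    c5 <- sum(ch$length[ch$id %in% c("V_C_5_E", "V_C_5_T", "V_C_5_B")])
    expect_equal(c5 * 1e3, geom$l_c5, tolerance = 1e-12)
    c4 <- sum(ch$length[ch$id %in% c("V_C_4_E", "V_C_4_B")])
    expect_equal(c4 * 1e3, geom$l_c4, tolerance = 1e-12)
  }

  expect_error(reposition_network(base, geom, a = 0, p = 0.5),
               class = "veinflow_invalid_geometry_error")
  expect_error(reposition_network(base, geom, a = 0.5, p = 1),
               class = "veinflow_invalid_geometry_error")
})

test_that("the loss penalty off the junction grows with the transfer length", {
  base <- build_cyrtoloma_network()
  geom <- reposition_geometry()
  # hold the crossvein's own length fixed so only the transfer segment varies
  losses <- sapply(c(0.506, 0.6, 0.7, 0.8), function(p) {
    solve_nodal(reposition_network(base, geom, a = 0.486, p = p,
                                   ecv_length = 0.62))$total_loss
  })
  expect_true(all(diff(losses) > 0))
})

test_that("the sweep surface has its valley minimum at the crossvein junction", {
  geom <- reposition_geometry()
  surf <- sweep_positions(a_grid = c(0.3, 0.486, 0.7),
                          p_grid = sort(c(seq(0.1, 0.9, by = 0.1),
                                          geom$x_pcv)))
  df <- tidy(surf)
  expect_true(all(is.finite(df$norm_loss)))
  expect_true(all(df$norm_loss > 0))
  for (a in unique(df$a)) {
    prof <- df[df$a == a, ]
    expect_equal(prof$p[which.min(prof$norm_loss)], geom$x_pcv)
  }
  am <- attr(surf, "argmin")
  expect_equal(am$p, geom$x_pcv)

  # loss shrinks as the anterior connection approaches the edge vein
  trend <- df$norm_loss[df$p == geom$x_pcv][order(df$a[df$p == geom$x_pcv])]
  expect_true(all(diff(trend) < 0))
})

test_that("glance and tidy summarise a sweep surface", {
  surf <- sweep_positions(a_grid = c(0.4, 0.6), p_grid = c(0.4, 0.506, 0.6))
  expect_equal(nrow(tidy(surf)), 6)
  gl <- glance(surf)
  expect_equal(gl$n_cells, 6)
  expect_lt(gl$min_norm_loss, gl$max_norm_loss)
})
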