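test_that("ladder generation is deterministic and correctly sized", {
  spec <- ladder_spec(n_rungs = 4, seed = 99)
  a <- random_ladder(spec)
  b <- random_ladder(spec)
  expect_identical(a, b)

  # 2(n+1) rail channels + n rungs
  expect_equal(nrow(a$topology), 2 * 5 + 4)
  expect_equal(sort(a$veins$vein_id), sort(a$topology$channel_id))
  expect_true(all(a$veins$length_mm > 0))
  expect_true(all(a$veins$inner_diameter_mm > 0))
  expect_equal(a$veins$inner_diameter_mm / a$veins$outer_diameter_mm,
               rep(0.2, nrow(a$veins)), tolerance = 1e-4)

  c <- random_ladder(ladder_spec(n_rungs = 4, seed = 100))
  expect_false(identical(a$veins$length_mm, c$veins$length_mm))
})

test_that("crossvein insertion splits the rungs and links their midpoints", {
  cv <- data.frame(rung_a = 2, rung_b = 3, frac_a = 0.4, frac_b = 0.6)
  lad <- random_ladder(ladder_spec(n_rungs = 4, seed = 5, crossveins = cv))
  # two rungs replaced by split halves (+2) plus the crossvein (+1)
  expect_equal(nrow(lad$topology), 14 + 3)
  expect_true(all(c("V_C_2_E", "V_C_2_B", "V_C_3_E", "V_C_3_B", "CV_2_3")
                  %in% lad$topology$channel_id))
  v <- lad$veins
  split_sum <- v$length_mm[v$vein_id == "V_C_2_E"] +
    v$length_mm[v$vein_id == "V_C_2_B"]
  # halves conserve the parent length to the table's stored precision
  expect_equal(
    v$length_mm[v$vein_id == "V_C_2_B"] / split_sum, 0.4, tolerance = 1e-4)

  net <- build_network(lad$veins, lad$topology, "IN", "OUT", inflow = 12e-15)
  expect_lte(max_node_residual(solve_nodal(net)), 1e-9 * net$inflow)
})

test_that("ladder specs validate their inputs", {
  expect_error(ladder_spec(0, seed = 1),
               class = "veinflow_invalid_geometry_error")
  expect_error(ladder_spec(3, length_sdlog = 0, seed = 1),
               class = "veinflow_invalid_geometry_error")
  expect_error(ladder_spec(3), class = "veinflow_invalid_geometry_error")
  expect_error(
    ladder_spec(3, seed = 1,
                crossveins = data.frame(rung_a = 2, rung_b = 2,
                                        frac_a = 0.5, frac_b = 0.5)),
    class = "veinflow_invalid_geometry_error")
})

test_that("generated tables survive a write/read round trip unchanged", {
  lad <- random_ladder(ladder_spec(n_rungs = 5, seed = 21))
  vp <- withr::local_tempfile(fileext = ".tsv")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_vein_table(lad$veins, vp)
  write_topology(lad$topology, tp)
  expect_equal(as.data.frame(read_vein_table(vp)),
               as.data.frame(lad$veins))
  expect_equal(as.data.frame(read_topology(tp)),
               as.data.frame(lad$topology))
})
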