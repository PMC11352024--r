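test_that("the wing network has the ladder-with-crossveins structure", {
  net <- build_cyrtoloma_network()
  expect_length(net$nodes, 17)
  expect_equal(nrow(net$channels), 25)

  degree <- table(c(net$channels$node_a, net$channels$node_b))
  # the cruciform node: fifth connecting vein halves + both crossveins
  expect_equal(unname(degree[["X"]]), 4L)
  x_channels <- net$channels$id[net$channels$node_a == "X" |
                                  net$channels$node_b == "X"]
  expect_setequal(x_channels, c("V_C_5_E", "V_C_5_B", "ECV", "PCV"))

  noecv <- ablate(net, "ECV")
  degree2 <- table(c(noecv$channels$node_a, noecv$channels$node_b))
  expect_equal(unname(degree2[["A"]]), 2L)
})

test_that("building fails cleanly on missing or duplicate veins", {
  veins <- cyrtoloma_veins()
  expect_error(build_cyrtoloma_network(veins[veins$vein_id != "ECV", ]),
               class = "veinflow_missing_id_error")
  expect_error(build_cyrtoloma_network(rbind(veins, veins[1, ])),
               class = "veinflow_malformed_table_error")
  net <- build_cyrtoloma_network()
  expect_error(ablate(net, "nonesuch"), class = "veinflow_missing_id_error")
  once <- ablate(net, "ECV")
  expect_error(ablate(once, "ECV"), class = "veinflow_missing_id_error")
})

test_that("the crossvein drains the fifth vein pair and feeds the posterior crossvein", {
  net <- build_cyrtoloma_network()
  with_ecv <- solve_nodal(net)
  without <- solve_nodal(ablate(net, "ECV"))
  q <- function(sol, id) sol$channels$flow[sol$channels$id == id]

  # the crossvein's intake equals the flow lost by the fifth edge/base pair
  drained <- (abs(q(without, "V_E_5")) - abs(q(with_ecv, "V_E_5"))) +
    (abs(q(without, "V_B_5")) - abs(q(with_ecv, "V_B_5")))
  expect_equal(abs(q(with_ecv, "ECV")), drained, tolerance = 1e-6)

  # posterior crossvein flow rises by about 30%
  expect_equal(abs(q(with_ecv, "PCV")) / abs(q(without, "PCV")), 1.30,
               tolerance = 0.01)

  # fifth and sixth pairs all slow down when the crossvein is present
  for (id in c("V_E_5", "V_B_5", "V_E_6", "V_B_6")) {
    expect_lt(abs(q(with_ecv, id)), abs(q(without, id)))
  }

  # without the crossvein the bypass still runs: the common fruit-fly route
  # into the posterior crossvein via the fifth/sixth connecting segments
  for (id in c("PCV", "V_C_5_E", "V_C_5_B", "V_C_6_E", "V_C_6_B")) {
    expect_gt(abs(q(without, id)), 0.001 * net$inflow)
  }
})

test_that("flow-change classification separates gains, losses and reversals", {
  net <- build_cyrtoloma_network()
  with_ecv <- solve_nodal(net)
  without <- solve_nodal(ablate(net, "ECV"))
  cmp <- compare_flows(with_ecv, without)

  expect_false("ECV" %in% cmp$id)  # present only in one network
  expect_equal(cmp$category[cmp$id == "V_C_5_B"], "no_flow")
  expect_true(cmp$reversed[cmp$id == "V_C_4_B"])
  expect_equal(cmp$category[cmp$id == "PCV"], "increase")
  expect_equal(cmp$category[cmp$id == "V_E_6"], "decrease")

  self_cmp <- compare_flows(with_ecv, with_ecv)
  expect_true(all(self_cmp$change_rate == 0))
  expect_false(any(self_cmp$reversed))

  expect_error(compare_flows(without, with_ecv),
               class = "veinflow_missing_id_error")
})

test_that("reduction percent behaves as a relative improvement", {
  expect_equal(reduction_percent(100, 96.9), 3.1)
  expect_equal(reduction_percent(5, 5), 0)
  expect_error(reduction_percent(0, 1),
               class = "veinflow_invalid_geometry_error")
})

test_that("ablation_experiment bundles both solves and their comparison", {
  exp <- ablation_experiment(build_cyrtoloma_network())
  expect_named(exp, c("with", "without", "changes", "summary"))
  expect_equal(exp$summary$reduction_percent,
               reduction_percent(exp$summary$loss_without_pa,
                                 exp$summary$loss_with_pa))
  expect_gt(exp$summary$reduction_percent, 0)
})
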