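test_that("both solvers reproduce every closed-form fixture circuit", {
  for (fx in fixture_circuits()) {
    for (solver in list(solve_nodal, solve_mesh)) {
      sol <- solver(fx$network)
      q <- stats::setNames(sol$channels$flow, sol$channels$id)
      expect_equal(unname(q[names(fx$flows)]), unname(fx$flows),
                   tolerance = 1e-12)
      expect_equal(sol$total_loss, fx$total_loss, tolerance = 1e-12)
    }
  }
})

test_that("flow solutions satisfy conservation, loop and energy identities", {
  for (fx in fixture_circuits()) {
    sol <- solve_nodal(fx$network)
    expect_lte(max_node_residual(sol), 1e-9 * fx$network$inflow)
    if (sol$total_loss > 0) {
      expect_lte(max_loop_residual(fx$network, sol), 1e-9 * sol$total_loss)
      expect_lte(energy_identity_error(sol), 1e-8)
    }
    expect_equal(sol$nodes$pressure[sol$nodes$node == "OUT"], 0)
    expect_equal(sol$total_loss,
                 sol$nodes$pressure[sol$nodes$node == "IN"])
  }
})

test_that("solution is invariant to channel and node ordering", {
  fx <- fixture_circuits()$wheatstone_balanced
  shuffled <- fx$network$channels[c(4, 1, 5, 3, 2), ]
  net2 <- hydraulic_network(shuffled, inlet = "IN", outlet = "OUT",
                            inflow = fx$network$inflow)
  s1 <- solve_nodal(fx$network)
  s2 <- solve_nodal(net2)
  q1 <- stats::setNames(s1$channels$flow, s1$channels$id)
  q2 <- stats::setNames(s2$channels$flow, s2$channels$id)
  expect_equal(q2[names(q1)], q1, tolerance = 1e-12)
  expect_equal(s2$total_loss, s1$total_loss, tolerance = 1e-12)
})

test_that("removing a channel that carries no flow leaves the solution unchanged", {
  fx <- fixture_circuits()$wheatstone_balanced
  before <- solve_nodal(fx$network)
  expect_equal(before$channels$flow[before$channels$id == "r3"], 0,
               tolerance = 1e-15)
  after <- solve_nodal(ablate(fx$network, "r3"))
  shared <- intersect(before$channels$id, after$channels$id)
  qb <- stats::setNames(before$channels$flow, before$channels$id)[shared]
  qa <- stats::setNames(after$channels$flow, after$channels$id)[shared]
  expect_equal(qa, qb, tolerance = 1e-12)
  expect_equal(after$total_loss, before$total_loss, tolerance = 1e-12)
})

test_that("rescaling all resistances rescales pressures and preserves flows", {
  net <- random_ladder_network(seed = 11)
  scaled <- hydraulic_network(
    dplyr::mutate(net$channels, resistance = resistance * 7.5,
                  length = NULL, diameter = NULL),
    inlet = "IN", outlet = "OUT", inflow = net$inflow)
  s1 <- solve_nodal(net)
  s2 <- solve_nodal(scaled)
  expect_equal(s2$channels$flow, s1$channels$flow, tolerance = 1e-10)
  expect_equal(s2$total_loss, 7.5 * s1$total_loss, tolerance = 1e-10)
})

test_that("degenerate and singular networks raise classed errors", {
  bad <- tibble::tibble(id = c("a", "b"), node_a = c("IN", "M"),
                        node_b = c("M", "OUT"), resistance = c(1, 0))
  net <- hydraulic_network(bad, "IN", "OUT", inflow = 1)
  expect_error(solve_nodal(net), class = "veinflow_degenerate_network_error")
  expect_error(solve_mesh(net), class = "veinflow_degenerate_network_error")

  expect_error(
    hydraulic_network(
      tibble::tibble(id = c("a", "b"), node_a = c("IN", "P"),
                     node_b = c("M", "OUT"), resistance = c(1, 1)),
      "IN", "OUT", inflow = 1),
    class = "veinflow_singular_network_error")

  expect_error(
    hydraulic_network(
      tibble::tibble(id = "a", node_a = "IN", node_b = "OUT",
                     resistance = 1),
      "IN", "IN", inflow = 1),
    class = "veinflow_malformed_table_error")
})

test_that("tidy and glance expose the solution tables", {
  sol <- solve_nodal(fixture_circuits()$series_pair$network)
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("id", "node_a", "node_b", "resistance", "flow",
                     "loss", "flow_fraction"))
  gl <- glance(sol)
  expect_equal(gl$n_channels, 2L)
  expect_equal(gl$total_loss, 3)
  expect_equal(gl$method, "nodal")
})

test_that("autoplot methods return ggplot objects", {
  net <- build_cyrtoloma_network()
  sol <- solve_nodal(net)
  expect_s3_class(autoplot(sol), "ggplot")
  cmp <- compare_flows(sol, solve_nodal(ablate(net, "ECV")))
  expect_s3_class(autoplot(cmp), "ggplot")
  surf <- sweep_idealized(idealized_spec("uniform"),
                          u_grid = c(0.3, 0.5, 0.7),
                          v_grid = c(0.3, 0.5, 0.7))
  expect_s3_class(autoplot(surf), "ggplot")
})
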