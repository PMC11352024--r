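# Shared helpers for solver and property tests.

# A seeded random ladder (optionally with a crossvein between rung midpoints)
# assembled into a hydraulic_network at the wing-scale inflow.
random_ladder_network <- function(seed, n_rungs = 5, crossveins = NULL,
                                  inflow = 12e-15) {
  lad <- random_ladder(ladder_spec(n_rungs = n_rungs, seed = seed,
                                   crossveins = crossveins))
  build_network(lad$veins, lad$topology, inlet = "IN", outlet = "OUT",
                inflow = inflow)
}

# Residual of Kirchhoff's current law at every interior node.
max_node_residual <- function(solution) {
  ch <- solution$channels
  outgoing <- tapply(ch$flow, ch$node_a, sum)
  incoming <- tapply(ch$flow, ch$node_b, sum)
  nodes <- solution$nodes$node
  net <- sapply(nodes, function(v) {
    s <- 0
    if (v %in% names(incoming)) s <- s + incoming[[v]]
    if (v %in% names(outgoing)) s <- s - outgoing[[v]]
    s
  })
  interior <- !(nodes %in% c(solution$inlet, solution$outlet))
  if (!any(interior)) return(0)
  max(abs(net[interior]))
}

# Max |sum of signed losses| over a fundamental cycle basis of the network.
max_loop_residual <- function(network, solution) {
  g <- igraph::graph_from_data_frame(
    network$channels[, c("node_a", "node_b", "id")], directed = FALSE)
  loss <- stats::setNames(solution$channels$loss, solution$channels$id)
  a_of <- stats::setNames(solution$channels$node_a, solution$channels$id)
  mst <- igraph::mst(g, weights = rep(1, igraph::ecount(g)))
  chords <- igraph::difference(g, mst)
  if (igraph::ecount(chords) == 0) return(0)
  worst <- 0
  for (k in seq_len(igraph::ecount(chords))) {
    ends <- igraph::ends(chords, k)
    chord_id <- igraph::edge_attr(chords, "id", k)
    path <- igraph::shortest_paths(mst, from = ends[2], to = ends[1],
                                   output = "both")
    path_nodes <- names(path$vpath[[1]])
    path_ids <- igraph::edge_attr(mst, "id", path$epath[[1]])
    total <- loss[[chord_id]] * (if (a_of[[chord_id]] == ends[1]) 1 else -1)
    for (i in seq_along(path_ids)) {
      sgn <- if (a_of[[path_ids[i]]] == path_nodes[i]) 1 else -1
      total <- total + sgn * loss[[path_ids[i]]]
    }
    worst <- max(worst, abs(total))
  }
  worst
}

energy_identity_error <- function(solution) {
  dissipated <- sum(solution$channels$resistance * solution$channels$flow^2)
  supplied <- solution$total_loss * solution$inflow
  abs(dissipated - supplied) / supplied
}
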