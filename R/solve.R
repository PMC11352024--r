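check_solvable <- function(network) {
  r <- network$channels$resistance
  if (any(r <= 0)) {
    abort_veinflow(
      "Network contains channel(s) with non-positive resistance; the steady-state solve is degenerate.",
      class = "veinflow_degenerate_network_error")
  }
}

# Dense grounded-Laplacian solve on integer-indexed edges. Returns node
# pressures (outlet grounded at 0). Used by solve_nodal() and, directly,
# by the sweep fast paths where thousands of small solves are needed.
conductance_pressures <- function(ai, bi, r, n, inlet_i, outlet_i, inflow) {
  g <- 1 / r
  G <- matrix(0, n, n)
  for (e in seq_along(ai)) {
    a <- ai[e]; b <- bi[e]; ge <- g[e]
    G[a, a] <- G[a, a] + ge
    G[b, b] <- G[b, b] + ge
    G[a, b] <- G[a, b] - ge
    G[b, a] <- G[b, a] - ge
  }
  keep <- seq_len(n) != outlet_i
  rhs <- numeric(n)
  rhs[inlet_i] <- inflow
  p <- numeric(n)
  p[keep] <- solve(G[keep, keep, drop = FALSE], rhs[keep])
  p
}

new_flow_solution <- function(network, pressures, method) {
  ch <- network$channels
  p_a <- pressures[ch$node_a]
  p_b <- pressures[ch$node_b]
  flow <- unname((p_a - p_b) / ch$resistance)
  out <- tibble::tibble(
    id = ch$id, node_a = ch$node_a, node_b = ch$node_b,
    resistance = ch$resistance,
    flow = flow,
    loss = ch$resistance * flow,
    flow_fraction = abs(flow) / network$inflow
  )
  structure(
    list(
      channels = out,
      nodes = tibble::tibble(node = network$nodes,
                             pressure = unname(pressures[network$nodes])),
      total_loss = unname(pressures[network$inlet]),
      inflow = network$inflow,
      inlet = network$inlet, outlet = network$outlet,
      method = method
    ),
    class = "flow_solution")
}

#' Solve a hydraulic network by nodal (conductance) analysis
#'
#' Imposes mass conservation at every node (Kirchhoff's current law) on the
#' node-pressure unknowns: the grounded conductance Laplacian is assembled,
#' the outlet pressure is fixed at zero, the boundary inflow enters at the
#' inlet, and the resulting dense linear system is solved directly in
#' double precision. Channel flows follow from the pressure differences and
#' Poiseuille resistances, which makes energy conservation around every
#' closed loop automatic.
#'
#' @param network A [hydraulic_network()].
#'
#' @return A `flow_solution`: per-channel signed flows (positive from
#'   `node_a` to `node_b`), per-channel pressure losses, node pressures
#'   relative to the outlet, and the total inlet-to-outlet loss.
#'   [tidy()][generics::tidy] extracts the per-channel tibble and
#'   [glance()][generics::glance] the one-row summary.
#' @export
#'
#' @examples
#' net <- build_cyrtoloma_network()
#' sol <- solve_nodal(net)
#' glance(sol)
solve_nodal <- function(network) {
  stopifnot(inherits(network, "hydraulic_network"))
  check_solvable(network)
  ch <- network$channels
  nodes <- network$nodes
  n <- length(nodes)
  ni <- stats::setNames(seq_len(n), nodes)
  ai <- ni[ch$node_a]; bi <- ni[ch$node_b]

  p <- tryCatch(
    conductance_pressures(ai, bi, ch$resistance, n,
                          ni[[network$inlet]], ni[[network$outlet]],
                          network$inflow),
    error = function(e) {
      abort_veinflow(
        paste0("Conductance matrix is singular (disconnected or degenerate network): ",
               conditionMessage(e)),
        class = "veinflow_singular_network_error")
    })
  names(p) <- nodes
  new_flow_solution(network, p, method = "nodal")
}

# --- mesh / loop-current analysis ------------------------------------------

# Spanning tree by union-find over the channel list; returns logical vector.
spanning_tree_edges <- function(ai, bi, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_tree <- logical(length(ai))
  for (e in seq_along(ai)) {
    ra <- find(ai[e]); rb <- find(bi[e])
    if (ra != rb) {
      parent[ra] <- rb
      in_tree[e] <- TRUE
    }
  }
  in_tree
}

# Root the tree at `root`; returns parent node, connecting edge, and depth
# per node (NA for the root and for nodes in other components).
root_tree <- function(ai, bi, in_tree, n, root) {
  adj <- vector("list", n)
  for (e in which(in_tree)) {
    adj[[ai[e]]] <- c(adj[[ai[e]]], e)
    adj[[bi[e]]] <- c(adj[[bi[e]]], e)
  }
  par_node <- rep(NA_integer_, n)
  par_edge <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  queue <- root
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    for (e in adj[[v]]) {
      w <- if (ai[e] == v) bi[e] else ai[e]
      if (is.na(depth[w])) {
        depth[w] <- depth[v] + 1L
        par_node[w] <- v
        par_edge[w] <- e
        queue <- c(queue, w)
      }
    }
  }
  list(par_node = par_node, par_edge = par_edge, depth = depth)
}

# Signed tree path from u to v: edges with +1 if traversed node_a -> node_b.
tree_path_signs <- function(u, v, tree, ai) {
  up <- integer(0); up_sign <- integer(0)      # u -> lca
  down <- integer(0); down_sign <- integer(0)  # lca -> v (built backwards)
  du <- tree$depth[u]; dv <- tree$depth[v]
  while (du > dv) {
    e <- tree$par_edge[u]
    up <- c(up, e); up_sign <- c(up_sign, if (ai[e] == u) 1L else -1L)
    u <- tree$par_node[u]; du <- du - 1L
  }
  while (dv > du) {
    e <- tree$par_edge[v]
    # traversed parent -> v on the way down, opposite of v's parent link
    down <- c(e, down); down_sign <- c(if (ai[e] == v) -1L else 1L, down_sign)
    v <- tree$par_node[v]; dv <- dv - 1L
  }
  while (u != v) {
    e <- tree$par_edge[u]
    up <- c(up, e); up_sign <- c(up_sign, if (ai[e] == u) 1L else -1L)
    u <- tree$par_node[u]
    e <- tree$par_edge[v]
    down <- c(e, down); down_sign <- c(if (ai[e] == v) -1L else 1L, down_sign)
    v <- tree$par_node[v]
  }
  list(edges = c(up, down), signs = c(up_sign, down_sign))
}

#' Solve a hydraulic network by mesh (loop-current) analysis
#'
#' The dual formulation: a spanning tree of the channel graph is built, each
#' remaining chord defines a fundamental closed loop, and the unknowns are
#' the loop flow rates. Kirchhoff's voltage law -- the signed pressure
#' losses around every closed loop sum to zero, except around the loop
#' containing the pressure source, where they sum to the total loss --
#' yields a symmetric linear system in the loop flows. Mass conservation at
#' the nodes is automatic by construction.
#'
#' `solve_mesh()` shares no linear-algebra route with [solve_nodal()]; the
#' two serve as independent cross-checks of one another.
#'
#' @inheritParams solve_nodal
#' @return A `flow_solution`, identical in contract to [solve_nodal()].
#' @export
#'
#' @examples
#' net <- build_cyrtoloma_network()
#' glance(solve_mesh(net))
solve_mesh <- function(network) {
  stopifnot(inherits(network, "hydraulic_network"))
  check_solvable(network)
  ch <- network$channels
  nodes <- network$nodes
  n <- length(nodes)
  ni <- stats::setNames(seq_len(n), nodes)
  ai <- unname(ni[ch$node_a]); bi <- unname(ni[ch$node_b])
  m <- length(ai)
  r <- ch$resistance

  in_tree <- spanning_tree_edges(ai, bi, n)
  tree <- root_tree(ai, bi, in_tree, n, root = ni[[network$outlet]])
  if (is.na(tree$depth[ni[[network$inlet]]])) {
    abort_veinflow("`inlet` and `outlet` are not connected.",
                   class = "veinflow_singular_network_error")
  }

  chords <- which(!in_tree)
  k <- length(chords)

  # loop-edge incidence: S[e, j] = sign of edge e in chord j's loop
  S <- matrix(0, nrow = m, ncol = k)
  for (j in seq_len(k)) {
    e <- chords[j]
    S[e, j] <- 1
    path <- tree_path_signs(bi[e], ai[e], tree, ai)
    S[cbind(path$edges, j)] <- path$signs
  }
  # the source loop: virtual channel outlet -> inlet carrying the inflow,
  # returning through the tree from inlet to outlet
  s0 <- numeric(m)
  src <- tree_path_signs(ni[[network$inlet]], ni[[network$outlet]], tree, ai)
  s0[src$edges] <- src$signs

  if (k > 0) {
    RS <- r * S
    A <- crossprod(S, RS)                     # S' R S
    y <- -crossprod(S, r * s0) * network$inflow
    x <- tryCatch(solve(A, y), error = function(e) {
      abort_veinflow(paste0("Loop system is singular: ", conditionMessage(e)),
                     class = "veinflow_singular_network_error")
    })
    q <- as.vector(S %*% x) + s0 * network$inflow
  } else {
    q <- s0 * network$inflow
  }

  # reconstruct node pressures down the tree from the grounded outlet
  p <- rep(NA_real_, n)
  p[ni[[network$outlet]]] <- 0
  order_by_depth <- order(tree$depth, na.last = NA)
  for (v in order_by_depth) {
    pv <- tree$par_node[v]
    if (is.na(pv)) next
    e <- tree$par_edge[v]
    p[v] <- if (ai[e] == v) p[pv] + r[e] * q[e] else p[pv] - r[e] * q[e]
  }
  names(p) <- nodes
  new_flow_solution(network, p, method = "mesh")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> (", x$method, " analysis)\n", sep = "")
  cat("  total loss: ", format(x$total_loss), " Pa (",
      format(signif(x$total_loss / 1e3, 3)), " kPa) at inflow ",
      format(x$inflow / 1e-15), " pl/s\n", sep = "")
  print(x$channels, n = 8)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname solve_nodal
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @method tidy flow_solution
#' @export
tidy.flow_solution <- function(x, ...) {
  x$channels
}

#' @rdname solve_nodal
#' @method glance flow_solution
#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(
    total_loss = x$total_loss,
    total_loss_kpa = x$total_loss / 1e3,
    inflow = x$inflow,
    n_nodes = nrow(x$nodes),
    n_channels = nrow(x$channels),
    method = x$method
  )
}

#' @rdname solve_nodal
#' @param object A `flow_solution`.
#' @method autoplot flow_solution
#' @export
autoplot.flow_solution <- function(object, ...) {
  dat <- object$channels %>%
    dplyr::mutate(
      direction = ifelse(.data$flow >= 0, "node_a → node_b",
                         "node_b → node_a"),
      id = factor(.data$id, levels = .data$id)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$id, y = .data$flow_fraction,
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression("|q| / " * Q["in"]),
                  fill = "direction",
                  title = "Channel flow shares") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
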