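#' Specification for a random ladder network
#'
#' Describes a family of synthetic vein networks with the same structure
#' the wing analysis assumes: two serial rails sharing their terminal
#' nodes, joined by rungs, optionally with crossveins inserted between
#' rung midpoints. Lengths and diameters are drawn from log-normal
#' distributions whose defaults bracket the measured wing's ranges
#' (lengths 0.16-5.0 mm, lumen diameters 2.9-32 um).
#'
#' @param n_rungs Number of rungs (>= 1).
#' @param length_meanlog,length_sdlog Log-normal parameters for segment
#'   lengths in mm.
#' @param diameter_meanlog,diameter_sdlog Log-normal parameters for lumen
#'   diameters in um.
#' @param crossveins Optional data frame with columns `rung_a`, `rung_b`,
#'   `frac_a`, `frac_b`: each row inserts a crossvein between the two
#'   rungs, splitting each at the given base-side fraction.
#' @param seed Integer seed; the spec fully determines the generated
#'   network.
#'
#' @return A `ladder_spec` object.
#' @export
#'
#' @examples
#' ladder_spec(n_rungs = 4, seed = 1)
ladder_spec <- function(n_rungs, length_meanlog = log(1.0),
                        length_sdlog = 0.8,
                        diameter_meanlog = log(9.6), diameter_sdlog = 0.6,
                        crossveins = NULL, seed) {
  if (!is.numeric(n_rungs) || length(n_rungs) != 1L || n_rungs < 1) {
    abort_veinflow("`n_rungs` must be >= 1.",
                   class = "veinflow_invalid_geometry_error")
  }
  if (length_sdlog <= 0 || diameter_sdlog <= 0) {
    abort_veinflow("Log-normal scale parameters must be positive.",
                   class = "veinflow_invalid_geometry_error")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    abort_veinflow("`seed` is required and must be a single integer.",
                   class = "veinflow_invalid_geometry_error")
  }
  if (!is.null(crossveins)) {
    crossveins <- tibble::as_tibble(crossveins)
    need <- c("rung_a", "rung_b", "frac_a", "frac_b")
    if (!all(need %in% names(crossveins))) {
      abort_veinflow(paste0("`crossveins` needs columns: ",
                            paste(need, collapse = ", ")),
                     class = "veinflow_malformed_table_error")
    }
    if (any(crossveins$rung_a < 1) || any(crossveins$rung_b > n_rungs) ||
        any(crossveins$rung_a >= crossveins$rung_b)) {
      abort_veinflow("`crossveins` rung indices must satisfy 1 <= rung_a < rung_b <= n_rungs.",
                     class = "veinflow_invalid_geometry_error")
    }
  }
  structure(
    list(n_rungs = as.integer(n_rungs),
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         diameter_meanlog = diameter_meanlog, diameter_sdlog = diameter_sdlog,
         crossveins = crossveins, seed = as.integer(seed)),
    class = "ladder_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random ladder network table and topology
#'
#' Draws a connected shared-terminal ladder in the same vein-table and
#' topology formats as the packaged wing model, so every downstream stage
#' (file IO, network assembly, both solvers) can be exercised without any
#' measurement data. Outer diameters follow the 20%-lumen convention.
#' The same spec (including seed) always yields the identical network.
#'
#' @param spec A [ladder_spec()].
#'
#' @return A list with elements `veins` (tibble: `vein_id`, `length_mm`,
#'   `outer_diameter_mm`, `inner_diameter_mm`) and `topology` (tibble:
#'   `channel_id`, `node_a`, `node_b`); inlet `IN`, outlet `OUT`.
#' @export
#'
#' @examples
#' lad <- random_ladder(ladder_spec(n_rungs = 3, seed = 42))
#' net <- build_network(lad$veins, lad$topology, "IN", "OUT", inflow = 12e-15)
#' glance(solve_nodal(net))
random_ladder <- function(spec) {
  stopifnot(inherits(spec, "ladder_spec"))
  n <- spec$n_rungs
  with_seed(spec$seed, {
    rail_nodes <- function(prefix) c("IN", paste0(prefix, seq_len(n)), "OUT")
    e_nodes <- rail_nodes("E")
    b_nodes <- rail_nodes("B")
    draw_len <- function(k) signif(stats::rlnorm(k, spec$length_meanlog,
                                                 spec$length_sdlog), 6)
    draw_diam <- function(k) signif(stats::rlnorm(k, spec$diameter_meanlog,
                                                  spec$diameter_sdlog) * 1e-3,
                                    6)  # um -> mm

    topo <- tibble::tibble(
      channel_id = c(paste0("V_E_", seq_len(n + 1)),
                     paste0("V_B_", seq_len(n + 1)),
                     paste0("V_C_", seq_len(n))),
      node_a = c(e_nodes[seq_len(n + 1)], b_nodes[seq_len(n + 1)],
                 paste0("E", seq_len(n))),
      node_b = c(e_nodes[seq_len(n + 1) + 1], b_nodes[seq_len(n + 1) + 1],
                 paste0("B", seq_len(n)))
    )
    lengths <- draw_len(nrow(topo))
    diams <- draw_diam(nrow(topo))
    veins <- tibble::tibble(
      vein_id = topo$channel_id,
      length_mm = lengths,
      inner_diameter_mm = diams,
      outer_diameter_mm = signif(diams / 0.2, 6)
    )

    if (!is.null(spec$crossveins)) {
      for (i in seq_len(nrow(spec$crossveins))) {
        cv <- spec$crossveins[i, ]
        for (side in c("a", "b")) {
          rung <- cv[[paste0("rung_", side)]]
          frac <- cv[[paste0("frac_", side)]]
          rid <- paste0("V_C_", rung)
          if (!rid %in% topo$channel_id) next  # already split
          row <- which(topo$channel_id == rid)
          vrow <- which(veins$vein_id == rid)
          jn <- paste0("J", rung)
          total <- veins$length_mm[vrow]
          d <- veins$inner_diameter_mm[vrow]
          topo <- dplyr::bind_rows(
            topo[-row, ],
            tibble::tibble(channel_id = paste0(rid, c("_E", "_B")),
                           node_a = c(topo$node_a[row], jn),
                           node_b = c(jn, topo$node_b[row])))
          veins <- dplyr::bind_rows(
            veins[-vrow, ],
            tibble::tibble(vein_id = paste0(rid, c("_E", "_B")),
                           length_mm = signif(total * c(1 - frac, frac), 6),
                           inner_diameter_mm = d,
                           outer_diameter_mm = signif(d / 0.2, 6)))
        }
        cv_id <- paste0("CV_", cv$rung_a, "_", cv$rung_b)
        cv_len <- draw_len(1)
        cv_d <- draw_diam(1)
        topo <- dplyr::bind_rows(
          topo, tibble::tibble(channel_id = cv_id,
                               node_a = paste0("J", cv$rung_a),
                               node_b = paste0("J", cv$rung_b)))
        veins <- dplyr::bind_rows(
          veins, tibble::tibble(vein_id = cv_id, length_mm = cv_len,
                                inner_diameter_mm = cv_d,
                                outer_diameter_mm = signif(cv_d / 0.2, 6)))
      }
    }
    list(veins = veins[, c("vein_id", "length_mm", "outer_diameter_mm",
                           "inner_diameter_mm")],
         topology = topo)
  })
}

#' Reference circuits with closed-form solutions
#'
#' Small fixture networks whose flows and total losses are known
#' analytically by series/parallel reduction or symmetry, used as ground
#' truth for both solvers: a single pipe, two resistors in series and in
#' parallel, a balanced Wheatstone bridge, the classic five-resistor
#' three-loop circuit with unit resistances, and the uniform idealized
#' ladder (crossvein absent), whose posterior-crossvein resistor carries
#' exactly a quarter of the inflow.
#'
#' @return A named list; each element has `network` (a
#'   `hydraulic_network`), `flows` (named vector of expected signed
#'   channel flows) and `total_loss`.
#' @export
#'
#' @examples
#' fx <- fixture_circuits()
#' names(fx)
#' solve_nodal(fx$single_pipe$network)$total_loss  # == fx$single_pipe$total_loss
fixture_circuits <- function() {
  net <- function(df, inflow = 1) {
    hydraulic_network(df, inlet = "IN", outlet = "OUT", inflow = inflow)
  }
  fx <- list()

  fx$single_pipe <- list(
    network = net(tibble::tibble(id = "p1", node_a = "IN", node_b = "OUT",
                                 resistance = 2), inflow = 3),
    flows = c(p1 = 3), total_loss = 6)

  fx$series_pair <- list(
    network = net(tibble::tibble(id = c("p1", "p2"),
                                 node_a = c("IN", "M"),
                                 node_b = c("M", "OUT"),
                                 resistance = c(1, 2))),
    flows = c(p1 = 1, p2 = 1), total_loss = 3)

  fx$parallel_pair <- list(
    network = net(tibble::tibble(id = c("top", "bottom"),
                                 node_a = "IN", node_b = "OUT",
                                 resistance = c(2, 2))),
    flows = c(top = 0.5, bottom = 0.5), total_loss = 1)

  # balanced bridge: r1/r2 = r4/r5, so the bridge arm carries nothing and
  # the two branches split the inflow inversely to their series resistance
  fx$wheatstone_balanced <- list(
    network = net(tibble::tribble(
      ~id, ~node_a, ~node_b, ~resistance,
      "r1", "IN", "T", 1,
      "r2", "T", "OUT", 2,
      "r4", "IN", "M", 2,
      "r5", "M", "OUT", 4,
      "r3", "T", "M", 1)),
    flows = c(r1 = 2 / 3, r2 = 2 / 3, r4 = 1 / 3, r5 = 1 / 3, r3 = 0),
    total_loss = 2)

  # the five-resistor, three-loop circuit with unit resistances: both
  # loop flows are Q/2 and the source loop loss equals R*Q
  fx$five_resistor_loops <- list(
    network = net(tibble::tribble(
      ~id, ~node_a, ~node_b, ~resistance,
      "r1", "IN", "T", 1,
      "r2", "T", "OUT", 1,
      "r3", "T", "M", 1,
      "r4", "IN", "M", 1,
      "r5", "M", "OUT", 1)),
    flows = c(r1 = 0.5, r2 = 0.5, r3 = 0, r4 = 0.5, r5 = 0.5),
    total_loss = 1)

  # uniform idealized ladder without the extra crossvein (unit R, unit Q):
  # rails carry Q/2 except the sixth pair, bypassed by a quarter of the
  # inflow through the crossvein compound
  fx$uniform_ladder_no_ecv <- list(
    network = net(tibble::tribble(
      ~id, ~node_a, ~node_b, ~resistance,
      "E4", "IN", "e1", 1, "E5", "e1", "e2", 1,
      "E6", "e2", "e3", 1, "E7", "e3", "OUT", 1,
      "B4", "IN", "b1", 1, "B5", "b1", "b2", 1,
      "B6", "b2", "b3", 1, "B7", "b3", "OUT", 1,
      "C4_E", "e1", "A", 0.5, "C4_B", "A", "b1", 0.5,
      "C5_E", "e2", "X", 0.5, "C5_B", "X", "b2", 0.5,
      "C6_E", "e3", "Y", 0.5, "C6_B", "Y", "b3", 0.5,
      "PCV", "X", "Y", 1)),
    flows = c(E4 = 0.5, E5 = 0.5, E6 = 0.375, E7 = 0.5,
              B4 = 0.5, B5 = 0.5, B6 = 0.375, B7 = 0.5,
              C4_E = 0, C4_B = 0,
              C5_E = 0.125, C5_B = -0.125,
              C6_E = -0.125, C6_B = 0.125,
              PCV = 0.25),
    total_loss = 1.875)

  fx
}
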