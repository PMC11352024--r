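#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

abort_veinflow <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "veinflow_error"), ...)
}

#' Construct a hydraulic resistor network
#'
#' A hydraulic network is a planar graph of cylindrical channels between
#' named nodes, with a designated inlet and outlet and a fixed boundary
#' volumetric inflow. Each channel either carries explicit geometry
#' (`length`, `diameter`, both in metres), from which its Poiseuille
#' resistance is derived, or an explicit `resistance` override
#' (Pa s/m^3) as used by the idealized circuit models.
#'
#' @param channels A data frame with columns `id`, `node_a`, `node_b`
#'   and either (`length`, `diameter`) in SI units or `resistance`
#'   (Pa s/m^3); an `outer_diameter` column (m) is retained if present.
#'   Channel ids must be unique and `node_a != node_b` for every row.
#' @param inlet,outlet Node ids of the boundary nodes; must differ and be
#'   connected through the channel graph.
#' @param inflow Boundary volumetric inflow rate in m^3/s (> 0). The paper
#'   scale for a Hawaiian fly wing is 12 pl/s = `12e-15` m^3/s.
#' @param fluid A [fluid_properties()] object, used to derive resistances
#'   from geometry.
#'
#' @return An object of class `hydraulic_network`: a list with a `channels`
#'   tibble (including derived `resistance`), `nodes`, `inlet`, `outlet`,
#'   `inflow`, and `fluid`.
#' @export
#'
#' @examples
#' net <- hydraulic_network(
#'   tibble::tibble(
#'     id = c("left", "right"), node_a = "IN", node_b = "OUT",
#'     resistance = c(2, 2)
#'   ),
#'   inlet = "IN", outlet = "OUT", inflow = 1
#' )
#' solve_nodal(net)
hydraulic_network <- function(channels, inlet, outlet, inflow,
                              fluid = fluid_properties()) {
  channels <- tibble::as_tibble(channels)
  required <- c("id", "node_a", "node_b")
  missing <- setdiff(required, names(channels))
  if (length(missing) > 0) {
    abort_veinflow(paste0("`channels` lacks column(s): ",
                          paste(missing, collapse = ", ")),
                   class = "veinflow_malformed_table_error")
  }
  if (nrow(channels) == 0) {
    abort_veinflow("`channels` must contain at least one channel.",
                   class = "veinflow_malformed_table_error")
  }
  channels$id <- as.character(channels$id)
  channels$node_a <- as.character(channels$node_a)
  channels$node_b <- as.character(channels$node_b)
  if (anyDuplicated(channels$id)) {
    abort_veinflow("Duplicate channel ids.",
                   class = "veinflow_malformed_table_error")
  }
  if (any(channels$node_a == channels$node_b)) {
    abort_veinflow("Self-loop channels (node_a == node_b) are not allowed.",
                   class = "veinflow_malformed_table_error")
  }

  has_geom <- all(c("length", "diameter") %in% names(channels))
  if (!("resistance" %in% names(channels))) {
    if (!has_geom) {
      abort_veinflow(
        "`channels` needs either a `resistance` column or `length` + `diameter`.",
        class = "veinflow_malformed_table_error")
    }
    channels$resistance <- poiseuille_resistance(
      channels$length, channels$diameter, fluid$viscosity)
  } else if (has_geom) {
    # explicit resistance wins; keep geometry for mass/length bookkeeping
    idx <- is.na(channels$resistance)
    if (any(idx)) {
      channels$resistance[idx] <- poiseuille_resistance(
        channels$length[idx], channels$diameter[idx], fluid$viscosity)
    }
  }
  if (any(!is.finite(channels$resistance)) || any(channels$resistance < 0)) {
    abort_veinflow("Channel resistances must be finite and non-negative.",
                   class = "veinflow_invalid_geometry_error")
  }
  if ("outer_diameter" %in% names(channels) && has_geom) {
    bad <- !is.na(channels$outer_diameter) &
      channels$outer_diameter < channels$diameter
    if (any(bad)) {
      abort_veinflow("`outer_diameter` must be >= inner `diameter`.",
                     class = "veinflow_invalid_geometry_error")
    }
  }

  nodes <- unique(c(channels$node_a, channels$node_b))
  inlet <- as.character(inlet); outlet <- as.character(outlet)
  if (identical(inlet, outlet)) {
    abort_veinflow("`inlet` and `outlet` must differ.",
                   class = "veinflow_malformed_table_error")
  }
  if (!all(c(inlet, outlet) %in% nodes)) {
    abort_veinflow("`inlet` and `outlet` must appear among the channel end nodes.",
                   class = "veinflow_malformed_table_error")
  }
  if (!is.numeric(inflow) || length(inflow) != 1L || !is.finite(inflow) ||
      inflow <= 0) {
    abort_veinflow("`inflow` must be a single positive number (m^3/s).",
                   class = "veinflow_malformed_table_error")
  }

  net <- structure(
    list(channels = channels, nodes = nodes, inlet = inlet, outlet = outlet,
         inflow = inflow, fluid = fluid),
    class = "hydraulic_network")
  if (!nodes_connected(net, inlet, outlet)) {
    abort_veinflow("`inlet` and `outlet` are not connected by the channel graph.",
                   class = "veinflow_singular_network_error")
  }
  net
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$channels[, c("node_a", "node_b", "id")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes))
}

nodes_connected <- function(network, a, b) {
  g <- as_igraph(network)
  comp <- igraph::components(g)$membership
  comp[[a]] == comp[[b]]
}

#' @export
print.hydraulic_network <- function(x, ...) {
  cat("<hydraulic_network> ", length(x$nodes), " nodes, ",
      nrow(x$channels), " channels\n", sep = "")
  cat("  inlet: ", x$inlet, "  outlet: ", x$outlet,
      "  inflow: ", format(x$inflow), " m^3/s (",
      format(x$inflow / 1e-15), " pl/s)\n", sep = "")
  print(x$channels, n = 6)
  invisible(x)
}

#' Assemble a hydraulic network from a vein table and a topology table
#'
#' Joins per-vein geometry (lengths and diameters in millimetres, as
#' printed in morphometric tables) with a channel topology (which nodes
#' each vein connects) and converts to SI.
#'
#' @param veins A data frame with columns `vein_id`, `length_mm`,
#'   `inner_diameter_mm` and optionally `outer_diameter_mm`.
#' @param topology A data frame with columns `channel_id`, `node_a`,
#'   `node_b`; every `channel_id` must match a `vein_id`.
#' @param inlet,outlet,inflow,fluid Passed to [hydraulic_network()].
#'
#' @return A `hydraulic_network`.
#' @export
build_network <- function(veins, topology, inlet, outlet, inflow,
                          fluid = fluid_properties()) {
  veins <- tibble::as_tibble(veins)
  topology <- tibble::as_tibble(topology)
  need_v <- c("vein_id", "length_mm", "inner_diameter_mm")
  need_t <- c("channel_id", "node_a", "node_b")
  if (!all(need_v %in% names(veins))) {
    abort_veinflow(paste0("`veins` needs columns: ", paste(need_v, collapse = ", ")),
                   class = "veinflow_malformed_table_error")
  }
  if (!all(need_t %in% names(topology))) {
    abort_veinflow(paste0("`topology` needs columns: ", paste(need_t, collapse = ", ")),
                   class = "veinflow_malformed_table_error")
  }
  unknown <- setdiff(topology$channel_id, veins$vein_id)
  if (length(unknown) > 0) {
    abort_veinflow(paste0("Topology references vein id(s) absent from the table: ",
                          paste(unknown, collapse = ", ")),
                   class = "veinflow_missing_id_error")
  }
  channels <- topology %>%
    dplyr::rename(id = "channel_id") %>%
    dplyr::left_join(veins, by = c(id = "vein_id")) %>%
    dplyr::mutate(
      length = .data$length_mm * 1e-3,
      diameter = .data$inner_diameter_mm * 1e-3,
      outer_diameter = if ("outer_diameter_mm" %in% names(veins))
        .data$outer_diameter_mm * 1e-3 else NA_real_
    ) %>%
    dplyr::select("id", "node_a", "node_b", "length", "diameter",
                  "outer_diameter")
  hydraulic_network(channels, inlet = inlet, outlet = outlet,
                    inflow = inflow, fluid = fluid)
}

#' Remove a channel from a network (virtual ablation)
#'
#' Deletes one named channel, leaving everything else untouched. This is
#' the in-silico analogue of severing a vein: the experiment behind the
#' extra-crossvein analysis, impossible in a living wing.
#'
#' @param network A `hydraulic_network`.
#' @param channel_id Id of the channel to remove.
#'
#' @return The reduced `hydraulic_network`.
#' @export
#'
#' @examples
#' net <- build_cyrtoloma_network()
#' ablate(net, "ECV")
ablate <- function(network, channel_id) {
  stopifnot(inherits(network, "hydraulic_network"))
  if (!channel_id %in% network$channels$id) {
    abort_veinflow(paste0("No channel named '", channel_id, "' in the network."),
                   class = "veinflow_missing_id_error")
  }
  channels <- network$channels[network$channels$id != channel_id, ]
  hydraulic_network(channels, inlet = network$inlet, outlet = network$outlet,
                    inflow = network$inflow, fluid = network$fluid)
}
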