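cyrtoloma_vein_ids <- c(
  paste0("V_E_", 1:7), paste0("V_B_", 1:7), paste0("V_C_", 1:3),
  "V_C_4_E", "V_C_4_B", "V_C_5_E", "V_C_5_B", "V_C_6_E", "V_C_6_B",
  "ECV", "PCV")

#' Measured wing vein geometry of *Drosophila cyrtoloma*
#'
#' The 25-vein morphometric table of the Hawaiian fly forewing: per-vein
#' length, outer diameter and inner (lumen) diameter in millimetres. Seven
#' edge veins (`V_E_1..7`) run along the wing margin, seven base veins
#' (`V_B_1..7`) along the wing base, six connecting veins bridge the two
#' rails (the fourth to sixth split into edge- and base-side segments by
#' the crossvein junctions), and two crossveins -- the extra crossvein
#' (`ECV`) peculiar to the Hawaiian planitibia group and the posterior
#' crossvein (`PCV`) shared by all fruit flies -- join the connecting
#' veins, meeting at a cruciform node. Lumen diameters are 20% of the
#' measured outer diameters, reflecting the vein cross-section of
#' drosophilid wings.
#'
#' @return A tibble with columns `vein_id`, `length_mm`,
#'   `outer_diameter_mm`, `inner_diameter_mm`.
#' @export
#'
#' @examples
#' cyrtoloma_veins()
cyrtoloma_veins <- function() {
  read_vein_table(system.file("extdata", "cyrtoloma_veins.tsv",
                              package = "veinflow", mustWork = TRUE))
}

#' Channel topology of the *D. cyrtoloma* vein network
#'
#' The ladder graph of the wing: the edge and base rails share an anterior
#' terminal (`IN`, the hemolymph inlet at the wing base) and a posterior
#' terminal (`OUT`, the outlet), rungs `V_C_1..3` join the rails directly,
#' and the fourth to sixth rungs pass through the crossvein junction nodes
#' `A` (ECV anterior connection), `X` (the cruciform node where ECV, PCV
#' and the fifth connecting vein meet) and `Y` (PCV posterior connection).
#'
#' @return A tibble with columns `channel_id`, `node_a`, `node_b`.
#' @export
cyrtoloma_topology <- function() {
  read_topology(system.file("extdata", "cyrtoloma_topology.tsv",
                            package = "veinflow", mustWork = TRUE))
}

#' Build the *D. cyrtoloma* wing vein network
#'
#' Assembles the measured vein table and ladder topology into a
#' [hydraulic_network()] with the hemolymph inlet and outlet at the
#' anterior and posterior wing base and the boundary inflow fixed.
#'
#' @param veins Vein geometry table, by default [cyrtoloma_veins()]. Must
#'   contain exactly the 25 canonical vein ids.
#' @param topology Channel topology, by default [cyrtoloma_topology()].
#' @param fluid Hemolymph [fluid_properties()].
#' @param inflow Boundary inflow in m^3/s; the default 1.2e-14 is the
#'   12 pl/s wing-scale rate (the common fruit fly's assumed rate scaled
#'   isometrically by k^3).
#'
#' @return A `hydraulic_network` with 17 nodes and 25 channels.
#' @export
#'
#' @examples
#' net <- build_cyrtoloma_network()
#' sol <- solve_nodal(net)
#' glance(sol)$total_loss_kpa
build_cyrtoloma_network <- function(veins = cyrtoloma_veins(),
                                    topology = cyrtoloma_topology(),
                                    fluid = fluid_properties(),
                                    inflow = 12e-15) {
  veins <- tibble::as_tibble(veins)
  missing <- setdiff(topology$channel_id, veins$vein_id)
  if (length(missing) > 0) {
    abort_veinflow(paste0("Vein table is missing id(s): ",
                          paste(missing, collapse = ", ")),
                   class = "veinflow_missing_id_error")
  }
  if (anyDuplicated(veins$vein_id)) {
    abort_veinflow("Vein table has duplicated ids.",
                   class = "veinflow_malformed_table_error")
  }
  build_network(veins, topology, inlet = "IN", outlet = "OUT",
                inflow = inflow, fluid = fluid)
}

#' Classify per-channel flow changes between two solutions
#'
#' Compares channel flow magnitudes between a solution of interest (e.g.
#' with the extra crossvein present) and a reference (e.g. with it
#' ablated). For each channel shared by both networks, the change rate
#' `(|q| - |q_ref|) / |q_ref|` is computed and the channel is categorized
#' as `"no_flow"` (magnitude below `threshold * Q_in`), `"increase"` or
#' `"decrease"`; a channel whose signed flow direction flips between the
#' two solutions (both magnitudes above threshold) is additionally flagged
#' `reversed`.
#'
#' @param solution A `flow_solution`, the state of interest.
#' @param reference A `flow_solution` on a congruent channel set (channels
#'   present only in `solution`, such as an inserted crossvein, are
#'   excluded from the rates).
#' @param threshold Zero-flow threshold as a fraction of the boundary
#'   inflow; default 0.001 (0.1% of Q_in).
#'
#' @return A tibble of class `flow_change_map` with columns `id`,
#'   `flow`, `flow_ref`, `change_rate`, `category`, `reversed`.
#' @export
#'
#' @examples
#' net <- build_cyrtoloma_network()
#' cmp <- compare_flows(solve_nodal(net), solve_nodal(ablate(net, "ECV")))
#' cmp[cmp$id == "V_C_5_B", ]
compare_flows <- function(solution, reference, threshold = 0.001) {
  stopifnot(inherits(solution, "flow_solution"),
            inherits(reference, "flow_solution"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    abort_veinflow("`threshold` must be a single non-negative fraction.",
                   class = "veinflow_malformed_table_error")
  }
  only_ref <- setdiff(reference$channels$id, solution$channels$id)
  if (length(only_ref) > 0) {
    abort_veinflow(paste0("Reference has channel(s) absent from `solution`: ",
                          paste(only_ref, collapse = ", ")),
                   class = "veinflow_missing_id_error")
  }
  qin <- solution$inflow
  out <- solution$channels %>%
    dplyr::select("id", flow = "flow") %>%
    dplyr::inner_join(
      reference$channels %>% dplyr::select("id", flow_ref = "flow"),
      by = "id") %>%
    dplyr::mutate(
      change_rate = (abs(.data$flow) - abs(.data$flow_ref)) / abs(.data$flow_ref),
      category = dplyr::case_when(
        abs(.data$flow) < threshold * qin ~ "no_flow",
        abs(.data$flow) > abs(.data$flow_ref) ~ "increase",
        abs(.data$flow) < abs(.data$flow_ref) ~ "decrease",
        TRUE ~ "unchanged"
      ),
      reversed = sign(.data$flow) != sign(.data$flow_ref) &
        abs(.data$flow) >= threshold * qin &
        abs(.data$flow_ref) >= threshold * qin
    )
  attr(out, "threshold") <- threshold
  class(out) <- c("flow_change_map", class(out))
  out
}

#' @rdname compare_flows
#' @param object A `flow_change_map`.
#' @param ... Unused.
#' @method autoplot flow_change_map
#' @export
autoplot.flow_change_map <- function(object, ...) {
  dat <- dplyr::mutate(
    tibble::as_tibble(object),
    id = factor(.data$id, levels = .data$id),
    rate = ifelse(.data$category == "no_flow", NA_real_, .data$change_rate))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$id, y = .data$rate,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = dat[dat$reversed, ],
                        ggplot2::aes(y = 0), shape = 17, colour = "red",
                        size = 2, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression((q - q[ref]) / q[ref]),
                  title = "Flow change relative to reference",
                  subtitle = "red triangles: direction reversed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Percent reduction in total pressure loss
#'
#' `100 * (loss_without - loss_with) / loss_without`: how much a topology
#' change (typically adding a crossvein) lowers the inlet-to-outlet
#' frictional loss at fixed boundary inflow.
#'
#' @param loss_without Baseline total loss (Pa), must be positive.
#' @param loss_with Total loss of the modified network (Pa).
#'
#' @return The reduction in percent (positive when the change helps).
#' @export
#'
#' @examples
#' reduction_percent(100, 96.9)
reduction_percent <- function(loss_without, loss_with) {
  if (!is.numeric(loss_without) || any(loss_without <= 0)) {
    abort_veinflow("`loss_without` must be positive.",
                   class = "veinflow_invalid_geometry_error")
  }
  100 * (loss_without - loss_with) / loss_without
}

#' Run the extra-crossvein ablation experiment
#'
#' Solves a network twice -- with a named crossvein present and with it
#' virtually removed -- and summarises the hemodynamic effect of its
#' presence: total losses, the percent loss reduction, the crossvein's own
#' flow share, and the flow-change classification of every other channel.
#'
#' @param network A `hydraulic_network` containing `channel_id`.
#' @param channel_id The channel to ablate (default `"ECV"`).
#' @param threshold Zero-flow threshold passed to [compare_flows()].
#' @param solver Either [solve_nodal] (default) or [solve_mesh].
#'
#' @return A list with elements `with` and `without` (`flow_solution`s),
#'   `changes` (a `flow_change_map`), and `summary` (one-row tibble:
#'   `loss_with_pa`, `loss_without_pa`, `reduction_percent`,
#'   `ablated_flow_fraction`).
#' @export
#'
#' @examples
#' exp <- ablation_experiment(build_cyrtoloma_network())
#' exp$summary
ablation_experiment <- function(network, channel_id = "ECV",
                                threshold = 0.001, solver = solve_nodal) {
  with_sol <- solver(network)
  without_sol <- solver(ablate(network, channel_id))
  changes <- compare_flows(with_sol, without_sol, threshold = threshold)
  summary <- tibble::tibble(
    loss_with_pa = with_sol$total_loss,
    loss_without_pa = without_sol$total_loss,
    reduction_percent = reduction_percent(without_sol$total_loss,
                                          with_sol$total_loss),
    ablated_flow_fraction =
      with_sol$channels$flow_fraction[with_sol$channels$id == channel_id]
  )
  list(with = with_sol, without = without_sol, changes = changes,
       summary = summary)
}
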