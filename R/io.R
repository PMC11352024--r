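#' Read and write vein geometry tables and channel topologies
#'
#' Vein tables are tab-delimited text with columns `vein_id`, `length_mm`,
#' `outer_diameter_mm` (optional), `inner_diameter_mm`; topologies carry
#' `channel_id`, `node_a`, `node_b`. All geometry is in millimetres, as
#' printed in morphometric tables. Reading validates the layout and warns
#' (class `veinflow_diameter_rule_warning`) when an inner diameter
#' deviates from the 20%-of-outer-diameter convention by more than the
#' rounding of two-significant-figure inputs can explain.
#'
#' @param path File path.
#'
#' @return `read_vein_table()` and `read_topology()` return tibbles;
#'   the writers return `path` invisibly.
#' @export
#'
#' @examples
#' tab <- read_vein_table(system.file("extdata", "cyrtoloma_veins.tsv",
#'                                    package = "veinflow"))
#' nrow(tab)
read_vein_table <- function(path) {
  if (!file.exists(path)) {
    abort_veinflow(paste0("No such file: ", path),
                   class = "veinflow_io_error")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("vein_id", "length_mm", "inner_diameter_mm")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort_veinflow(paste0("Vein table lacks column(s): ",
                          paste(missing, collapse = ", ")),
                   class = "veinflow_malformed_table_error")
  }
  num_cols <- intersect(c("length_mm", "inner_diameter_mm",
                          "outer_diameter_mm"), names(tab))
  for (cl in num_cols) {
    if (!is.numeric(tab[[cl]])) {
      abort_veinflow(paste0("Column `", cl, "` contains non-numeric values."),
                     class = "veinflow_malformed_table_error")
    }
  }
  if (anyDuplicated(tab$vein_id)) {
    abort_veinflow("Duplicated vein_id values.",
                   class = "veinflow_malformed_table_error")
  }
  if (any(tab$length_mm < 0, na.rm = TRUE) ||
      any(tab$inner_diameter_mm <= 0, na.rm = TRUE)) {
    abort_veinflow("Lengths must be >= 0 and inner diameters > 0.",
                   class = "veinflow_invalid_geometry_error")
  }
  if ("outer_diameter_mm" %in% names(tab)) {
    dev <- abs(tab$inner_diameter_mm - 0.2 * tab$outer_diameter_mm) /
      (0.2 * tab$outer_diameter_mm)
    off <- which(dev > 0.05)
    if (length(off) > 0) {
      rlang::warn(
        paste0("Inner diameter deviates from 20% of outer beyond rounding for: ",
               paste(tab$vein_id[off], collapse = ", ")),
        class = "veinflow_diameter_rule_warning")
    }
  }
  tab
}

#' @rdname read_vein_table
#' @param veins A vein table (see above).
#' @export
write_vein_table <- function(veins, path) {
  readr::write_tsv(tibble::as_tibble(veins), path)
  invisible(path)
}

#' @rdname read_vein_table
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) {
    abort_veinflow(paste0("No such file: ", path),
                   class = "veinflow_io_error")
  }
  topo <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  need <- c("channel_id", "node_a", "node_b")
  if (!all(need %in% names(topo))) {
    abort_veinflow(paste0("Topology lacks column(s): ",
                          paste(setdiff(need, names(topo)), collapse = ", ")),
                   class = "veinflow_malformed_table_error")
  }
  if (anyDuplicated(topo$channel_id)) {
    abort_veinflow("Duplicated channel_id values.",
                   class = "veinflow_malformed_table_error")
  }
  topo
}

#' @rdname read_vein_table
#' @param topology A topology table (see above).
#' @export
write_topology <- function(topology, path) {
  readr::write_tsv(tibble::as_tibble(topology), path)
  invisible(path)
}

#' Write a sweep surface as long-format delimited text
#'
#' @param surface A `sweep_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_surface <- function(surface, path) {
  readr::write_tsv(tidy(surface), path)
  invisible(path)
}

default_run_config <- function() {
  list(
    experiment = "ablate",
    viscosity = 1.3e-3,
    density = 1.02e3,
    inflow_pl_s = 12,
    table = NULL,
    topology = NULL,
    threshold = 0.001,
    variant = "uniform",
    grid_step = 0.05,
    n_rungs = 6,
    seed = 1,
    out_dir = "veinflow-run"
  )
}

resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort_veinflow("`config` must be a list or the path to a YAML file.",
                   class = "veinflow_io_error")
  }
  cfg <- utils::modifyList(default_run_config(), config)
  ok <- c("solve", "ablate", "reposition_sweep", "idealized", "mass", "synth")
  if (!cfg$experiment %in% ok) {
    abort_veinflow(paste0("Unknown experiment '", cfg$experiment,
                          "'; choose one of: ", paste(ok, collapse = ", ")),
                   class = "veinflow_io_error")
  }
  cfg
}

summary_kv <- function(...) {
  vals <- c(...)
  tibble::tibble(key = names(vals), value = unname(vals))
}

#' Run a configured experiment and write its report files
#'
#' The file-level driver behind the package's analyses. A configuration
#' (a list, or the path to a YAML file with the same fields) selects one
#' experiment and its parameters; results are written as tab-delimited
#' text under `out_dir`, together with a log of every resolved parameter.
#' Numeric files carry full double precision; the log presents headline
#' values at two significant figures. Reruns with the same configuration
#' produce identical outputs.
#'
#' Config fields (all optional except `out_dir` is recommended):
#' `experiment` (`"solve"`, `"ablate"`, `"reposition_sweep"`,
#' `"idealized"`, `"mass"`, `"synth"`), `viscosity`, `density`,
#' `inflow_pl_s`, `table`/`topology` (paths; `NULL` uses the packaged
#' wing model), `threshold`, `variant`, `grid_step`, `n_rungs`, `seed`,
#' `out_dir`.
#'
#' @param config A list or YAML file path.
#'
#' @return Invisibly, a named character vector of the files written.
#' @export
#'
#' @examples
#' out <- run_experiment(list(experiment = "solve", out_dir = tempfile()))
#' readr::read_tsv(out[["summary"]], show_col_types = FALSE)
run_experiment <- function(config = list()) {
  cfg <- resolve_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fluid <- fluid_properties(cfg$viscosity, cfg$density)
  inflow <- cfg$inflow_pl_s * 1e-15
  paths <- c()
  emit <- function(name, fname, writer) {
    p <- file.path(cfg$out_dir, fname)
    writer(p)
    paths[[name]] <<- p
  }
  load_net <- function() {
    veins <- if (is.null(cfg$table)) cyrtoloma_veins() else
      read_vein_table(cfg$table)
    topo <- if (is.null(cfg$topology)) cyrtoloma_topology() else
      read_topology(cfg$topology)
    build_network(veins, topo, inlet = "IN", outlet = "OUT",
                  inflow = inflow, fluid = fluid)
  }

  log_lines <- c(
    "veinflow run log",
    paste0("experiment: ", cfg$experiment),
    paste0("viscosity: ", cfg$viscosity, " Pa s; density: ", cfg$density,
           " kg/m^3"),
    paste0("inflow: ", cfg$inflow_pl_s, " pl/s"),
    paste0("table: ", if (is.null(cfg$table)) "<packaged>" else cfg$table),
    paste0("topology: ",
           if (is.null(cfg$topology)) "<packaged>" else cfg$topology),
    paste0("threshold: ", cfg$threshold, "; variant: ", cfg$variant,
           "; grid_step: ", cfg$grid_step, "; n_rungs: ", cfg$n_rungs,
           "; seed: ", cfg$seed))

  if (cfg$experiment == "solve") {
    sol <- solve_nodal(load_net())
    emit("flows", "flows.tsv", function(p) readr::write_tsv(tidy(sol), p))
    emit("summary", "summary.tsv", function(p) readr::write_tsv(summary_kv(
      total_loss_pa = sol$total_loss,
      total_loss_kpa = sol$total_loss / 1e3,
      inflow_pl_s = cfg$inflow_pl_s), p))
    log_lines <- c(log_lines, paste0(
      "total loss: ", signif(sol$total_loss / 1e3, 2), " kPa"))
  } else if (cfg$experiment == "ablate") {
    exp <- ablation_experiment(load_net(), threshold = cfg$threshold)
    emit("flows_with", "flows_with.tsv",
         function(p) readr::write_tsv(tidy(exp$with), p))
    emit("flows_without", "flows_without.tsv",
         function(p) readr::write_tsv(tidy(exp$without), p))
    emit("changes", "changes.tsv",
         function(p) readr::write_tsv(tibble::as_tibble(exp$changes), p))
    pcv_with <- exp$with$channels$flow_fraction[exp$with$channels$id == "PCV"]
    emit("summary", "summary.tsv", function(p) readr::write_tsv(summary_kv(
      loss_with_kpa = exp$summary$loss_with_pa / 1e3,
      loss_without_kpa = exp$summary$loss_without_pa / 1e3,
      reduction_percent = exp$summary$reduction_percent,
      ecv_flow_fraction = exp$summary$ablated_flow_fraction,
      ecv_flow_pl_s = exp$summary$ablated_flow_fraction * cfg$inflow_pl_s,
      pcv_flow_fraction = if (length(pcv_with)) pcv_with else NA_real_), p))
    log_lines <- c(log_lines, paste0(
      "loss with/without: ", signif(exp$summary$loss_with_pa / 1e3, 2), " / ",
      signif(exp$summary$loss_without_pa / 1e3, 2), " kPa; reduction ",
      signif(exp$summary$reduction_percent, 2), "%"))
  } else if (cfg$experiment == "reposition_sweep") {
    geom <- reposition_geometry()
    grid <- seq(cfg$grid_step, 1 - cfg$grid_step, by = cfg$grid_step)
    surf <- sweep_positions(load_net(), geom, a_grid = grid,
                            p_grid = sort(unique(c(grid, geom$x_pcv))))
    emit("surface", "surface.tsv", function(p) write_sweep_surface(surf, p))
    emit("summary", "summary.tsv", function(p) readr::write_tsv(summary_kv(
      min_norm_loss = attr(surf, "argmin")$norm_loss,
      min_a = attr(surf, "argmin")$a,
      min_p = attr(surf, "argmin")$p,
      reference_loss_kpa = attr(surf, "reference_loss") / 1e3), p))
    log_lines <- c(log_lines, paste0(
      "surface minimum ", signif(attr(surf, "argmin")$norm_loss, 2),
      " at (a, p) = (", attr(surf, "argmin")$a, ", ",
      attr(surf, "argmin")$p, ")"))
  } else if (cfg$experiment == "idealized") {
    spec <- idealized_spec(cfg$variant, fluid = fluid, inflow = inflow)
    exp <- ablation_experiment(build_idealized(spec),
                               threshold = cfg$threshold)
    pcv_with <- exp$with$channels$flow_fraction[exp$with$channels$id == "PCV"]
    pcv_without <-
      exp$without$channels$flow_fraction[exp$without$channels$id == "PCV"]
    emit("flows_with", "flows_with.tsv",
         function(p) readr::write_tsv(tidy(exp$with), p))
    emit("flows_without", "flows_without.tsv",
         function(p) readr::write_tsv(tidy(exp$without), p))
    emit("changes", "changes.tsv",
         function(p) readr::write_tsv(tibble::as_tibble(exp$changes), p))
    emit("summary", "summary.tsv", function(p) readr::write_tsv(summary_kv(
      pcv_share_without_ecv = pcv_without,
      ecv_share = exp$summary$ablated_flow_fraction,
      pcv_share_with_ecv = pcv_with,
      reduction_percent = exp$summary$reduction_percent), p))
    log_lines <- c(log_lines, paste0(
      "variant ", cfg$variant, ": PCV share without ",
      signif(pcv_without, 2), ", ECV share ",
      signif(exp$summary$ablated_flow_fraction, 2), ", reduction ",
      signif(exp$summary$reduction_percent, 2), "%"))
  } else if (cfg$experiment == "mass") {
    rep <- allometry_report(inflow_pl_s = cfg$inflow_pl_s)
    emit("summary", "summary.tsv", function(p) readr::write_tsv(
      tidyr::pivot_longer(rep, dplyr::everything(),
                          names_to = "key", values_to = "value"), p))
    log_lines <- c(log_lines, paste0(
      "k = ", signif(rep$k, 2), "; wing ", signif(rep$wing_mass_ug, 2),
      " ug; crossvein ", signif(rep$ecv_mass_ug, 2), " ug (+",
      signif(rep$mass_increase_percent, 2), "%)"))
  } else if (cfg$experiment == "synth") {
    lad <- random_ladder(ladder_spec(n_rungs = cfg$n_rungs, seed = cfg$seed))
    net <- build_network(lad$veins, lad$topology, "IN", "OUT",
                         inflow = inflow, fluid = fluid)
    sol <- solve_nodal(net)
    emit("veins", "veins.tsv", function(p) write_vein_table(lad$veins, p))
    emit("topology", "topology.tsv",
         function(p) write_topology(lad$topology, p))
    emit("flows", "flows.tsv", function(p) readr::write_tsv(tidy(sol), p))
    emit("summary", "summary.tsv", function(p) readr::write_tsv(summary_kv(
      total_loss_kpa = sol$total_loss / 1e3,
      n_channels = nrow(tidy(sol))), p))
    log_lines <- c(log_lines, paste0(
      "synthetic ladder, ", cfg$n_rungs, " rungs, total loss ",
      signif(sol$total_loss / 1e3, 2), " kPa"))
  }

  emit("log", "run_log.txt",
       function(p) writeLines(log_lines, p))
  invisible(unlist(paths))
}
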