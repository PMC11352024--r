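#' Simplified planar geometry for crossvein repositioning
#'
#' To move the extra crossvein's connections along the fourth and fifth
#' connecting veins, those veins are modelled as parallel straight
#' segments aligned at their base-side endpoints. Connection positions are
#' expressed as base-side length fractions `a = l_C4B / l_C4` and
#' `p = l_C5B / l_C5`; the posterior crossvein's junction sits at the
#' fixed fraction `x_pcv` of the fifth connecting vein. The rail
#' separation is calibrated so that the straight crossvein connecting the
#' actual positions `(a_actual, p_actual)` has its measured length.
#'
#' The true planar coordinates of the wing are not part of the measured
#' table, so sweep surface *values* carry geometry-model uncertainty; the
#' location of the loss minimum does not (it is set by the transfer-path
#' length between the two crossveins vanishing).
#'
#' @param l_c4,l_c5 Full lengths of the fourth and fifth connecting veins
#'   in mm (defaults: sums of the measured edge- and base-side segments).
#' @param x_pcv Fixed PCV junction fraction along the fifth connecting
#'   vein, in (0, 1).
#' @param a_actual,p_actual The crossvein's actual connection fractions.
#' @param ecv_length_actual Measured crossvein length in mm, used to
#'   calibrate the rail separation.
#'
#' @return A `reposition_geometry` object.
#' @export
#'
#' @examples
#' reposition_geometry()
reposition_geometry <- function(l_c4 = 4.7, l_c5 = 4.6, x_pcv = 0.506,
                                a_actual = 0.486, p_actual = 0.506,
                                ecv_length_actual = 0.62) {
  stopifnot(l_c4 > 0, l_c5 > 0, x_pcv > 0, x_pcv < 1,
            a_actual > 0, a_actual < 1, p_actual > 0, p_actual < 1)
  axial_offset <- a_actual * l_c4 - p_actual * l_c5
  sep_sq <- ecv_length_actual^2 - axial_offset^2
  if (sep_sq <= 0) {
    abort_veinflow(
      "Actual crossvein length is shorter than the axial offset between its connections; geometry is inconsistent.",
      class = "veinflow_invalid_geometry_error")
  }
  structure(
    list(l_c4 = l_c4, l_c5 = l_c5, x_pcv = x_pcv,
         a_actual = a_actual, p_actual = p_actual,
         separation = sqrt(sep_sq)),
    class = "reposition_geometry")
}

#' @export
print.reposition_geometry <- function(x, ...) {
  cat("<reposition_geometry>\n")
  cat("  l_C4 = ", x$l_c4, " mm, l_C5 = ", x$l_c5, " mm, separation = ",
      signif(x$separation, 4), " mm\n", sep = "")
  cat("  PCV junction at fraction ", x$x_pcv,
      "; actual position (a, p) = (", x$a_actual, ", ", x$p_actual, ")\n",
      sep = "")
  invisible(x)
}

ecv_length_mm <- function(geom, a, p) {
  sqrt(geom$separation^2 + (a * geom$l_c4 - p * geom$l_c5)^2)
}

reposition_channel_table <- function(base, geom, a, p, ecv_length = NULL) {
  ch <- base$channels
  need <- c("V_C_4_E", "V_C_4_B", "V_C_5_E", "V_C_5_B", "ECV")
  if (!all(need %in% ch$id)) {
    abort_veinflow("Base network lacks the crossvein-adjacent channels.",
                   class = "veinflow_missing_id_error")
  }
  d <- function(id) ch$diameter[ch$id == id]
  outer <- function(id) ch$outer_diameter[ch$id == id]
  if (is.null(ecv_length)) ecv_length <- ecv_length_mm(geom, a, p)

  fixed <- ch[!ch$id %in% need, c("id", "node_a", "node_b", "length",
                                  "diameter", "outer_diameter")]
  seg <- function(id, na, nb, len_mm, diam, out_d) {
    tibble::tibble(id = id, node_a = na, node_b = nb, length = len_mm * 1e-3,
                   diameter = diam, outer_diameter = out_d)
  }
  mm <- 1
  var_rows <- dplyr::bind_rows(
    seg("V_C_4_E", "E4", "A", (1 - a) * geom$l_c4, d("V_C_4_E"), outer("V_C_4_E")),
    seg("V_C_4_B", "A", "B4", a * geom$l_c4, d("V_C_4_B"), outer("V_C_4_B"))
  )
  if (isTRUE(all.equal(p, geom$x_pcv, tolerance = 1e-9))) {
    var_rows <- dplyr::bind_rows(
      var_rows,
      seg("V_C_5_E", "E5", "X", (1 - geom$x_pcv) * geom$l_c5,
          d("V_C_5_E"), outer("V_C_5_E")),
      seg("V_C_5_B", "X", "B5", geom$x_pcv * geom$l_c5,
          d("V_C_5_B"), outer("V_C_5_B")),
      seg("ECV", "A", "X", ecv_length, d("ECV"), outer("ECV"))
    )
  } else if (p < geom$x_pcv) {
    # P lies base-side of the PCV junction: transfer segment X-P belongs to
    # the edge side of P and keeps the edge-side diameter
    var_rows <- dplyr::bind_rows(
      var_rows,
      seg("V_C_5_E", "E5", "X", (1 - geom$x_pcv) * geom$l_c5,
          d("V_C_5_E"), outer("V_C_5_E")),
      seg("V_C_5_T", "X", "P", (geom$x_pcv - p) * geom$l_c5,
          d("V_C_5_E"), outer("V_C_5_E")),
      seg("V_C_5_B", "P", "B5", p * geom$l_c5,
          d("V_C_5_B"), outer("V_C_5_B")),
      seg("ECV", "A", "P", ecv_length, d("ECV"), outer("ECV"))
    )
  } else {
    var_rows <- dplyr::bind_rows(
      var_rows,
      seg("V_C_5_E", "E5", "P", (1 - p) * geom$l_c5,
          d("V_C_5_E"), outer("V_C_5_E")),
      seg("V_C_5_T", "P", "X", (p - geom$x_pcv) * geom$l_c5,
          d("V_C_5_B"), outer("V_C_5_B")),
      seg("V_C_5_B", "X", "B5", geom$x_pcv * geom$l_c5,
          d("V_C_5_B"), outer("V_C_5_B")),
      seg("ECV", "A", "P", ecv_length, d("ECV"), outer("ECV"))
    )
  }
  dplyr::bind_rows(fixed, var_rows)
}

#' Move the extra crossvein's connections in the simplified geometry
#'
#' Splits the fourth connecting vein at the anterior connection `a` and
#' the fifth at both the posterior connection `p` and the fixed PCV
#' junction `x_pcv`, keeping each sub-segment's parent diameter, and
#' re-derives the crossvein length as the straight-line distance between
#' the two connections. All hydraulic resistances are recomputed from the
#' new lengths at fixed diameters. When `p` differs from `x_pcv`, a
#' transfer segment (`V_C_5_T`) carries the bypass flow between the two
#' crossveins and adds a pressure loss proportional to its length.
#'
#' @param base The crossvein-bearing network, by default the
#'   *D. cyrtoloma* model, containing channels `V_C_4_E`, `V_C_4_B`,
#'   `V_C_5_E`, `V_C_5_B` and `ECV`.
#' @param geom A [reposition_geometry()].
#' @param a,p Connection fractions in (0, 1).
#' @param ecv_length Optional crossvein length override in mm (used to
#'   isolate the transfer-length effect from the crossvein's own length
#'   change); default derives it from the geometry.
#'
#' @return A `hydraulic_network` with the repositioned crossvein.
#' @export
#'
#' @examples
#' net <- reposition_network(a = 0.3, p = 0.7)
#' glance(solve_nodal(net))
reposition_network <- function(base = build_cyrtoloma_network(),
                               geom = reposition_geometry(),
                               a, p, ecv_length = NULL) {
  stopifnot(inherits(base, "hydraulic_network"),
            inherits(geom, "reposition_geometry"))
  if (!is.numeric(a) || !is.numeric(p) || length(a) != 1L || length(p) != 1L ||
      a <= 0 || a >= 1 || p <= 0 || p >= 1) {
    abort_veinflow("`a` and `p` must be single fractions in (0, 1).",
                   class = "veinflow_invalid_geometry_error")
  }
  channels <- reposition_channel_table(base, geom, a, p, ecv_length)
  hydraulic_network(channels, inlet = base$inlet, outlet = base$outlet,
                    inflow = base$inflow, fluid = base$fluid)
}

new_sweep_surface <- function(df, axes, reference_loss, geom = NULL) {
  df <- tibble::as_tibble(df)
  i_min <- which.min(df$norm_loss)
  i_max <- which.max(df$norm_loss)
  structure(df,
            axes = axes,
            reference_loss = reference_loss,
            argmin = df[i_min, ],
            argmax = df[i_max, ],
            geometry = geom,
            class = c("sweep_surface", class(tibble::tibble())))
}

#' Sweep the crossvein connection positions and map the total loss
#'
#' Solves the repositioned network over a grid of anterior (`a`) and
#' posterior (`p`) connection fractions and normalizes each total
#' pressure loss by the loss of the crossvein-ablated network, the
#' figure of merit for the crossvein's benefit at each position.
#'
#' @inheritParams reposition_network
#' @param a_grid,p_grid Numeric vectors of fractions in (0, 1). To probe
#'   the loss minimum exactly, include `geom$x_pcv` in `p_grid`.
#'
#' @return A `sweep_surface` tibble with columns `a`, `p`, `total_loss`
#'   (Pa) and `norm_loss` (loss over the crossvein-free loss). The
#'   attributes `argmin`/`argmax` locate the extremes;
#'   [glance()][generics::glance] reports them.
#' @export
#'
#' @examples
#' surf <- sweep_positions(a_grid = c(0.3, 0.486, 0.7),
#'                         p_grid = c(0.3, 0.506, 0.7))
#' glance(surf)
sweep_positions <- function(base = build_cyrtoloma_network(),
                            geom = reposition_geometry(),
                            a_grid = seq(0.05, 0.95, by = 0.05),
                            p_grid = sort(c(seq(0.05, 0.95, by = 0.05),
                                            geom$x_pcv))) {
  stopifnot(all(a_grid > 0 & a_grid < 1), all(p_grid > 0 & p_grid < 1))
  reference <- solve_nodal(ablate(base, "ECV"))$total_loss

  # lean per-cell solve: fixed channels preassembled, node indices reused
  ch <- base$channels
  need <- c("V_C_4_E", "V_C_4_B", "V_C_5_E", "V_C_5_B", "ECV")
  fixed <- ch[!ch$id %in% need, ]
  nodes <- c(base$nodes, "P")
  ni <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  fa <- unname(ni[fixed$node_a]); fb <- unname(ni[fixed$node_b])
  fr <- fixed$resistance
  kr <- 128 * base$fluid$viscosity / pi
  d4 <- function(id) ch$diameter[ch$id == id]^4
  d4_c4e <- d4("V_C_4_E"); d4_c4b <- d4("V_C_4_B")
  d4_c5e <- d4("V_C_5_E"); d4_c5b <- d4("V_C_5_B"); d4_ecv <- d4("ECV")
  inlet_i <- ni[[base$inlet]]; outlet_i <- ni[[base$outlet]]
  iA <- ni[["A"]]; iX <- ni[["X"]]; iP <- ni[["P"]]
  iE4 <- ni[["E4"]]; iB4 <- ni[["B4"]]; iE5 <- ni[["E5"]]; iB5 <- ni[["B5"]]
  xq <- geom$x_pcv

  cell_loss <- function(a, p) {
    r_c4e <- kr * (1 - a) * geom$l_c4 * 1e-3 / d4_c4e
    r_c4b <- kr * a * geom$l_c4 * 1e-3 / d4_c4b
    r_ecv <- kr * ecv_length_mm(geom, a, p) * 1e-3 / d4_ecv
    if (abs(p - xq) < 1e-12) {
      ea <- c(fa, iE4, iA, iE5, iX, iA)
      eb <- c(fb, iA, iB4, iX, iB5, iX)
      rr <- c(fr, r_c4e, r_c4b,
              kr * (1 - xq) * geom$l_c5 * 1e-3 / d4_c5e,
              kr * xq * geom$l_c5 * 1e-3 / d4_c5b,
              r_ecv)
      nn <- n - 1L  # node P unused; drop it from the system
      keep_nodes <- seq_len(n) != iP
      p_sol <- tryCatch(
        conductance_pressures(ea, eb, rr, nn, inlet_i, outlet_i, base$inflow),
        error = function(e) rep(NA_real_, nn))
      return(p_sol[inlet_i])
    }
    if (p < xq) {
      ea <- c(fa, iE4, iA, iE5, iX, iP, iA)
      eb <- c(fb, iA, iB4, iX, iP, iB5, iP)
      rr <- c(fr, r_c4e, r_c4b,
              kr * (1 - xq) * geom$l_c5 * 1e-3 / d4_c5e,
              kr * (xq - p) * geom$l_c5 * 1e-3 / d4_c5e,
              kr * p * geom$l_c5 * 1e-3 / d4_c5b,
              r_ecv)
    } else {
      ea <- c(fa, iE4, iA, iE5, iP, iX, iA)
      eb <- c(fb, iA, iB4, iP, iX, iB5, iP)
      rr <- c(fr, r_c4e, r_c4b,
              kr * (1 - p) * geom$l_c5 * 1e-3 / d4_c5e,
              kr * (p - xq) * geom$l_c5 * 1e-3 / d4_c5b,
              kr * xq * geom$l_c5 * 1e-3 / d4_c5b,
              r_ecv)
    }
    p_sol <- tryCatch(
      conductance_pressures(ea, eb, rr, n, inlet_i, outlet_i, base$inflow),
      error = function(e) rep(NA_real_, n))
    p_sol[inlet_i]
  }

  grid <- tidyr::expand_grid(a = a_grid, p = p_grid)
  grid$total_loss <- purrr::map2_dbl(grid$a, grid$p, cell_loss)
  grid$norm_loss <- grid$total_loss / reference
  new_sweep_surface(grid, axes = c("p", "a"), reference_loss = reference,
                    geom = geom)
}

#' @rdname sweep_positions
#' @param x,object A `sweep_surface`.
#' @param ... Unused.
#' @method tidy sweep_surface
#' @export
tidy.sweep_surface <- function(x, ...) {
  tibble::as_tibble(unclass_surface(x))
}

unclass_surface <- function(x) {
  x <- x[seq_len(nrow(x)), , drop = FALSE]
  class(x) <- class(tibble::tibble())
  x
}

#' @rdname sweep_positions
#' @method glance sweep_surface
#' @export
glance.sweep_surface <- function(x, ...) {
  am <- attr(x, "argmin"); ax <- attr(x, "argmax")
  axes <- attr(x, "axes")
  tibble::tibble(
    n_cells = nrow(x),
    reference_loss = attr(x, "reference_loss"),
    min_norm_loss = am$norm_loss,
    max_norm_loss = ax$norm_loss,
    !!paste0("min_", axes[1]) := am[[axes[1]]],
    !!paste0("min_", axes[2]) := am[[axes[2]]],
    !!paste0("max_", axes[1]) := ax[[axes[1]]],
    !!paste0("max_", axes[2]) := ax[[axes[2]]]
  )
}

#' @rdname sweep_positions
#' @method autoplot sweep_surface
#' @export
autoplot.sweep_surface <- function(object, ...) {
  axes <- attr(object, "axes")
  dat <- unclass_surface(object)
  am <- attr(object, "argmin")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[axes[1]]],
                                    y = .data[[axes[2]]],
                                    fill = .data$norm_loss)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = am, shape = 21, fill = "white", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "normalized\nloss") +
    ggplot2::labs(x = axes[1], y = axes[2],
                  title = "Total pressure loss over crossvein positions",
                  subtitle = "white dot: minimum") +
    ggplot2::theme_minimal()
}
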