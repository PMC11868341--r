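#' Plot a single-neuron simulation
#'
#' Stacked panels of the membrane potential, adaptation current and
#' impairment variable over time, with spike times marked on the V panel.
#'
#' @param object An `adex_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adex_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, c("V", "w", "z"),
                              names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = c("V", "w", "z"),
                          labels = c("V (mV)", "w (pA)", "z (mV)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time / 1000, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("Extended AdEx, Z0 = %g mV", object$params$Z0))
  if (length(object$spikes)) {
    ticks <- tibble(time = object$spikes,
                    variable = factor("V (mV)",
                                      levels = levels(long$variable)))
    p <- p + ggplot2::geom_rug(data = ticks,
                               ggplot2::aes(x = .data$time / 1000),
                               inherit.aes = FALSE, sides = "t", length = ggplot2::unit(0.05, "npc"))
  }
  p
}

#' Plot a fast-subsystem bifurcation diagram
#'
#' Equilibrium potential against the frozen impairment value, solid for
#' stable and dashed for unstable equilibria, with the detected
#' Andronov-Hopf and saddle-node events marked.
#'
#' @param object An `adex_bifurcation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adex_bifurcation <- function(object, ...) {
  eq <- object$equilibria %>%
    mutate(stable = .data$stability %in% c("stable_node", "stable_focus"),
           branch = ifelse(.data$stability == "saddle", "saddle", "node/focus"))
  ggplot2::ggplot(eq, ggplot2::aes(x = .data$z, y = .data$V_star,
                                   group = .data$branch,
                                   linetype = .data$stable)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   name = "stable") +
    ggplot2::geom_point(data = object$events,
                        ggplot2::aes(x = .data$z_value, y = .data$V_value),
                        inherit.aes = FALSE, shape = 21, size = 3,
                        fill = "white") +
    ggplot2::geom_text(data = object$events,
                       ggplot2::aes(x = .data$z_value, y = .data$V_value,
                                    label = ifelse(.data$kind == "andronov_hopf",
                                                   "AH", "SN")),
                       inherit.aes = FALSE, vjust = -1, size = 3) +
    ggplot2::labs(x = "z (mV)", y = "V* (mV)",
                  title = "Fast-subsystem equilibria along z")
}

#' Plot a network simulation
#'
#' Raster of spike events (cells reordered by population) above the three
#' smoothed population-rate traces.
#'
#' @param object An `adex_netsim` object.
#' @param max_points Subsample the raster above this many events.
#' @param ... Unused.
#' @return A ggplot object (patchwork-free single plot with facets).
#' @export
autoplot.adex_netsim <- function(object, max_points = 2e5, ...) {
  labels <- object$network$labels
  rates <- purrr::map_dfr(c("RS_impaired", "FS", "RS_healthy"), function(pop) {
    if (!any(labels == pop)) return(NULL)
    dplyr::mutate(population_rate(object, pop), population = pop)
  })
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$time / 1000, y = .data$rate,
                                      colour = .data$population)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "population rate (Hz)",
                  title = sprintf("Network activity (%d cells, %d impaired)",
                                  object$network$N,
                                  length(object$network$impaired)))
}

#' Heatmaps of the (Z0, N_SC) regime map
#'
#' Tile plots of the per-population maximum rates and the region label over
#' the explored parameter plane.
#'
#' @param regime_map The tibble returned by [run_grid()].
#' @param value One of `region`, `max_impaired_hz`, `max_healthy_exc_hz`,
#'   `max_inhibitory_hz`.
#' @return A ggplot object.
#' @export
plot_regime_map <- function(regime_map, value = "region") {
  stopifnot(value %in% c("region", "max_impaired_hz", "max_healthy_exc_hz",
                         "max_inhibitory_hz"))
  df <- regime_map %>%
    group_by(.data$Z0, .data$n_impaired) %>%
    summarise(v = mean(.data[[value]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_impaired),
                                   y = factor(.data$Z0), fill = .data$v)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "number of impaired cells", y = "Z0 (mV)", fill = value)
}
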