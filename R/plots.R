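# ggplot2 views of trajectories, ensembles and experiment results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a single-cell trajectory
#'
#' Facetted time courses of selected components, with the zeitgeber's warm
#' intervals shaded.
#'
#' @param object A `clock_trajectory` from [simulate_cell()].
#' @param components Components to show.
#' @param from Start of the plotted span, h.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clock_trajectory <- function(object,
                                      components = c("TS2", "actHSF1",
                                                     "PerCry_mRNA",
                                                     "Bmal1_mRNA"),
                                      from = 0, ...) {
  long <- tidyr::pivot_longer(object[object$time_h >= from, ],
                              cols = dplyr::all_of(components),
                              names_to = "component")
  long$component <- factor(long$component, levels = components)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line(colour = "#2c4b8e") +
    ggplot2::facet_wrap(~component, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble mean field
#'
#' The ensemble average of one component with the across-cell interquartile
#' band.
#'
#' @param object A `clock_ensemble`.
#' @param component Component to show.
#' @param from Start of the plotted span, h.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clock_ensemble <- function(object, component = "PerCry_mRNA",
                                    from = 0, ...) {
  m <- .ens_component(object, component)
  sel <- object$time_h >= from
  d <- tibble::tibble(
    time_h = object$time_h[sel],
    mean = colMeans(m[, sel, drop = FALSE]),
    q25 = apply(m[, sel, drop = FALSE], 2, stats::quantile, 0.25),
    q75 = apply(m[, sel, drop = FALSE], 2, stats::quantile, 0.75))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "#b2332c") +
    ggplot2::labs(x = "time (h)", y = paste(component, "(nM)"),
                  title = sprintf("ensemble of %d cells", nrow(m))) +
    ggplot2::theme_minimal()
}

#' Plot a shift-schedule adaptation course
#'
#' Per-cycle ensemble phase (top) and 24 h-windowed R_syn (bottom).
#'
#' @param object An `ass_result` from [run_ass()].
#' @param ... Unused.
#' @return A ggplot (patchwork-free two-panel facet).
#' @export
autoplot.ass_result <- function(object, ...) {
  ph <- dplyr::transmute(object$phase_trace, day = .data$day,
                         value = .data$phase_h, panel = "ensemble phase (h)")
  rs <- dplyr::transmute(object$r_syn_trace,
                         day = .data$window_mid_h / 24,
                         value = .data$r_syn, panel = "R_syn (24 h windows)")
  ggplot2::ggplot(dplyr::bind_rows(ph, rs),
                  ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_point(size = 0.6, colour = "#2c4b8e") +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day", y = NULL, title = object$spec) +
    ggplot2::theme_minimal()
}

#' Plot the validation R_syn trace
#'
#' @param object A `validation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validation_result <- function(object, ...) {
  ggplot2::ggplot(object$r_syn_trace,
                  ggplot2::aes(.data$window_mid_h / 24, .data$r_syn,
                               colour = .data$orientation)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = "R_syn") +
    ggplot2::theme_minimal()
}

#' Amplitude-sweep synchronization plot
#'
#' R_syn against zeitgeber amplitude for each component.
#'
#' @param data Tibble from [run_amplitude_sweep()].
#' @return A ggplot.
#' @export
plot_amplitude_sweep <- function(data) {
  d <- data[!data$decoupled, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$amplitude, .data$r_syn,
                                  colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "zeitgeber amplitude (degC)", y = "R_syn") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Arnold-tongue tile plot
#'
#' Entrainment region on the zeitgeber period x amplitude plane.
#'
#' @param data Tibble from [run_arnold_grid()].
#' @return A ggplot.
#' @export
plot_arnold_grid <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$zeitgeber_period,
                                     factor(.data$amplitude),
                                     fill = .data$r_syn)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = data[data$entrained, ], shape = 4) +
    ggplot2::labs(x = "zeitgeber period (h)",
                  y = "amplitude (degC)", fill = "R_syn") +
    ggplot2::theme_minimal()
}
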