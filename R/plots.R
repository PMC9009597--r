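#' Plots of a contraction analysis
#'
#' Four standard views of a fitted recording: the displacement waveform with
#' detected maxima/minima, the per-cycle contraction kinetics (10%/90%
#' crossings), the contraction force trace, and the axial stress (force per
#' surface area) trace. `autoplot()` dispatches on `type`.
#'
#' @param analysis An `eht_analysis`.
#' @return A ggplot object.
#' @name eht_plots
NULL

#' @rdname eht_plots
#' @export
plot_displacement <- function(analysis) {
  tr <- analysis$trace
  ex <- analysis$extrema
  marks <- dplyr::bind_rows(
    tibble(time_s = tr$time_s[ex$peaks], displacement_um = tr$smoothed_um[ex$peaks],
           what = "maximum"),
    tibble(time_s = tr$time_s[ex$troughs], displacement_um = tr$smoothed_um[ex$troughs],
           what = "minimum"))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$smoothed_um)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(y = .data$displacement_um, color = .data$what),
                        size = 2) +
    ggplot2::labs(x = "time (s)", y = "pillar displacement (µm)",
                  color = NULL,
                  title = paste0(analysis$source_name, ": displacement")) +
    ggplot2::theme_minimal()
}

#' @rdname eht_plots
#' @export
plot_kinetics <- function(analysis) {
  tr <- analysis$trace
  cyc <- analysis$cycles
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$smoothed_um)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::labs(x = "time (s)", y = "pillar displacement (µm)",
                  title = paste0(analysis$source_name,
                                 ": contraction kinetics (10%/90%)")) +
    ggplot2::theme_minimal()
  if (nrow(cyc) > 0) {
    km <- dplyr::bind_rows(
      tibble(time_s = tr$time_s[cyc$start_min_idx] + cyc$t_con_10_s, level = "10% contraction"),
      tibble(time_s = tr$time_s[cyc$start_min_idx] + cyc$t_con_90_s, level = "90% contraction"),
      tibble(time_s = tr$time_s[cyc$peak_idx] + cyc$t_rel_10_s, level = "10% relaxation"),
      tibble(time_s = tr$time_s[cyc$peak_idx] + cyc$t_rel_90_s, level = "90% relaxation"))
    km$displacement_um <- stats::approx(tr$time_s, tr$smoothed_um,
                                        xout = km$time_s)$y
    p <- p + ggplot2::geom_point(
      data = km, ggplot2::aes(y = .data$displacement_um, color = .data$level),
      size = 2) +
      ggplot2::labs(color = NULL)
  }
  p
}

#' @rdname eht_plots
#' @export
plot_force <- function(analysis) {
  tr <- analysis$trace
  ex <- analysis$extrema
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$force_un)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_point(data = tr[c(ex$peaks, ex$troughs), ],
                        color = "black", size = 1.5) +
    ggplot2::labs(x = "time (s)", y = "contraction force (µN)",
                  title = paste0(analysis$source_name, ": contraction force")) +
    ggplot2::theme_minimal()
}

#' @rdname eht_plots
#' @export
plot_stress <- function(analysis) {
  tr <- analysis$trace
  if (all(is.na(tr$stress_un_mm2))) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no tissue area available") +
             ggplot2::theme_void() +
             ggplot2::labs(title = paste0(analysis$source_name,
                                          ": force per surface area")))
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$stress_un_mm2)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (s)",
                  y = "axial stress (µN/mm²)",
                  title = paste0(analysis$source_name,
                                 ": force per surface area")) +
    ggplot2::theme_minimal()
}

#' @rdname eht_plots
#' @param object An `eht_analysis`.
#' @param type One of `"displacement"`, `"kinetics"`, `"force"`, `"stress"`.
#' @param ... Unused.
#' @method autoplot eht_analysis
#' @export
autoplot.eht_analysis <- function(object,
                                  type = c("displacement", "kinetics",
                                           "force", "stress"), ...) {
  switch(match.arg(type),
         displacement = plot_displacement(object),
         kinetics = plot_kinetics(object),
         force = plot_force(object),
         stress = plot_stress(object))
}
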