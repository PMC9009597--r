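#' Tidy a fitted contraction analysis
#'
#' `tidy()` returns one row per complete contraction cycle with the per-beat
#' features; `glance()` returns a one-row per-recording summary (means over
#' complete cycles, plus baseline, resting tension and tissue area).
#'
#' @param x An `eht_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy eht_analysis
#' @export
tidy.eht_analysis <- function(x, ...) {
  dplyr::mutate(x$cycles, source_name = x$source_name, .before = 1)
}

#' @rdname tidy.eht_analysis
#' @method glance eht_analysis
#' @export
glance.eht_analysis <- function(x, ...) {
  cyc <- x$cycles
  tibble(
    source_name = x$source_name,
    n_frames = nrow(x$trace),
    n_cycles = nrow(cyc),
    baseline_um = x$baseline_um,
    resting_tension_um = x$resting_tension_um,
    area_tissue_mm2 = x$area_tissue_mm2,
    amplitude_um = mean(cyc$amplitude_um),
    peak_force_un = mean(cyc$peak_force_un),
    max_peak_force_un = if (nrow(cyc) > 0) max(cyc$peak_force_un) else NA_real_,
    peak_stress_un_mm2 = mean(cyc$peak_stress_un_mm2),
    t_con_10_s = mean(cyc$t_con_10_s),
    t_con_90_s = mean(cyc$t_con_90_s),
    t_rel_10_s = mean(cyc$t_rel_10_s),
    t_rel_90_s = mean(cyc$t_rel_90_s),
    contraction_velocity_um_s = mean(cyc$contraction_velocity_um_s),
    relaxation_velocity_um_s = mean(cyc$relaxation_velocity_um_s),
    period_s = mean(cyc$period_s, na.rm = TRUE))
}
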