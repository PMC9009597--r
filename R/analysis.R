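#' Remove the resting tension from a distance trace
#'
#' The relaxed baseline is estimated as an upper percentile of the raw
#' inter-centroid distance (distance is maximal at full relaxation; the
#' percentile is robust to single-frame tracking jitter). Displacement is
#' `delta(t) = baseline - distance(t)`. When the unloaded inter-pillar
#' distance (no tissue attached) is known, the resting tension is reported
#' as `unloaded - baseline`, the static inward deflection held by the
#' relaxed tissue.
#'
#' Small negative displacements (within `neg_tol_um`) are measurement jitter
#' around the baseline and are clipped to zero; larger negatives indicate a
#' baseline failure and raise an error.
#'
#' @param trace Data frame with columns `time_s` and `distance_um` (a
#'   tracking trace, see [track_stack()]).
#' @param unloaded_distance_um Unloaded spacing in um, or `NA` if unknown.
#' @param baseline_percentile Percentile of the distance used as baseline.
#' @param neg_tol_um Clipping tolerance for negative displacement (um).
#' @return The input tibble with added `displacement_um`, plus attributes
#'   `baseline_um` and `resting_tension_um` (`NA` when unavailable).
#' @export
remove_resting_tension <- function(trace, unloaded_distance_um = NA_real_,
                                   baseline_percentile = 0.98,
                                   neg_tol_um = 2) {
  stopifnot(nrow(trace) > 0, all(c("time_s", "distance_um") %in% names(trace)))
  baseline <- quantile(trace$distance_um, baseline_percentile, names = FALSE)
  delta <- baseline - trace$distance_um
  if (any(delta < -neg_tol_um)) {
    abort(sprintf(
      "Displacement of %.3g um above the relaxed baseline: baseline estimate failed.",
      -min(delta)), class = "eht_analysis_error")
  }
  delta[delta < 0] <- 0
  out <- dplyr::mutate(as_tibble(trace), displacement_um = delta)
  attr(out, "baseline_um") <- baseline
  attr(out, "resting_tension_um") <-
    if (is.na(unloaded_distance_um)) NA_real_ else unloaded_distance_um - baseline
  out
}

#' Savitzky-Golay smoothing of a displacement trace
#'
#' Applies a Savitzky-Golay filter (local least-squares polynomial fit);
#' within the terminal windows the fitted polynomials are evaluated directly,
#' so edges are handled without padding artifacts and any polynomial of
#' degree up to `polyorder` passes through unchanged.
#'
#' @param x Numeric vector.
#' @param window Odd window length in samples.
#' @param polyorder Polynomial order (< window).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_trace <- function(x, window = 11, polyorder = 3) {
  if (window %% 2 == 0) window <- window + 1
  if (length(x) < window) {
    abort(sprintf("Trace of %d samples is shorter than the filter window (%d).",
                  length(x), window), class = "eht_analysis_error")
  }
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window))
}

# Savitzky-Golay window stated at the reference frame rate, rescaled to the
# recording's rate and kept odd.
sg_window_for_fps <- function(config, fps) {
  w <- round(config$sg_window * fps / config$sg_ref_fps)
  w <- max(w, config$sg_polyorder + 2, 5)
  if (w %% 2 == 0) w <- w + 1
  as.integer(w)
}

# interior local extrema with plateau handling: a plateau extremum is
# reported at its middle sample
local_extrema <- function(x) {
  sgn <- sign(diff(x))
  # carry the last nonzero slope through plateaus
  run <- sgn
  for (i in seq_along(run)) if (run[i] == 0 && i > 1) run[i] <- run[i - 1]
  peaks <- integer(0); troughs <- integer(0)
  # turning points of the de-plateaued slope
  turns <- which(diff(run) != 0) + 1L
  for (i in turns) {
    before <- run[i - 1]; after <- run[i]
    # locate plateau midpoint: extend left over equal values
    j <- i
    while (j > 1 && x[j - 1] == x[i]) j <- j - 1
    idx <- as.integer(floor((j + i) / 2))
    if (before > 0 && after < 0) peaks <- c(peaks, idx)
    if (before < 0 && after > 0) troughs <- c(troughs, idx)
  }
  list(peaks = peaks, troughs = troughs)
}

#' Detect contraction peaks and troughs
#'
#' Accepts local maxima lying within `peak_band_frac` of the top of the
#' trace's range ("20% from the top") and local minima within
#' `trough_band_frac` of the bottom ("15% from the baseline"), then enforces
#' alternation: between consecutive accepted peaks only the deepest trough
#' is kept and vice versa. A trace with no accepted peak raises the
#' documented "no peaks" error.
#'
#' @param x Smoothed displacement trace.
#' @param peak_band_frac,trough_band_frac Acceptance bands as fractions of
#'   the global range.
#' @param min_range Minimum global range for the trace to count as beating;
#'   below it (tracking jitter only) the "no peaks" error is raised.
#' @return List with integer vectors `peaks` and `troughs` (sample indices).
#' @export
detect_extrema <- function(x, peak_band_frac = 0.20, trough_band_frac = 0.15,
                           min_range = 0) {
  r <- max(x) - min(x)
  ex <- if (r > 0) local_extrema(x) else list(peaks = integer(0),
                                              troughs = integer(0))
  peaks <- ex$peaks[x[ex$peaks] >= min(x) + (1 - peak_band_frac) * r]
  troughs <- ex$troughs[x[ex$troughs] <= min(x) + trough_band_frac * r]
  if (length(peaks) == 0 || r <= min_range) {
    abort("No peaks detected in the contraction waveform.",
          class = "eht_analysis_error")
  }
  # alternation: keep the most extreme of any same-type run
  ev <- rbind(data.frame(idx = peaks, type = rep("peak", length(peaks))),
              data.frame(idx = troughs, type = rep("trough", length(troughs))))
  ev <- ev[order(ev$idx), ]
  keep <- logical(nrow(ev))
  i <- 1
  while (i <= nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$type[j + 1] == ev$type[i]) j <- j + 1
    run <- i:j
    best <- if (ev$type[i] == "peak") run[which.max(x[ev$idx[run]])]
            else run[which.min(x[ev$idx[run]])]
    keep[best] <- TRUE
    i <- j + 1
  }
  ev <- ev[keep, ]
  list(peaks = ev$idx[ev$type == "peak"], troughs = ev$idx[ev$type == "trough"])
}

#' Select complete contraction cycles
#'
#' A cycle is a trough-to-peak-to-trough excursion. Cycles missing a leading
#' or trailing trough, or whose bounding troughs coincide with the first or
#' last sample of the recording, are marked incomplete: recordings rarely
#' start exactly at the beginning of a beat, and truncated boundary beats
#' would bias force and kinetics.
#'
#' @param extrema Output of [detect_extrema()].
#' @param n_samples Trace length.
#' @return Tibble with `start_min_idx`, `peak_idx`, `end_min_idx`,
#'   `complete`; raises an error when no complete cycle exists.
#' @export
select_complete_cycles <- function(extrema, n_samples) {
  peaks <- extrema$peaks; troughs <- extrema$troughs
  cyc <- purrr::map_dfr(peaks, function(p) {
    lead <- troughs[troughs < p]
    trail <- troughs[troughs > p]
    s <- if (length(lead)) max(lead) else NA_integer_
    e <- if (length(trail)) min(trail) else NA_integer_
    tibble(start_min_idx = s, peak_idx = p, end_min_idx = e,
           complete = !is.na(s) && !is.na(e) && s > 1 && e < n_samples)
  })
  if (!any(cyc$complete)) {
    abort("No complete contraction cycle in the recording.",
          class = "eht_analysis_error")
  }
  cyc
}

#' Beam stiffness of the pillar
#'
#' The elastic beam bending relation for a cylindrical cantilever loaded at
#' height `a` gives a force-per-deflection stiffness
#' `k = 3 pi E R^4 / (2 a^2 (3 L - a))` in N/m. Conveniently,
#' `k` in N/m times a deflection in um is a force in uN.
#'
#' @param geometry A [pillar_geometry()].
#' @return Stiffness in N/m.
#' @export
beam_stiffness <- function(geometry) {
  stopifnot(inherits(geometry, "pillar_geometry"))
  E <- geometry$youngs_modulus_pa
  R <- geometry$pillar_radius_m
  L <- geometry$pillar_length_m
  a <- geometry$tissue_position_m
  3 * pi * E * R^4 / (2 * a^2 * (3 * L - a))
}

#' Convert pillar displacement to contraction force
#'
#' `F = 3 pi E R^4 delta / (2 a^2 (3 L - a))`: force is linear in the
#' deflection, scales with the fourth power of the pillar radius and the
#' first power of the Young's modulus.
#'
#' @param displacement_um Deflection trace in micrometres.
#' @param geometry A [pillar_geometry()].
#' @return Force trace in micronewtons.
#' @export
compute_force <- function(displacement_um, geometry) {
  beam_stiffness(geometry) * displacement_um
}

#' Axial stress: force per tissue surface area
#'
#' Normalizing the contraction force by the tissue's projected surface area
#' gives an axial stress in uN/mm^2 that can be followed over time without
#' the endpoint histology that a physiological cross-sectional area requires.
#'
#' @param force_un Force trace (uN).
#' @param area_tissue_mm2 Tissue surface area (mm^2, > 0).
#' @return Stress trace (uN/mm^2).
#' @export
compute_axial_stress <- function(force_un, area_tissue_mm2) {
  if (is.na(area_tissue_mm2) || area_tissue_mm2 <= 0) {
    abort("Tissue area must be positive to compute axial stress.",
          class = "eht_analysis_error")
  }
  force_un / area_tissue_mm2
}

# first crossing time of `level` on x[idx] (idx a contiguous range), linear
# interpolation between samples, relative to time[idx[1]]
first_crossing <- function(x, time, idx, level, rising = TRUE) {
  seg <- x[idx]
  hit <- if (rising) which(seg >= level) else which(seg <= level)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(0)
  x0 <- seg[i - 1]; x1 <- seg[i]
  t0 <- time[idx[i - 1]]; t1 <- time[idx[i]]
  f <- if (x1 == x0) 0 else (level - x0) / (x1 - x0)
  (t0 + f * (t1 - t0)) - time[idx[1]]
}

#' Per-cycle contraction features
#'
#' For one complete cycle, measures amplitude, peak force, kinetics (times
#' from the cycle start to reach 10% and 90% of the contraction amplitude,
#' and from the peak to decay by 10% and 90% of the relaxation amplitude,
#' linearly interpolated between frames) and phase velocities (maximum
#' |d delta/dt| by central differences on the smoothed trace, or
#' amplitude / 10-90% time when `velocity_mode = "amplitude_over_rise"`).
#'
#' @param cycle One row of [select_complete_cycles()].
#' @param x Smoothed displacement trace (um).
#' @param time Time vector (s).
#' @param geometry A [pillar_geometry()].
#' @param area_tissue_mm2 Tissue area for stress, or `NA`.
#' @param velocity_mode `"derivative"` or `"amplitude_over_rise"`.
#' @return One-row tibble of cycle features.
#' @export
compute_kinetics <- function(cycle, x, time, geometry,
                             area_tissue_mm2 = NA_real_,
                             velocity_mode = "derivative") {
  s <- cycle$start_min_idx; p <- cycle$peak_idx; e <- cycle$end_min_idx
  stopifnot(s < p, p < e)
  amp_con <- x[p] - x[s]
  amp_rel <- x[p] - x[e]
  if (amp_con <= 0) {
    abort("Cycle has non-positive amplitude.", class = "eht_analysis_error")
  }
  con_idx <- s:p; rel_idx <- p:e
  t_con_10 <- first_crossing(x, time, con_idx, x[s] + 0.1 * amp_con, TRUE)
  t_con_90 <- first_crossing(x, time, con_idx, x[s] + 0.9 * amp_con, TRUE)
  t_rel_10 <- first_crossing(x, time, rel_idx, x[p] - 0.1 * amp_rel, FALSE)
  t_rel_90 <- first_crossing(x, time, rel_idx, x[p] - 0.9 * amp_rel, FALSE)

  dt <- diff(time[1:2])
  vel <- function(idx, sgn) {
    if (length(idx) < 3) return(sgn * (x[idx[length(idx)]] - x[idx[1]]) /
                                  (time[idx[length(idx)]] - time[idx[1]]))
    i <- idx[2:(length(idx) - 1)]
    max(sgn * (x[i + 1] - x[i - 1]) / (2 * dt))
  }
  if (velocity_mode == "derivative") {
    v_con <- vel(con_idx, 1)
    v_rel <- vel(rel_idx, -1)
  } else {
    v_con <- amp_con / (t_con_90 - t_con_10)
    v_rel <- amp_rel / (t_rel_90 - t_rel_10)
  }

  peak_force <- compute_force(amp_con, geometry)
  tibble(
    start_min_idx = s, peak_idx = p, end_min_idx = e,
    amplitude_um = amp_con,
    peak_force_un = peak_force,
    peak_stress_un_mm2 = if (is.na(area_tissue_mm2)) NA_real_
                         else peak_force / area_tissue_mm2,
    t_con_10_s = t_con_10, t_con_90_s = t_con_90,
    t_rel_10_s = t_rel_10, t_rel_90_s = t_rel_90,
    time_to_peak_s = time[p] - time[s],
    contraction_velocity_um_s = v_con,
    relaxation_velocity_um_s = v_rel,
    period_s = NA_real_)  # peak-to-peak, filled in once all peaks are known
}

#' Full waveform analysis of a distance trace
#'
#' Chains baseline removal, Savitzky-Golay smoothing, extremum detection,
#' complete-cycle selection, force, stress and kinetics into one fitted
#' object. This is the post-tracking half of the pipeline and can be applied
#' to any distance trace (measured or synthetic).
#'
#' @param trace Data frame with `time_s` and `distance_um` (and optionally
#'   `frame`, `area_mm2`).
#' @param config An [eht_config()].
#' @param area_tissue_mm2 Per-recording tissue area (mm^2) for stress, `NA`
#'   to skip stress.
#' @param frame_rate_fps Frame rate; inferred from `time_s` when missing.
#' @param pixel_size_um Pixel calibration used for the negative-displacement
#'   clipping tolerance.
#' @param extrema_override Optional list with `peaks`/`troughs` indices or
#'   `window = c(first, last)` frames (the declarative form of the manual
#'   mode): supplied extrema replace the detector's output before cycle
#'   selection; a window restricts detection to that frame range.
#' @param source_name Identifier carried into outputs.
#' @return An object of class `eht_analysis`; see [tidy.eht_analysis()] and
#'   [glance.eht_analysis()].
#' @export
analyze_trace <- function(trace, config = eht_config(),
                          area_tissue_mm2 = NA_real_,
                          frame_rate_fps = NULL,
                          pixel_size_um = 3.25,
                          extrema_override = NULL,
                          source_name = "trace") {
  if (is.null(frame_rate_fps)) {
    frame_rate_fps <- 1 / median(diff(trace$time_s))
  }
  geometry <- geometry_from_config(config)
  base <- remove_resting_tension(
    trace, config$unloaded_distance_um, config$baseline_percentile,
    neg_tol_um = config$neg_clip_px * pixel_size_um)
  win <- sg_window_for_fps(config, frame_rate_fps)
  smoothed <- smooth_trace(base$displacement_um, win, config$sg_polyorder)

  n <- nrow(base)
  if (!is.null(extrema_override) &&
      (!is.null(extrema_override$peaks) || !is.null(extrema_override$troughs))) {
    extrema <- list(peaks = sort(as.integer(extrema_override$peaks)),
                    troughs = sort(as.integer(extrema_override$troughs)))
    if (length(extrema$peaks) == 0) {
      abort("No peaks detected in the contraction waveform.",
            class = "eht_analysis_error")
    }
  } else if (!is.null(extrema_override$window)) {
    wnd <- as.integer(extrema_override$window)
    idx <- max(wnd[1], 1):min(wnd[2], n)
    extrema <- detect_extrema(smoothed[idx], config$peak_band_frac,
                              config$trough_band_frac,
                              min_range = config$min_amplitude_um)
    extrema <- list(peaks = extrema$peaks + idx[1] - 1L,
                    troughs = extrema$troughs + idx[1] - 1L)
  } else {
    extrema <- detect_extrema(smoothed, config$peak_band_frac,
                              config$trough_band_frac,
                              min_range = config$min_amplitude_um)
  }

  cycles <- select_complete_cycles(extrema, n)
  complete <- cycles[cycles$complete, ]
  features <- purrr::map_dfr(seq_len(nrow(complete)), function(i) {
    compute_kinetics(complete[i, ], smoothed, base$time_s, geometry,
                     area_tissue_mm2, config$velocity_mode)
  })
  # beat period: interval between consecutive detected peaks (all peaks, so a
  # truncated neighbor still anchors the interval); NA only for the last peak
  if (nrow(features) > 0) {
    all_peaks <- sort(extrema$peaks)
    nxt <- findInterval(features$peak_idx, all_peaks) + 1L
    features$period_s <- ifelse(nxt <= length(all_peaks),
                                base$time_s[all_peaks[nxt]] -
                                  base$time_s[features$peak_idx],
                                NA_real_)
  }

  force <- compute_force(smoothed, geometry)
  full <- dplyr::mutate(
    base,
    smoothed_um = smoothed,
    force_un = force,
    stress_un_mm2 = if (!is.na(area_tissue_mm2) && area_tissue_mm2 > 0)
      force / area_tissue_mm2 else NA_real_)

  structure(list(
    trace = full,
    cycles = features,
    all_cycles = cycles,
    extrema = extrema,
    baseline_um = attr(base, "baseline_um"),
    resting_tension_um = attr(base, "resting_tension_um"),
    area_tissue_mm2 = area_tissue_mm2,
    geometry = geometry,
    config = config,
    frame_rate_fps = frame_rate_fps,
    source_name = source_name),
    class = "eht_analysis")
}

#' @export
print.eht_analysis <- function(x, ...) {
  cat(sprintf("<eht_analysis> %s: %d frames, %d complete cycles\n",
              x$source_name, nrow(x$trace), nrow(x$cycles)))
  if (nrow(x$cycles) > 0) {
    cat(sprintf("  mean amplitude %.2f um, mean peak force %.2f uN\n",
                mean(x$cycles$amplitude_um), mean(x$cycles$peak_force_un)))
  }
  invisible(x)
}
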