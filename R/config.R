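#' Analysis configuration
#'
#' Builds the configuration list consumed by [analyze_file()] and [run_batch()].
#' Every knob of the pipeline lives here so that a batch run is fully described
#' by one object. Defaults follow a 100 fps, 2x magnification acquisition with
#' PDMS pillars.
#'
#' @param mode Pillar detection mode: `"black_tip"` (carbon-black painted pillar
#'   tips appearing as solid dark discs) or `"mser"` (transparent pillars found
#'   as maximally stable extremal regions with low eccentricity).
#' @param camera_pixel_um Physical sensor pixel pitch in micrometres. Used with
#'   binning and magnification to calibrate pixel size when the metadata file
#'   does not carry a calibration.
#' @param magnification Optical magnification of the acquisition.
#' @param eccentricity_max Maximum ellipse eccentricity for an MSER region to be
#'   considered a candidate pillar tip (0 = circle, 1 = line).
#' @param mser_delta Stability test half-width in grey levels.
#' @param mser_area_min_frac,mser_area_max_frac Admissible region area as a
#'   fraction of the half-image area.
#' @param mser_max_variation Maximum relative area variation for a region to be
#'   considered stable.
#' @param min_component_px Minimum dark-component area (px) in black-tip mode;
#'   components below it are ignored as debris.
#' @param debris_frac Components smaller than this fraction of the expected
#'   pillar area are treated as artifacts and filled before detection.
#' @param pillar_area_mm2 Combined footprint of the two pillar tips, subtracted
#'   from the segmented area to obtain the tissue-only area (mm^2).
#' @param youngs_modulus_pa,pillar_radius_m,pillar_length_m,tissue_position_m
#'   Elastic beam parameters E, R, L and a of the force transduction
#'   F = 3*pi*E*R^4 * delta / (2*a^2*(3L - a)).
#' @param unloaded_distance_um Inter-centroid distance with no tissue attached;
#'   enables the resting-tension readout when provided (`NA` disables it).
#' @param baseline_percentile Percentile of the raw distance trace taken as the
#'   relaxed baseline (distance is maximal at relaxation).
#' @param peak_band_frac Peaks must lie within this fraction of the trace range
#'   from the top (the "20% from the top" acceptance band).
#' @param trough_band_frac Troughs must lie within this fraction of the range
#'   from the bottom (the "15% from the baseline" band).
#' @param sg_window,sg_polyorder Savitzky-Golay window length (odd, frames at
#'   `sg_ref_fps`) and polynomial order. The window is rescaled proportionally
#'   to the actual frame rate and kept odd.
#' @param sg_ref_fps Frame rate at which `sg_window` is stated.
#' @param velocity_mode `"derivative"` (max |d delta/dt| within the phase) or
#'   `"amplitude_over_rise"` (amplitude / 10-90% time).
#' @param neg_clip_px Negative displacements smaller in magnitude than this
#'   many pixels (after calibration) are clipped to zero; larger negatives
#'   indicate a baseline failure and raise an error.
#' @param min_amplitude_um Minimum peak-to-trough range (um) for the waveform
#'   to count as contracting; traces whose whole range is below it (e.g. a
#'   non-beating tissue, where the only structure is tracking jitter) raise
#'   the "no peaks" error instead of reporting sub-micrometre beats.
#'
#' @return A named list of class `eht_config`.
#' @export
#' @examples
#' cfg <- eht_config(mode = "black_tip")
#' cfg$pillar_area_mm2
eht_config <- function(mode = c("black_tip", "mser"),
                       camera_pixel_um = 6.5,
                       magnification = 2.0,
                       eccentricity_max = 0.75,
                       mser_delta = 5,
                       mser_area_min_frac = 0.002,
                       mser_area_max_frac = 0.25,
                       mser_max_variation = 0.5,
                       min_component_px = 50,
                       debris_frac = 0.01,
                       pillar_area_mm2 = 0.4,
                       youngs_modulus_pa = 1.5e6,
                       pillar_radius_m = 2.5e-4,
                       pillar_length_m = 3e-3,
                       tissue_position_m = 2e-3,
                       unloaded_distance_um = NA_real_,
                       baseline_percentile = 0.98,
                       peak_band_frac = 0.20,
                       trough_band_frac = 0.15,
                       sg_window = 11,
                       sg_polyorder = 3,
                       sg_ref_fps = 100,
                       velocity_mode = c("derivative", "amplitude_over_rise"),
                       neg_clip_px = 0.5,
                       min_amplitude_um = 1.0) {
  mode <- match.arg(mode)
  velocity_mode <- match.arg(velocity_mode)
  stopifnot(camera_pixel_um > 0, magnification > 0,
            eccentricity_max > 0, eccentricity_max <= 1,
            mser_delta >= 1, mser_area_min_frac > 0,
            mser_area_max_frac > mser_area_min_frac,
            pillar_area_mm2 >= 0,
            sg_window >= 3, sg_polyorder >= 1, sg_polyorder < sg_window)
  structure(
    list(mode = mode,
         camera_pixel_um = camera_pixel_um,
         magnification = magnification,
         eccentricity_max = eccentricity_max,
         mser_delta = mser_delta,
         mser_area_min_frac = mser_area_min_frac,
         mser_area_max_frac = mser_area_max_frac,
         mser_max_variation = mser_max_variation,
         min_component_px = min_component_px,
         debris_frac = debris_frac,
         pillar_area_mm2 = pillar_area_mm2,
         youngs_modulus_pa = youngs_modulus_pa,
         pillar_radius_m = pillar_radius_m,
         pillar_length_m = pillar_length_m,
         tissue_position_m = tissue_position_m,
         unloaded_distance_um = unloaded_distance_um,
         baseline_percentile = baseline_percentile,
         peak_band_frac = peak_band_frac,
         trough_band_frac = trough_band_frac,
         sg_window = sg_window,
         sg_polyorder = sg_polyorder,
         sg_ref_fps = sg_ref_fps,
         velocity_mode = velocity_mode,
         neg_clip_px = neg_clip_px,
         min_amplitude_um = min_amplitude_um),
    class = "eht_config")
}

#' Pillar beam geometry
#'
#' Convenience constructor for the elastic beam parameters of the pillar used
#' as force sensor. All lengths in metres, Young's modulus in pascal.
#'
#' @param youngs_modulus_pa Young's modulus E of the pillar material (Pa).
#' @param pillar_radius_m Pillar radius R (m).
#' @param pillar_length_m Pillar length L (m).
#' @param tissue_position_m Attachment height a of the tissue along the pillar
#'   (m), with 0 < a <= L.
#' @param unloaded_distance_um Optional unloaded inter-centroid distance (um).
#' @return A list of class `pillar_geometry`.
#' @export
pillar_geometry <- function(youngs_modulus_pa = 1.5e6,
                            pillar_radius_m = 2.5e-4,
                            pillar_length_m = 3e-3,
                            tissue_position_m = 2e-3,
                            unloaded_distance_um = NA_real_) {
  if (!(youngs_modulus_pa > 0 && pillar_radius_m > 0 && pillar_length_m > 0)) {
    abort("E, R and L must all be positive.", class = "eht_config_error")
  }
  if (!(tissue_position_m > 0 && tissue_position_m <= pillar_length_m)) {
    abort("tissue position a must satisfy 0 < a <= L.",
          class = "eht_config_error")
  }
  structure(list(youngs_modulus_pa = youngs_modulus_pa,
                 pillar_radius_m = pillar_radius_m,
                 pillar_length_m = pillar_length_m,
                 tissue_position_m = tissue_position_m,
                 unloaded_distance_um = unloaded_distance_um),
            class = "pillar_geometry")
}

geometry_from_config <- function(config) {
  pillar_geometry(config$youngs_modulus_pa, config$pillar_radius_m,
                  config$pillar_length_m, config$tissue_position_m,
                  config$unloaded_distance_um)
}
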