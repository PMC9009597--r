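# Shared fixture builders. All geometry is in px at a 3.25 um pixel
# (100 fps, 2x magnification, 6.5 um sensor pitch, binning 1).

PX_UM <- 3.25

# standard metadata sidecar content
fx_metadata <- function(fps = 100, binning = 1) {
  parse_metadata(sprintf("FrameRate=%g\nBinning=%g", fps, binning))
}

# Black-tip tracking scene: strong illumination, tissue barely visible,
# solid dark tips. Noise sd = 5% of the tip/background contrast.
fx_scene_blacktip <- function(amplitude_px = 12, noise = TRUE,
                              image_size = c(160, 360), radius = 22) {
  scene_spec(image_size_px = image_size, pillar_radius_px = radius,
             pillar_style = "black_tip", band_half_height_px = 12,
             background_level = 220, tissue_level = 200, pillar_level = 25,
             noise_sd = if (noise) 0.05 * (220 - 25) else 0)
}

# Transparent-pillar tracking scene: visible tissue band touching the rings.
fx_scene_ring <- function(noise = TRUE, image_size = c(160, 360), radius = 22,
                          band_half = 15) {
  scene_spec(image_size_px = image_size, pillar_radius_px = radius,
             pillar_style = "transparent_ring", band_half_height_px = band_half,
             ring_width_px = 7, background_level = 210, tissue_level = 110,
             pillar_level = 30, interior_level = 170,
             noise_sd = if (noise) 0.05 * (210 - 110) else 0)
}

# Realistic-scale compaction scene (transparent pillars): ~3 mm wide frame,
# tissue band shrinking as it compacts. band_half in px of a 3.25 um pixel.
fx_scene_area <- function(band_half, noise = TRUE) {
  scene_spec(image_size_px = c(420, 960), pillar_radius_px = 55,
             pillar_centers_rest_px = rbind(c(210, 180), c(210, 780)),
             pillar_style = "transparent_ring", band_half_height_px = band_half,
             ring_width_px = 9, background_level = 210, tissue_level = 110,
             pillar_level = 30, interior_level = 170,
             noise_sd = if (noise) 0.05 * (210 - 110) else 0)
}

# rest-distance of a scene in um
fx_rest_um <- function(scene, px_um = PX_UM) {
  cc <- scene$pillar_centers_rest_px
  sqrt(sum((cc[2, ] - cc[1, ])^2)) * px_um
}

fx_waveform <- function(scene, amplitude_px = 12, n_beats = 4,
                        n_frames = 520, period_s = 1, rise_fraction = 0.5,
                        phase_offset_s = 0.5, fps = 100, px_um = PX_UM) {
  generate_waveform(baseline_distance_um = fx_rest_um(scene, px_um),
                    amplitude_um = amplitude_px * px_um,
                    period_s = period_s, n_beats = n_beats,
                    rise_fraction = rise_fraction,
                    phase_offset_s = phase_offset_s,
                    frame_rate_fps = fps, n_frames = n_frames)
}

# static (non-beating) waveform for area scenes
fx_static_waveform <- function(scene, n_frames = 2, px_um = PX_UM) {
  generate_waveform(baseline_distance_um = fx_rest_um(scene, px_um),
                    amplitude_um = 0, n_beats = 0, n_frames = n_frames,
                    frame_rate_fps = 100)
}

# config matched to the small tracking fixtures: the pillar footprint of the
# synthetic platform (two discs of `radius` px) replaces the default 0.4 mm2
fx_config <- function(mode, radius = 22, px_um = PX_UM, ...) {
  eht_config(mode = mode,
             pillar_area_mm2 = 2 * pi * radius^2 * (px_um / 1000)^2, ...)
}
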