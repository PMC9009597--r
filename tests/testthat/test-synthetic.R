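# dense numeric sampling of one raised-cosine beat: independent oracle for
# the analytic crossing times frozen into the waveform's ground truth
numeric_crossing <- function(p, period = 1, rf = 0.5, n = 2e6) {
  u <- seq(0, rf, length.out = n)
  g <- (1 - cos(pi * u / rf)) / 2
  u[which(g >= p)[1]] * period
}

test_that("analytic 10-90% contraction time matches dense numeric inversion", {
  wf <- generate_waveform(amplitude_um = 40, period_s = 1, rise_fraction = 0.5,
                          n_beats = 1, n_frames = 200)
  t10 <- numeric_crossing(0.1); t90 <- numeric_crossing(0.9)
  expect_equal(wf$beats$t_con_10_s[1], t10, tolerance = 1e-5)
  expect_equal(wf$beats$t_con_90_s[1], t90, tolerance = 1e-5)
  # closed form evaluates to ~0.295 s for T = 1 s
  expect_equal(wf$beats$t_con_90_s[1] - wf$beats$t_con_10_s[1],
               (0.5 / pi) * (acos(-0.8) - acos(0.8)), tolerance = 1e-12)
  # asymmetric beat scales the contraction-phase kinetics by rise_fraction
  wf2 <- generate_waveform(amplitude_um = 40, period_s = 1, rise_fraction = 0.3,
                           n_beats = 1, n_frames = 200)
  expect_equal(wf2$beats$t_con_90_s[1] - wf2$beats$t_con_10_s[1],
               numeric_crossing(0.9, rf = 0.3) - numeric_crossing(0.1, rf = 0.3),
               tolerance = 1e-5)
})

test_that("waveform degenerate and error cases behave as specified", {
  wf0 <- generate_waveform(amplitude_um = 0, n_beats = 3, n_frames = 100)
  expect_true(all(wf0$trace$distance_um == wf0$baseline_distance_um))
  expect_error(generate_waveform(baseline_distance_um = 10, amplitude_um = 10),
               class = "eht_spec_error")
})

test_that("beats that straddle a recording boundary are labelled incomplete", {
  wf <- generate_waveform(amplitude_um = 30, period_s = 1, n_beats = 3,
                          phase_offset_s = -0.5, n_frames = 220,
                          frame_rate_fps = 100)
  expect_equal(wf$beats$complete, c(FALSE, TRUE, FALSE))
})

test_that("rendered ground-truth spacing equals the waveform distance", {
  sc <- fx_scene_blacktip(noise = FALSE)
  wf <- fx_waveform(sc, n_frames = 60, n_beats = 1, phase_offset_s = 0.1)
  vid <- render_video(sc, wf, pixel_size_um = PX_UM, seed = 1)
  expect_equal(vid$truth$distance_um, wf$trace$distance_um, tolerance = 1e-9)
  # asymmetric motion leaves the distance trace untouched
  sc2 <- fx_scene_blacktip(noise = FALSE); sc2$asymmetry <- 0.8
  vid2 <- render_video(sc2, wf, pixel_size_um = PX_UM, seed = 1)
  expect_equal(vid2$truth$distance_um, wf$trace$distance_um, tolerance = 1e-9)
})

test_that("rendering is deterministic under a fixed seed", {
  sc <- fx_scene_ring()
  sc$n_debris <- 3
  wf <- fx_waveform(sc, n_frames = 12, n_beats = 1, phase_offset_s = 0)
  v1 <- render_video(sc, wf, seed = 99)
  v2 <- render_video(sc, wf, seed = 99)
  expect_identical(v1$stack$frames, v2$stack$frames)
  v3 <- render_video(sc, wf, seed = 100)
  expect_false(identical(v3$stack$frames, v1$stack$frames))
})

test_that("rasterized tissue-band area matches the analytic union area", {
  for (band_half in c(15, 30)) {   # band thinner and thicker than the tip radius
    sc <- fx_scene_ring(noise = FALSE, band_half = band_half)
    wf <- fx_static_waveform(sc)
    vid <- render_video(sc, wf, seed = 1)
    img <- matrix(vid$stack$frames[1, , ], sc$image_size_px[1])
    mask <- img < (sc$tissue_level + sc$background_level) / 2
    lab <- label_components(mask, conn = 8)
    sizes <- tabulate(lab[lab > 0])
    # fill interior holes of the connected tissue+pillar structure
    filled <- ehttrack:::fill_holes(lab == which.max(sizes))
    expect_equal(sum(filled), vid$truth$area_px2[1],
                 tolerance = 0.015)
  }
})

test_that("pillar discs leaving the frame raise a spec error", {
  sc <- fx_scene_blacktip(noise = FALSE, image_size = c(60, 120), radius = 25)
  sc$pillar_centers_rest_px <- rbind(c(30, 20), c(30, 94))
  wf <- generate_waveform(baseline_distance_um = fx_rest_um(sc),
                          amplitude_um = 40 * PX_UM, n_beats = 1,
                          n_frames = 50, frame_rate_fps = 100,
                          phase_offset_s = 0)
  expect_error(render_video(sc, wf), class = "eht_spec_error")
})

test_that("write_fixture emits the reader's exact dialect and round-trips", {
  dir <- withr::local_tempdir()
  sc <- fx_scene_blacktip(noise = FALSE)
  wf <- fx_waveform(sc, n_frames = 10, n_beats = 1, phase_offset_s = 0)
  vid <- render_video(sc, wf, seed = 2)
  paths <- write_fixture(vid, dir, "rec1")
  st <- load_stack(paths[["tif"]])
  expect_identical(st$frames, vid$stack$frames)
  md <- read_metadata(paths[["txt"]])
  expect_equal(md$pixel_size_um, PX_UM)
  truth <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(truth$truth$distance_um, vid$truth$distance_um)
})
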