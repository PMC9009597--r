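test_that("resting tension is the unloaded-minus-baseline offset", {
  wf <- generate_waveform(baseline_distance_um = 2000, amplitude_um = 35,
                          resting_tension_um = 50, n_beats = 4,
                          phase_offset_s = 0.5, n_frames = 520)
  base <- remove_resting_tension(wf$trace,
                                 unloaded_distance_um = wf$unloaded_distance_um)
  expect_equal(attr(base, "resting_tension_um"), 50, tolerance = 1e-6)
  expect_equal(max(base$displacement_um), 35, tolerance = 0.02 * 35)

  # unloaded spacing unknown -> resting tension not available, delta unchanged
  base2 <- remove_resting_tension(wf$trace)
  expect_true(is.na(attr(base2, "resting_tension_um")))
  expect_equal(base2$displacement_um, base$displacement_um)

  # constant trace -> delta identically zero
  flat <- tibble::tibble(time_s = (0:99) / 100, distance_um = rep(1500, 100))
  expect_true(all(remove_resting_tension(flat)$displacement_um == 0))
})

test_that("displacements far above the baseline raise a baseline error", {
  tr <- tibble::tibble(time_s = (0:99) / 100,
                       distance_um = c(rep(1000, 99), 1100))
  expect_error(remove_resting_tension(tr, neg_tol_um = 2),
               class = "eht_analysis_error")
})

test_that("savitzky-golay smoothing reproduces polynomials and reduces noise", {
  t <- seq(0, 1, length.out = 200)
  for (cf in list(c(1, -2, 3, 0.5), c(0, 1, 0, -4))) {
    y <- cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3
    expect_lt(max(abs(smooth_trace(y, 11, 3) - y)), 1e-9)
  }
  set.seed(33)
  noise <- rnorm(500, sd = 1)
  expect_lt(sd(smooth_trace(noise, 11, 3)), sd(noise))
  expect_error(smooth_trace(rnorm(5), 11, 3), class = "eht_analysis_error")
})

test_that("smoothing keeps beat timing stable under tracking jitter", {
  # jitter at the scale the tracker actually produces (~0.2 px = 0.65 um)
  wf <- generate_waveform(amplitude_um = 40, n_beats = 4, phase_offset_s = 0.5,
                          n_frames = 520)
  clean <- wf$baseline_distance_um - wf$trace$distance_um
  set.seed(12)
  noisy <- clean + rnorm(length(clean), sd = 0.65)
  s_clean <- smooth_trace(clean, 11, 3)
  s_noisy <- smooth_trace(noisy, 11, 3)
  p_clean <- detect_extrema(s_clean)$peaks
  p_noisy <- detect_extrema(s_noisy)$peaks
  expect_equal(length(p_noisy), length(p_clean))
  # the beat's flat top lets the argmax wander a little; the steep-slope
  # half-amplitude crossings, which set the kinetics, stay within a frame
  cross <- function(x, peaks) {
    vapply(peaks, function(p) {
      seg <- x[(p - 60):p]
      (p - 60) + which(seg >= min(x) + 0.5 * (max(x) - min(x)))[1] - 1
    }, numeric(1))
  }
  expect_lt(max(abs(cross(s_noisy, p_noisy) - cross(s_clean, p_clean))), 1.5)
})

test_that("extremum detection enforces bands and alternation", {
  wf <- generate_waveform(amplitude_um = 40, n_beats = 5, phase_offset_s = 0.5,
                          n_frames = 620)
  x <- smooth_trace(wf$baseline_distance_um - wf$trace$distance_um, 11, 3)
  ex <- detect_extrema(x)
  expect_length(ex$peaks, 5)
  expect_length(ex$troughs, 6)
  expect_true(all(diff(sort(c(ex$peaks, ex$troughs))) > 0))

  # a bump reaching only 50% of the range is rejected by the top-20% band
  y <- c(rep(0, 50), seq(0, 1, length.out = 20), seq(1, 0, length.out = 20),
         rep(0, 30), seq(0, 0.5, length.out = 10), seq(0.5, 0, length.out = 10),
         rep(0, 30), seq(0, 1, length.out = 20), seq(1, 0, length.out = 20),
         rep(0, 50))
  exy <- detect_extrema(y)
  expect_length(exy$peaks, 2)

  expect_error(detect_extrema(rep(1, 100)), class = "eht_analysis_error")
  # a jitter-scale trace is "not beating" under the amplitude floor
  set.seed(2)
  expect_error(detect_extrema(rnorm(200, sd = 0.05), min_range = 1),
               class = "eht_analysis_error")
})

test_that("only interior trough-peak-trough excursions count as complete", {
  # recording starts mid-contraction: first beat lacks its leading trough
  wf <- generate_waveform(amplitude_um = 40, n_beats = 5, phase_offset_s = -0.5,
                          n_frames = 520)
  x <- smooth_trace(wf$baseline_distance_um - wf$trace$distance_um, 11, 3)
  cyc <- select_complete_cycles(detect_extrema(x), length(x))
  expect_equal(sum(cyc$complete), 4)

  # five interior beats fully framed -> five complete cycles
  wf2 <- generate_waveform(amplitude_um = 40, n_beats = 5, phase_offset_s = 0.5,
                           n_frames = 620)
  x2 <- smooth_trace(wf2$baseline_distance_um - wf2$trace$distance_um, 11, 3)
  cyc2 <- select_complete_cycles(detect_extrema(x2), length(x2))
  expect_equal(sum(cyc2$complete), 5)

  # a single truncated beat has no complete cycle at all
  wf3 <- generate_waveform(amplitude_um = 40, n_beats = 1, phase_offset_s = -0.3,
                           n_frames = 60)
  x3 <- smooth_trace(wf3$baseline_distance_um - wf3$trace$distance_um, 11, 3)
  expect_error(select_complete_cycles(detect_extrema(x3), length(x3)),
               class = "eht_analysis_error")
})

test_that("beam bending force matches its closed form and scaling laws", {
  geo <- pillar_geometry(1e6, 1e-4, 1e-3, 5e-4)
  # independent evaluation in SI units, converted to uN at the end
  f_si <- 3 * pi * 1e6 * (1e-4)^4 * 1e-5 / (2 * (5e-4)^2 * (3 * 1e-3 - 5e-4))
  expect_equal(compute_force(10, geo), f_si * 1e6, tolerance = 1e-12)
  expect_equal(compute_force(10, geo), 7.5398, tolerance = 1e-4)

  expect_identical(compute_force(0, geo), 0)
  delta <- c(0.5, 1, 7, 30)
  expect_identical(compute_force(3 * delta, geo), 3 * compute_force(delta, geo))
  geo2E <- pillar_geometry(2e6, 1e-4, 1e-3, 5e-4)
  expect_equal(compute_force(delta, geo2E), 2 * compute_force(delta, geo))
  geo2R <- pillar_geometry(1e6, 2e-4, 1e-3, 5e-4)
  expect_equal(compute_force(delta, geo2R), 16 * compute_force(delta, geo))

  expect_error(pillar_geometry(1e6, 1e-4, 1e-3, 2e-3),  # a > L
               class = "eht_config_error")
})

test_that("axial stress is force per surface area", {
  expect_equal(compute_axial_stress(10, 2), 5)
  f <- c(0, 3, 9, 4.5)
  expect_equal(compute_axial_stress(f, 1.5), f / 1.5)
  expect_error(compute_axial_stress(10, 0), class = "eht_analysis_error")
  expect_error(compute_axial_stress(10, NA_real_), class = "eht_analysis_error")
})

test_that("measured kinetics match the closed-form raised-cosine values", {
  wf <- generate_waveform(amplitude_um = 40, period_s = 1, n_beats = 4,
                          phase_offset_s = 0.5, n_frames = 520,
                          frame_rate_fps = 100)
  an <- analyze_trace(wf$trace, eht_config("black_tip"), frame_rate_fps = 100)
  cyc <- an$cycles
  expect_equal(nrow(cyc), 4)
  truth <- wf$beats[wf$beats$complete, ]
  # 10-90% contraction time within one frame interval of the analytic value
  expect_lt(max(abs((cyc$t_con_90_s - cyc$t_con_10_s) -
                      (truth$t_con_90_s[1] - truth$t_con_10_s[1]))), 0.010)
  # symmetric beats: contraction and relaxation durations agree within a frame
  expect_lt(max(abs((cyc$t_rel_90_s - cyc$t_rel_10_s) -
                      (cyc$t_con_90_s - cyc$t_con_10_s))), 0.010)
  # peak contraction velocity ~ pi * A / T for the full-period raised cosine
  expect_equal(mean(cyc$contraction_velocity_um_s), pi * 40 / 1,
               tolerance = 0.02)
  expect_equal(mean(cyc$period_s, na.rm = TRUE), 1, tolerance = 0.01)
  # kinetics ordering holds cycle by cycle
  expect_true(all(cyc$t_con_10_s < cyc$t_con_90_s))
  expect_true(all(cyc$t_con_90_s <= cyc$time_to_peak_s))
  expect_true(all(cyc$t_rel_10_s < cyc$t_rel_90_s))
})

test_that("amplitude recovery is within 2% on noisy fixtures across seeds", {
  for (seed in 1:3) {
    wf <- generate_waveform(amplitude_um = 40, n_beats = 4,
                            phase_offset_s = 0.5, n_frames = 520)
    set.seed(seed)
    noisy <- dplyr::mutate(wf$trace,
                           distance_um = distance_um +
                             rnorm(dplyr::n(), sd = 0.65))
    an <- analyze_trace(noisy, eht_config("black_tip"), frame_rate_fps = 100)
    expect_equal(nrow(an$cycles), 4)
    expect_equal(mean(an$cycles$amplitude_um), 40, tolerance = 0.02)
    expect_equal(mean(an$cycles$period_s, na.rm = TRUE), 1, tolerance = 0.011)
  }
})

test_that("tidy and glance expose per-cycle and per-recording views", {
  wf <- generate_waveform(amplitude_um = 40, n_beats = 3, phase_offset_s = 0.5,
                          n_frames = 420)
  an <- analyze_trace(wf$trace, eht_config("black_tip"), frame_rate_fps = 100,
                      area_tissue_mm2 = 2, source_name = "demo")
  td <- tidy(an)
  expect_equal(nrow(td), 3)
  expect_equal(td$source_name, rep("demo", 3))
  gl <- glance(an)
  expect_equal(gl$n_cycles, 3)
  expect_equal(gl$peak_stress_un_mm2, gl$peak_force_un / 2, tolerance = 1e-9)
})
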