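# write a small beating black-tip recording (tiff + txt) into dir
fx_write_recording <- function(dir, name, seed, n_beats = 3, n_frames = 420,
                               amplitude_px = 12) {
  sc <- fx_scene_blacktip()
  wf <- fx_waveform(sc, amplitude_px = amplitude_px, n_beats = n_beats,
                    n_frames = n_frames, phase_offset_s = 0.5)
  vid <- render_video(sc, wf, seed = seed)
  write_fixture(vid, dir, name)
}

test_that("discovery pairs stacks with sidecars and skips orphans", {
  dir <- withr::local_tempdir()
  for (i in 1:3) fx_write_recording(dir, paste0("rec", i), seed = i,
                                    n_frames = 40, n_beats = 0)
  file.remove(file.path(dir, "rec3.txt"))    # orphan tiff
  expect_warning(inputs <- discover_inputs(dir), "rec3")
  expect_equal(inputs$source_name, c("rec1", "rec2"))
  expect_equal(attr(inputs, "skipped"), "rec3")

  empty <- withr::local_tempdir()
  expect_warning(e <- discover_inputs(empty), "No TIFF")
  expect_equal(nrow(e), 0)
})

test_that("an empty folder yields an empty summary and no error log", {
  empty <- withr::local_tempdir(); out <- withr::local_tempdir()
  suppressWarnings(report <- run_batch(empty, out, fx_config("black_tip")))
  expect_equal(nrow(report), 0)
  summary <- readr::read_csv(file.path(out, "summary.csv"),
                             show_col_types = FALSE)
  expect_equal(nrow(summary), 0)
  expect_true("peak_force_un" %in% names(summary))
  expect_false(file.exists(file.path(out, "errors.txt")))
})

test_that("a batch isolates failures and reports them in errors.txt", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  for (i in 1:3) fx_write_recording(dir, paste0("rec", i), seed = i)
  # a corrupted stack must fail alone
  writeLines("garbage", file.path(dir, "broken.tif"))
  writeLines("FrameRate=100\nBinning=1", file.path(dir, "broken.txt"))

  report <- run_batch(dir, out, fx_config("black_tip"))
  expect_equal(attr(report, "n_succeeded"), 3)
  expect_equal(attr(report, "n_failed"), 1)
  summary <- readr::read_csv(file.path(out, "summary.csv"),
                             show_col_types = FALSE)
  expect_equal(nrow(summary), 3)
  expect_equal(summary$n_cycles, rep(3, 3))
  errs <- readLines(file.path(out, "errors.txt"))
  expect_length(errs, 1)
  expect_match(errs, "broken")
  # per-recording outputs: csvs and the four plots
  expect_true(all(file.exists(file.path(
    out, c("rec1_raw.csv", "rec1_cycles.csv", "rec1_displacement.png",
           "rec1_kinetics.png", "rec1_force.png", "rec1_stress.png")))))
})

test_that("a clean batch writes no errors.txt and is byte-reproducible", {
  dir <- withr::local_tempdir()
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  for (i in 1:2) fx_write_recording(dir, paste0("rec", i), seed = 10 + i)
  run_batch(dir, out1, fx_config("black_tip"))
  run_batch(dir, out2, fx_config("black_tip"))
  expect_false(file.exists(file.path(out1, "errors.txt")))
  for (f in c("summary.csv", "rec1_raw.csv", "rec1_cycles.csv")) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
})

test_that("manual-mode window overrides restrict the analyzed cycles", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  fx_write_recording(dir, "rec1", seed = 5, n_beats = 5, n_frames = 620)
  # beats at 0.5-5.5 s; a window over beats 2-4 leaves exactly 3 cycles
  ov <- list(rec1 = list(window = c(140, 470)))
  report <- run_batch(dir, out, fx_config("black_tip"), mode = "manual",
                      overrides = ov)
  expect_equal(attr(report, "n_failed"), 0)
  expect_equal(attr(report, "results")$rec1$cycles |> nrow(), 3)
  # overrides must reference existing recordings
  expect_error(run_batch(dir, out, fx_config("black_tip"), mode = "manual",
                         overrides = list(nope = list(window = c(1, 2)))),
               class = "eht_config_error")
})

test_that("explicit extremum overrides replace the detector's output", {
  wf <- generate_waveform(amplitude_um = 40, n_beats = 3, phase_offset_s = 0.5,
                          n_frames = 420)
  an <- analyze_trace(wf$trace, eht_config("black_tip"), frame_rate_fps = 100,
                      extrema_override = list(peaks = c(101, 201),
                                              troughs = c(51, 151, 251)))
  expect_equal(nrow(an$cycles), 2)
  expect_equal(an$cycles$peak_idx, c(101, 201))
})

test_that("per-recording writers preserve counts and never clobber", {
  wf <- generate_waveform(amplitude_um = 40, n_beats = 5, phase_offset_s = 0.5,
                          n_frames = 620)
  an <- analyze_trace(wf$trace, eht_config("black_tip"), frame_rate_fps = 100,
                      source_name = "demo")
  out <- withr::local_tempdir()
  write_file_results(an, out)
  cyc <- readr::read_csv(file.path(out, "demo_cycles.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(cyc), 5)
  # a second recording with the same stem gets a distinct name
  write_file_results(an, out)
  expect_true(file.exists(file.path(out, "demo_2_raw.csv")))

  # zero complete cycles: header-only cycle table, plots still produced
  an0 <- an
  an0$cycles <- an$cycles[0, ]
  an0$source_name <- "empty"
  files <- write_file_results(an0, out)
  cyc0 <- readr::read_csv(file.path(out, "empty_cycles.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(cyc0), 0)
  expect_length(files, 6)
  expect_true(all(file.exists(files)))
})

test_that("zero-beat recordings fail with the documented no-peaks error", {
  dir <- withr::local_tempdir()
  out <- withr::local_tempdir()
  sc <- fx_scene_blacktip()
  wf <- fx_static_waveform(sc, n_frames = 120)
  write_fixture(render_video(sc, wf, seed = 3), dir, "still")
  report <- run_batch(dir, out, fx_config("black_tip"))
  expect_equal(attr(report, "n_failed"), 1)
  expect_match(report$message[report$source_name == "still"], "No peaks")
  expect_equal(readLines(file.path(out, "errors.txt")), "still")
})
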