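#' Track the pillar centroids through a stack
#'
#' Runs the configured pillar detector on both halves of every frame and
#' builds the contraction waveform: the Euclidean distance between the two
#' centroids, calibrated to micrometres. In `mser` mode the tissue is also
#' segmented on every frame (the transparent-pillar workflow), yielding a
#' per-frame area column and a per-recording median area.
#'
#' A detection failure on any frame fails the whole recording (the error
#' names the frame and half); displacement is never interpolated across
#' missing detections.
#'
#' @param stack An `eht_stack`.
#' @param metadata An `eht_metadata` (pixel calibration and frame rate).
#' @param config An [eht_config()].
#' @param segment Whether to segment the tissue per frame; defaults to `TRUE`
#'   in `mser` mode (transparent pillars, where the tissue is visible) and
#'   `FALSE` in `black_tip` mode (the paper's high-illumination mode where
#'   only the tips are visible).
#' @return List of class `eht_tracking`: `trace` (tibble `frame`, `time_s`,
#'   `distance_px`, `distance_um`, `area_mm2`), `detections` (tibble of
#'   per-frame centroids), `area_mm2` (median tissue area or `NA`),
#'   `pixel_size_um`, `frame_rate_fps`.
#' @export
track_stack <- function(stack, metadata, config = eht_config(),
                        segment = config$mode == "mser") {
  stopifnot(inherits(stack, "eht_stack"), inherits(metadata, "eht_metadata"))
  px_um <- metadata$pixel_size_um

  rows <- vector("list", stack$n_frames)
  for (i in seq_len(stack$n_frames)) {
    frame <- get_frame(stack, i)
    dets <- tryCatch(
      detect_pillars(frame, config),
      eht_detection_error = function(e) {
        abort(sprintf("Frame %d: %s", i, conditionMessage(e)),
              class = "eht_detection_error")
      })
    area <- NA_real_
    if (segment) {
      tis <- tryCatch(
        segment_tissue(frame, dets, px_um, config$pillar_area_mm2),
        eht_segmentation_error = function(e) {
          abort(sprintf("Frame %d: %s", i, conditionMessage(e)),
                class = "eht_segmentation_error")
        })
      area <- tis$area_tissue_mm2
    }
    d_px <- sqrt(sum((dets$right$centroid - dets$left$centroid)^2))
    rows[[i]] <- tibble(
      frame = i,
      time_s = (i - 1) / metadata$frame_rate_fps,
      left_row = dets$left$centroid[1], left_col = dets$left$centroid[2],
      right_row = dets$right$centroid[1], right_col = dets$right$centroid[2],
      distance_px = d_px,
      distance_um = d_px * px_um,
      area_mm2 = area)
  }
  detections <- dplyr::bind_rows(rows)
  structure(list(
    trace = dplyr::select(detections, "frame", "time_s", "distance_px",
                          "distance_um", "area_mm2"),
    detections = detections,
    area_mm2 = if (segment) median(detections$area_mm2) else NA_real_,
    pixel_size_um = px_um,
    frame_rate_fps = metadata$frame_rate_fps),
    class = "eht_tracking")
}
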