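#' Segment the tissue and measure its surface area
#'
#' The whole frame is binarized with Otsu's threshold and inverted so the
#' (dark) tissue becomes foreground; the detected pillar regions are filled
#' into the foreground, interior holes (e.g. the bright interior of a
#' transparent pillar ring) are closed, and the 8-connected component that
#' contains both pillar centroids is kept as the tissue. Its pixel count is
#' converted to mm^2 via the pixel size, and the combined pillar footprint
#' (`pillar_area_mm2`, default 0.4 mm^2) is subtracted to obtain the
#' tissue-only area, floored at zero.
#'
#' @param frame Integer matrix of grey levels.
#' @param pillars A list with `left` and `right` detections in full-frame
#'   coordinates (see [detect_pillars()]).
#' @param pixel_size_um Pixel size in micrometres.
#' @param pillar_area_mm2 Combined pillar-tip footprint to subtract (mm^2).
#' @return List of class `eht_tissue`: `mask` (logical), `area_px2`,
#'   `area_total_mm2`, `area_tissue_mm2`, `pillar_area_mm2`.
#' @export
segment_tissue <- function(frame, pillars, pixel_size_um,
                           pillar_area_mm2 = 0.4) {
  bin <- otsu_binarize(frame)
  mask <- bin$mask  # inverted view: dark tissue is foreground
  for (det in pillars[c("left", "right")]) {
    mask[det$pixels] <- TRUE
  }
  mask <- fill_holes(mask)
  lab <- label_components(mask, conn = 8)

  label_at <- function(rc) {
    rr <- pmax(round(rc[1]) - 1, 1):pmin(round(rc[1]) + 1, nrow(lab))
    cc <- pmax(round(rc[2]) - 1, 1):pmin(round(rc[2]) + 1, ncol(lab))
    win <- lab[rr, cc]
    win <- win[win > 0]
    if (length(win) == 0) return(0L)
    as.integer(names(which.max(table(win))))
  }
  l_left <- label_at(pillars$left$centroid)
  l_right <- label_at(pillars$right$centroid)
  if (l_left == 0 || l_left != l_right) {
    abort("No segmented component touches both pillar centroids.",
          class = "eht_segmentation_error")
  }
  comp <- lab == l_left
  area_px2 <- sum(comp)
  area_total_mm2 <- area_px2 * (pixel_size_um / 1000)^2
  structure(list(mask = matrix(comp, nrow(frame), ncol(frame)),
                 area_px2 = area_px2,
                 area_total_mm2 = area_total_mm2,
                 area_tissue_mm2 = max(area_total_mm2 - pillar_area_mm2, 0),
                 pillar_area_mm2 = pillar_area_mm2),
            class = "eht_tissue")
}
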