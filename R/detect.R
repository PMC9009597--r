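#' Split a frame into left and right halves
#'
#' Each pillar is searched in its own half of the image: the frame is split
#' vertically at `floor(width / 2)`. Coordinates found in the right half must
#' be shifted by the returned `offset` to be expressed in full-frame columns.
#'
#' @param frame Integer matrix `[height, width]`, width >= 2.
#' @return List with `left`, `right` (matrices) and `offset` (columns to add
#'   to right-half coordinates).
#' @export
split_halves <- function(frame) {
  w <- ncol(frame)
  stopifnot(w >= 2)
  s <- floor(w / 2)
  list(left = frame[, seq_len(s), drop = FALSE],
       right = frame[, (s + 1):w, drop = FALSE],
       offset = s)
}

#' Otsu threshold of an 8-bit image
#'
#' Exhaustively maximizes the between-class variance
#' `w0 w1 (mu0 - mu1)^2` of the 256-bin intensity histogram over all split
#' points. The dark class is `intensity <= threshold`; ties are broken toward
#' the lowest threshold.
#'
#' @param img Integer matrix or vector of grey levels in 0-255.
#' @return Integer threshold in 0-254.
#' @export
otsu_threshold <- function(img) {
  v <- as.integer(img)
  if (any(v < 0 | v > 255)) {
    abort("otsu_threshold expects 8-bit grey levels (0-255).",
          class = "eht_input_error")
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- sum(counts)
  if (sum(counts > 0) < 2) {
    abort("Cannot threshold a constant image.",
          class = "eht_segmentation_error")
  }
  lev <- 0:255
  cw <- cumsum(counts)                    # pixels with level <= t
  cm <- cumsum(counts * lev)              # intensity mass with level <= t
  w0 <- cw[1:255] / n
  w1 <- 1 - w0
  mu0 <- cm[1:255] / pmax(cw[1:255], 1)
  mu1 <- (cm[256] - cm[1:255]) / pmax(n - cw[1:255], 1)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- -Inf
  as.integer(which.max(sigma_b) - 1L)
}

#' Binarize an image with Otsu's method
#'
#' @inheritParams otsu_threshold
#' @return List with `mask` (logical matrix, `TRUE` = dark class, i.e.
#'   `intensity <= threshold`) and `threshold`.
#' @export
otsu_binarize <- function(img) {
  t <- otsu_threshold(img)
  list(mask = matrix(img <= t, nrow(img), ncol(img)), threshold = t)
}

#' Label connected components
#'
#' @param mask Logical matrix.
#' @param conn Connectivity, 4 or 8 (default 8, the convention used for dark
#'   components throughout the pipeline).
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, conn = 8) {
  stopifnot(is.logical(mask), conn %in% c(4, 8))
  .label_cpp(mask, as.integer(conn))
}

# Fill holes: background (4-connected, complementary to 8-connected
# foreground) components that do not touch the image border become foreground.
fill_holes <- function(mask) {
  bg <- label_components(!mask, conn = 4)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  holes <- bg > 0 & !(bg %in% border)
  mask | matrix(holes, nrow(mask), ncol(mask))
}

#' Fill small dark artifacts
#'
#' Debris or dead cells sitting on the pillar tips appear as small dark
#' speckles that can distort region detection. Dark connected components
#' (8-connectivity, dark class from Otsu's threshold) with fewer than
#' `cutoff_px` pixels are replaced by the median intensity of their
#' immediately surrounding non-dark pixels; components at or above pillar
#' scale are untouched. Images with no dark/bright contrast are returned
#' unchanged.
#'
#' @param img Integer matrix of grey levels 0-255.
#' @param cutoff_px Area cutoff in pixels below which a dark component is
#'   considered an artifact.
#' @return Cleaned integer matrix.
#' @export
fill_dark_artifacts <- function(img, cutoff_px) {
  bin <- tryCatch(otsu_binarize(img), eht_segmentation_error = function(e) NULL)
  if (is.null(bin)) return(img)
  lab <- label_components(bin$mask, conn = 8)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < cutoff_px)
  if (length(small) == 0) return(img)
  out <- img
  h <- nrow(img); w <- ncol(img)
  global_bg <- median(img[!bin$mask])
  for (lb in small) {
    px <- which(lab == lb, arr.ind = TRUE)
    rr <- pmax(min(px[, 1]) - 1, 1):pmin(max(px[, 1]) + 1, h)
    cc <- pmax(min(px[, 2]) - 1, 1):pmin(max(px[, 2]) + 1, w)
    ring <- img[rr, cc][!bin$mask[rr, cc]]
    fill <- if (length(ring) > 0) median(ring) else global_bg
    out[px] <- as.integer(round(fill))
  }
  out
}

# Moments of a pixel set: centroid and eccentricity of the moment-equivalent
# ellipse (0 = circle, 1 = line).
region_moments <- function(px) {
  n <- nrow(px)
  cr <- mean(px[, 1]); cc <- mean(px[, 2])
  mrr <- mean(px[, 1]^2) - cr^2
  mcc <- mean(px[, 2]^2) - cc^2
  mrc <- mean(px[, 1] * px[, 2]) - cr * cc
  det <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + det) / 2
  l2 <- (mrr + mcc - det) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  list(centroid = c(cr, cc), eccentricity = ecc, area = n)
}

#' Detect a black-tip pillar in a half frame
#'
#' For carbon-black painted pillar tips: binarize the half with Otsu's
#' threshold, keep the largest dark 8-connected component, and return its
#' unweighted sub-pixel centroid.
#'
#' @param half Integer matrix (one half of a frame).
#' @param min_component_px Minimum admissible component area; smaller
#'   components (or none at all) raise a detection error.
#' @param which_half Label used in error messages (`"left"`/`"right"`).
#' @return List of class `eht_detection`: `centroid` (row, col), `area_px2`,
#'   `eccentricity`, `pixels` (n x 2 matrix of member pixels), `mode`.
#' @export
detect_black_tip <- function(half, min_component_px = 50,
                             which_half = "half") {
  bin <- tryCatch(otsu_binarize(half), eht_segmentation_error = function(e) {
    abort(paste0("No pillar tip found in ", which_half,
                 " half: image has no contrast."),
          class = "eht_detection_error")
  })
  lab <- label_components(bin$mask, conn = 8)
  if (max(lab) == 0) {
    abort(paste0("No dark component in ", which_half, " half."),
          class = "eht_detection_error")
  }
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_component_px) {
    abort(paste0("No dark component above ", min_component_px,
                 " px in ", which_half, " half."),
          class = "eht_detection_error")
  }
  px <- which(lab == best, arr.ind = TRUE)
  m <- region_moments(px)
  structure(list(centroid = m$centroid, area_px2 = m$area,
                 eccentricity = m$eccentricity, pixels = unname(px),
                 level = bin$threshold, mode = "black_tip"),
            class = "eht_detection")
}

#' Detect a transparent pillar tip by MSER
#'
#' For unpainted pillars: run maximally stable extremal region detection
#' (dark regions) on the artifact-filled half, fit the moment-equivalent
#' ellipse to every stable region, discard regions with eccentricity above
#' the cutoff or with an area outside the admissible range, and return the
#' centroid of the largest surviving region. The member pixel set is
#' recovered as the connected component of `intensity <= level` whose
#' centroid matches the selected region.
#'
#' @param half Integer matrix (one half of a frame).
#' @param config An [eht_config()]; uses the `mser_*`, `eccentricity_max` and
#'   `debris_frac` entries.
#' @param which_half Label used in error messages.
#' @return Same structure as [detect_black_tip()], with `mode = "mser"`.
#' @export
detect_mser_pillar <- function(half, config = eht_config("mser"),
                               which_half = "half") {
  a_half <- nrow(half) * ncol(half)
  min_area <- max(10L, as.integer(config$mser_area_min_frac * a_half))
  max_area <- as.integer(config$mser_area_max_frac * a_half)
  cleaned <- fill_dark_artifacts(half, cutoff_px = config$debris_frac * max_area)
  cand <- .mser_detect_cpp(cleaned, as.integer(config$mser_delta),
                           min_area, max_area, config$mser_max_variation)
  keep <- cand[, "eccentricity"] <= config$eccentricity_max
  if (!any(keep)) {
    abort(paste0("No MSER region passes the eccentricity filter in ",
                 which_half, " half: a centroid is not found."),
          class = "eht_detection_error")
  }
  cand <- cand[keep, , drop = FALSE]
  best <- cand[which.max(cand[, "area"]), ]

  mask <- cleaned <= best[["level"]]
  lab <- label_components(mask, conn = 8)
  labs <- seq_len(max(lab))
  ctr <- c(best[["row"]], best[["col"]])
  dists <- vapply(labs, function(lb) {
    px <- which(lab == lb, arr.ind = TRUE)
    sum((colMeans(px) - ctr)^2)
  }, numeric(1))
  px <- unname(which(lab == labs[which.min(dists)], arr.ind = TRUE))
  structure(list(centroid = ctr, area_px2 = best[["area"]],
                 eccentricity = best[["eccentricity"]], pixels = px,
                 level = best[["level"]], mode = "mser"),
            class = "eht_detection")
}

# shift a detection into full-frame coordinates
offset_detection <- function(det, col_offset) {
  det$centroid[2] <- det$centroid[2] + col_offset
  det$pixels[, 2] <- det$pixels[, 2] + col_offset
  det
}

#' Detect both pillars in one frame
#'
#' Applies the configured detector to each half and reports both detections
#' in full-frame coordinates, checking that the left centroid lies left of
#' the right one.
#'
#' @param frame Integer matrix.
#' @param config An [eht_config()].
#' @return List with `left`, `right` (detections, full-frame coordinates).
#' @export
detect_pillars <- function(frame, config = eht_config()) {
  hs <- split_halves(frame)
  detect1 <- function(img, which_half) {
    if (config$mode == "black_tip") {
      a_half <- nrow(img) * ncol(img)
      cleaned <- fill_dark_artifacts(
        img, cutoff_px = config$debris_frac * config$mser_area_max_frac * a_half)
      detect_black_tip(cleaned, config$min_component_px, which_half)
    } else {
      detect_mser_pillar(img, config, which_half)
    }
  }
  left <- detect1(hs$left, "left")
  right <- offset_detection(detect1(hs$right, "right"), hs$offset)
  if (!(left$centroid[2] < right$centroid[2])) {
    abort("Left centroid is not left of the right centroid.",
          class = "eht_detection_error")
  }
  list(left = left, right = right)
}
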