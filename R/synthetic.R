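#' Ground-truth beat waveform
#'
#' Builds a synthetic inter-pillar distance trace with analytically known
#' kinetics. Each beat is a raised-cosine excursion: within a beat of period
#' `period_s` starting at `t0`, the normalized contraction level is
#' `g(u) = (1 - cos(pi u / rf)) / 2` during the contraction phase
#' (`u = (t - t0)/T` in `[0, rf]`) and the mirrored cosine during relaxation,
#' so with `rise_fraction = 0.5` a full beat is the classic
#' `(1 - cos(2 pi t / T)) / 2` pulse. The distance trace is
#' `d(t) = baseline - amplitude * g(t)`.
#'
#' Because the beat shape is a closed form, the per-beat 10%/90% crossing
#' times are exact: the contraction level `p` is reached at
#' `u_p = (rf T / pi) * acos(1 - 2 p)` after the beat start, giving a
#' 10-to-90% contraction time of `(rf T / pi) * (acos(-0.8) - acos(0.8))`
#' (about 0.295 s for `T = 1 s`, `rf = 0.5`), and the peak contraction
#' velocity is `amplitude * pi / (2 rf T)`.
#'
#' @param baseline_distance_um Inter-centroid distance at full relaxation (um).
#' @param amplitude_um Peak inward excursion of the distance (um); must be
#'   smaller than the baseline.
#' @param period_s Beat period (s).
#' @param n_beats Number of beats.
#' @param rise_fraction Fraction of the period spent contracting, in (0, 1).
#' @param resting_tension_um Constant offset between the unloaded pillar
#'   spacing and the loaded relaxed baseline (um, >= 0). Carried as ground
#'   truth; the rendered distance is the loaded one.
#' @param phase_offset_s Start time of the first beat (s); values < 0 or beats
#'   running past the last frame produce truncated boundary beats.
#' @param frame_rate_fps Sampling rate.
#' @param n_frames Number of samples (>= 2).
#' @return An object of class `eht_waveform`: list with `trace` (tibble
#'   `frame`, `time_s`, `distance_um`), `beats` (tibble of per-beat ground
#'   truth: `start_s`, `peak_s`, `end_s`, `amplitude_um`, analytic
#'   `t_con_10_s`, `t_con_90_s`, `t_rel_10_s`, `t_rel_90_s`,
#'   `contraction_velocity_um_s`, `relaxation_velocity_um_s`, `complete`),
#'   and the generating parameters.
#' @export
#' @examples
#' wf <- generate_waveform(amplitude_um = 30, n_beats = 3, n_frames = 500)
#' wf$beats$t_con_90_s - wf$beats$t_con_10_s  # analytic 10-90% rise time
generate_waveform <- function(baseline_distance_um = 2000,
                              amplitude_um = 40,
                              period_s = 1,
                              n_beats = 5,
                              rise_fraction = 0.5,
                              resting_tension_um = 0,
                              phase_offset_s = 0.5,
                              frame_rate_fps = 100,
                              n_frames = 800) {
  if (amplitude_um >= baseline_distance_um) {
    abort("amplitude_um must be smaller than baseline_distance_um.",
          class = "eht_spec_error")
  }
  stopifnot(n_frames >= 2, frame_rate_fps > 0, period_s > 0, n_beats >= 0,
            rise_fraction > 0, rise_fraction < 1, resting_tension_um >= 0)

  t <- (seq_len(n_frames) - 1) / frame_rate_fps
  t_max <- t[length(t)]
  rf <- rise_fraction
  g <- numeric(n_frames)
  starts <- phase_offset_s + (seq_len(n_beats) - 1) * period_s
  for (t0 in starts) {
    u <- (t - t0) / period_s
    inb <- u >= 0 & u < 1
    gu <- numeric(sum(inb))
    uu <- u[inb]
    con <- uu <= rf
    gu[con] <- (1 - cos(pi * uu[con] / rf)) / 2
    gu[!con] <- (1 + cos(pi * (uu[!con] - rf) / (1 - rf))) / 2
    g[inb] <- pmax(g[inb], gu)
  }
  d <- baseline_distance_um - amplitude_um * g

  cross <- function(p) (rf * period_s / pi) * acos(1 - 2 * p)
  cross_rel <- function(p) ((1 - rf) * period_s / pi) * acos(1 - 2 * p)
  beats <- tibble(
    beat = seq_len(n_beats),
    start_s = starts,
    peak_s = starts + rf * period_s,
    end_s = starts + period_s,
    amplitude_um = amplitude_um,
    t_con_10_s = cross(0.1),
    t_con_90_s = cross(0.9),
    t_rel_10_s = cross_rel(0.1),
    t_rel_90_s = cross_rel(0.9),
    contraction_velocity_um_s = amplitude_um * pi / (2 * rf * period_s),
    relaxation_velocity_um_s = amplitude_um * pi / (2 * (1 - rf) * period_s),
    complete = starts > 0 & (starts + period_s) < t_max
  )

  structure(list(
    trace = tibble(frame = seq_len(n_frames), time_s = t, distance_um = d),
    beats = beats,
    baseline_distance_um = baseline_distance_um,
    amplitude_um = amplitude_um,
    period_s = period_s,
    rise_fraction = rise_fraction,
    resting_tension_um = resting_tension_um,
    unloaded_distance_um = baseline_distance_um + resting_tension_um,
    frame_rate_fps = frame_rate_fps
  ), class = "eht_waveform")
}

#' Synthetic bright-field scene description
#'
#' Describes the static geometry of a two-pillar EHT scene: two circular
#' pillar tips on a bright background with a darker tissue band spanning
#' between them. `black_tip` renders solid dark discs (carbon-black painted
#' tips under strong illumination, where the tissue is nearly invisible);
#' `transparent_ring` renders a dark annulus with a lighter interior, the
#' bright-field appearance of an unpainted PDMS pillar, with the tissue band
#' clearly visible.
#'
#' The analytic area of the union of the band rectangle and the two pillar
#' discs is the tissue-area ground truth (the pillar footprint is part of the
#' segmented region, exactly as in the real pipeline before the pillar-area
#' subtraction).
#'
#' @param image_size_px `(height, width)` in pixels.
#' @param pillar_radius_px Pillar tip (outer) radius in px.
#' @param pillar_centers_rest_px 2x2 matrix, rows `(row, col)` of the left and
#'   right pillar centers at rest; must lie in opposite horizontal halves.
#' @param pillar_style `"black_tip"` or `"transparent_ring"`.
#' @param band_half_height_px Half-height of the tissue band (0 disables the
#'   band).
#' @param ring_width_px Annulus thickness for the transparent style.
#' @param background_level,tissue_level,pillar_level,interior_level 8-bit grey
#'   levels of the scene components.
#' @param noise_sd Additive Gaussian intensity noise, in grey levels.
#' @param n_debris,debris_radius_px Number and radius of small dark speckles
#'   placed at random on the pillar tips (emulating debris or dead cells).
#' @param asymmetry Fraction of the total inward displacement taken by the
#'   left pillar (0.5 = symmetric motion).
#' @return A list of class `eht_scene`.
#' @export
scene_spec <- function(image_size_px = c(160, 360),
                       pillar_radius_px = 22,
                       pillar_centers_rest_px = NULL,
                       pillar_style = c("black_tip", "transparent_ring"),
                       band_half_height_px = 15,
                       ring_width_px = 7,
                       background_level = 210,
                       tissue_level = 110,
                       pillar_level = 30,
                       interior_level = 170,
                       noise_sd = 0,
                       n_debris = 0,
                       debris_radius_px = 2,
                       asymmetry = 0.5) {
  pillar_style <- match.arg(pillar_style)
  h <- image_size_px[1]; w <- image_size_px[2]
  if (is.null(pillar_centers_rest_px)) {
    pillar_centers_rest_px <- rbind(c(h / 2, w * 0.22), c(h / 2, w * 0.78))
  }
  cc <- pillar_centers_rest_px
  if (!(cc[1, 2] < w / 2 && cc[2, 2] > w / 2)) {
    abort("Pillar centers must lie in opposite horizontal halves.",
          class = "eht_spec_error")
  }
  structure(list(image_size_px = c(h, w),
                 pillar_radius_px = pillar_radius_px,
                 pillar_centers_rest_px = cc,
                 pillar_style = pillar_style,
                 band_half_height_px = band_half_height_px,
                 ring_width_px = ring_width_px,
                 background_level = background_level,
                 tissue_level = tissue_level,
                 pillar_level = pillar_level,
                 interior_level = interior_level,
                 noise_sd = noise_sd,
                 n_debris = n_debris,
                 debris_radius_px = debris_radius_px,
                 asymmetry = asymmetry),
            class = "eht_scene")
}

#' Analytic area of the band-plus-pillars union
#'
#' Area in px^2 of the union of the tissue band (rectangle of half-height `h`
#' spanning between the two pillar centers a distance `W` apart) and the two
#' pillar discs of radius `r`. Closed form: the part of each disc inside the
#' rectangle is `r^2 asin(h/r) + h sqrt(r^2 - h^2)` when `h < r` (the full
#' inner half-disc when `h >= r`), so the union is
#' `2 h W + 2 (pi r^2 - A_inside)`.
#'
#' @param scene An `eht_scene`.
#' @param distance_px Center-to-center pillar distance (px); defaults to the
#'   rest distance.
#' @return Area in px^2.
#' @export
scene_true_area_px2 <- function(scene, distance_px = NULL) {
  cc <- scene$pillar_centers_rest_px
  if (is.null(distance_px)) distance_px <- sqrt(sum((cc[2, ] - cc[1, ])^2))
  r <- scene$pillar_radius_px
  h <- scene$band_half_height_px
  if (h <= 0) return(2 * pi * r^2)
  a_in <- if (h >= r) pi * r^2 / 2 else r^2 * asin(h / r) + h * sqrt(r^2 - h^2)
  2 * h * distance_px + 2 * (pi * r^2 - a_in)
}

# coverage of a disc over pixel centers: smooth 1-px edge for sub-pixel truth
disc_cov <- function(rowg, colg, ctr, r) {
  d <- sqrt((rowg - ctr[1])^2 + (colg - ctr[2])^2)
  pmin(pmax(r + 0.5 - d, 0), 1)
}

#' Render a synthetic EHT video
#'
#' Turns a scene and a ground-truth waveform into a frame stack. Per frame,
#' both pillars move inward along the pillar axis by their share of the
#' instantaneous displacement `baseline - d(t)` (converted to px), the band
#' follows the pillars, debris speckles ride on the tips, and seeded Gaussian
#' noise is added. Edges are anti-aliased over one pixel so centroids have
#' sub-pixel ground truth.
#'
#' @param scene An [scene_spec()] object.
#' @param waveform An [generate_waveform()] object.
#' @param pixel_size_um Calibration used to convert the waveform (um) to px.
#' @param seed Integer seed for noise and debris placement.
#' @return List of class `eht_synthetic_video`: `stack` (an `eht_stack`),
#'   `truth` (tibble with per-frame true centroids, true distance in px and
#'   um, true union area in px^2), `scene`, `waveform`, `pixel_size_um`.
#' @export
render_video <- function(scene, waveform, pixel_size_um = 3.25, seed = 1L) {
  stopifnot(inherits(scene, "eht_scene"), inherits(waveform, "eht_waveform"))
  h <- scene$image_size_px[1]; w <- scene$image_size_px[2]
  r <- scene$pillar_radius_px
  cc <- scene$pillar_centers_rest_px
  n <- nrow(waveform$trace)
  d_um <- waveform$trace$distance_um
  disp_px <- (waveform$baseline_distance_um - d_um) / pixel_size_um

  axis <- (cc[2, ] - cc[1, ])
  axis <- axis / sqrt(sum(axis^2))
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)

  set.seed(seed)
  debris <- NULL
  if (scene$n_debris > 0) {
    # polar placement inside each tip, fixed to the tip frame of reference
    side <- sample(1:2, scene$n_debris, replace = TRUE)
    rad <- sqrt(stats::runif(scene$n_debris)) * (r - scene$debris_radius_px - 1)
    th <- stats::runif(scene$n_debris, 0, 2 * pi)
    debris <- cbind(side, rad * cos(th), rad * sin(th))
  }
  noise <- if (scene$noise_sd > 0) {
    matrix(stats::rnorm(as.double(n) * h * w, 0, scene$noise_sd), nrow = n)
  } else NULL

  arr <- array(0L, c(n, h, w))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    p1 <- cc[1, ] + scene$asymmetry * disp_px[i] * axis
    p2 <- cc[2, ] - (1 - scene$asymmetry) * disp_px[i] * axis
    if (p1[1] < r + 1 || p1[1] > h - r || p1[2] < r + 1 ||
        p2[1] < r + 1 || p2[1] > h - r || p2[2] > w - r) {
      abort("Pillar disc leaves the frame; shrink amplitude or enlarge image.",
            class = "eht_spec_error")
    }
    img <- matrix(scene$background_level, h, w)
    if (scene$band_half_height_px > 0) {
      bh <- scene$band_half_height_px
      x1 <- min(p1[2], p2[2]); x2 <- max(p1[2], p2[2])
      y0 <- (p1[1] + p2[1]) / 2
      covx <- pmin(pmax(pmin(colg + 0.5, x2) - pmax(colg - 0.5, x1), 0), 1)
      covy <- pmin(pmax(pmin(rowg + 0.5, y0 + bh) - pmax(rowg - 0.5, y0 - bh), 0), 1)
      cov <- covx * covy
      img <- img * (1 - cov) + scene$tissue_level * cov
    }
    for (p in list(p1, p2)) {
      if (scene$pillar_style == "black_tip") {
        cov <- disc_cov(rowg, colg, p, r)
        img <- img * (1 - cov) + scene$pillar_level * cov
      } else {
        cov_o <- disc_cov(rowg, colg, p, r)
        img <- img * (1 - cov_o) + scene$interior_level * cov_o
        cov_i <- disc_cov(rowg, colg, p, r - scene$ring_width_px)
        ring <- cov_o * (1 - cov_i)
        img <- img * (1 - ring) + scene$pillar_level * ring
      }
    }
    if (!is.null(debris)) {
      for (k in seq_len(nrow(debris))) {
        p <- if (debris[k, 1] == 1) p1 else p2
        ctr <- p + debris[k, 2:3]
        cov <- disc_cov(rowg, colg, ctr, scene$debris_radius_px)
        img <- img * (1 - cov) + 15 * cov
      }
    }
    if (!is.null(noise)) img <- img + matrix(noise[i, ], h, w)
    arr[i, , ] <- as.integer(pmin(pmax(round(img), 0), 255))
    dist_px <- sqrt(sum((p2 - p1)^2))
    truth[[i]] <- tibble(frame = i, time_s = waveform$trace$time_s[i],
                         left_row = p1[1], left_col = p1[2],
                         right_row = p2[1], right_col = p2[2],
                         distance_px = dist_px,
                         distance_um = dist_px * pixel_size_um,
                         area_px2 = scene_true_area_px2(scene, dist_px))
  }

  structure(list(stack = eht_stack(arr),
                 truth = dplyr::bind_rows(truth),
                 scene = scene,
                 waveform = waveform,
                 pixel_size_um = pixel_size_um,
                 seed = seed),
            class = "eht_synthetic_video")
}

#' Write a synthetic recording to disk as a fixture
#'
#' Emits the exact on-disk dialect the reader expects: `<name>.tif`
#' (multi-page 8-bit grayscale), `<name>.txt` (metadata sidecar) and
#' `<name>_truth.json` (ground truth: per-frame centroids/distance/area and
#' per-beat kinetics).
#'
#' @param video An [render_video()] result.
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @param binning,camera_pixel_um,magnification Metadata values to write; the
#'   defaults reproduce the `pixel_size_um` used at render time when it is
#'   3.25 um.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(video, dir, name, binning = 1,
                          camera_pixel_um = NULL, magnification = 2.0) {
  stopifnot(inherits(video, "eht_synthetic_video"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(camera_pixel_um)) {
    camera_pixel_um <- video$pixel_size_um * magnification / binning
  }
  tif <- file.path(dir, paste0(name, ".tif"))
  txt <- file.path(dir, paste0(name, ".txt"))
  jsn <- file.path(dir, paste0(name, "_truth.json"))
  write_stack(video$stack, tif)
  writeLines(c(sprintf("FrameRate=%g", video$waveform$frame_rate_fps),
               sprintf("Binning=%g", binning),
               sprintf("CameraPixelUm=%g", camera_pixel_um),
               sprintf("Magnification=%g", magnification)), txt)
  jsonlite::write_json(
    list(truth = video$truth,
         beats = video$waveform$beats,
         baseline_distance_um = video$waveform$baseline_distance_um,
         resting_tension_um = video$waveform$resting_tension_um,
         unloaded_distance_um = video$waveform$unloaded_distance_um,
         pixel_size_um = video$pixel_size_um),
    jsn, digits = NA, auto_unbox = TRUE)
  invisible(c(tif = tif, txt = txt, json = jsn))
}
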