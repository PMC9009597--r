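#' Parse an acquisition metadata text file
#'
#' Microscope exports carry a plain-text sidecar with the acquisition settings.
#' The parser accepts `Key=Value` and `Key: Value` lines with case-insensitive
#' keys and the common synonyms `FrameRate`/`fps` and `Binning`/`bin`. Frame
#' rate and binning are mandatory (they calibrate time and pixel size); the
#' sensor pixel pitch and magnification fall back to the configured defaults
#' when the file does not carry them.
#'
#' @param text Character scalar (file contents) or character vector of lines.
#' @param camera_pixel_um Default physical sensor pixel pitch (um).
#' @param magnification Default optical magnification.
#' @return A list of class `eht_metadata` with fields `frame_rate_fps`,
#'   `binning`, `camera_pixel_um`, `magnification`, and the derived
#'   `pixel_size_um = camera_pixel_um * binning / magnification` and
#'   `frame_interval_s = 1 / frame_rate_fps`.
#' @export
#' @examples
#' parse_metadata("FrameRate=100\nBinning=1")$pixel_size_um
parse_metadata <- function(text, camera_pixel_um = 6.5, magnification = 2.0) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\r?\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_ .-]+?)\\s*[=:]\\s*(.+)$", lines))
  kv <- kv[lengths(kv) == 3]
  keys <- tolower(gsub("[ _.-]", "", vapply(kv, `[`, "", 2)))
  vals <- vapply(kv, `[`, "", 3)

  lookup <- function(synonyms) {
    hit <- which(keys %in% synonyms)
    if (length(hit) == 0) return(NA_real_)
    suppressWarnings(as.numeric(vals[hit[1]]))
  }

  frame_rate <- lookup(c("framerate", "fps", "framespersecond"))
  binning <- lookup(c("binning", "bin"))
  if (is.na(frame_rate) || frame_rate <= 0) {
    abort("Metadata is missing a usable frame rate (key 'FrameRate' or 'fps').",
          class = "eht_metadata_error")
  }
  if (is.na(binning) || binning < 1) {
    abort("Metadata is missing a usable binning factor (key 'Binning' or 'bin').",
          class = "eht_metadata_error")
  }

  pitch <- lookup(c("camerapixelum", "pixelpitch", "pixelpitchum"))
  mag <- lookup(c("magnification", "mag"))
  if (is.na(pitch)) pitch <- camera_pixel_um
  if (is.na(mag)) mag <- magnification
  stopifnot(pitch > 0, mag > 0)

  structure(list(frame_rate_fps = frame_rate,
                 binning = as.integer(round(binning)),
                 camera_pixel_um = pitch,
                 magnification = mag,
                 pixel_size_um = pitch * round(binning) / mag,
                 frame_interval_s = 1 / frame_rate),
            class = "eht_metadata")
}

#' Read a metadata sidecar file from disk
#'
#' @param path Path to the text file.
#' @inheritParams parse_metadata
#' @return See [parse_metadata()].
#' @export
read_metadata <- function(path, camera_pixel_um = 6.5, magnification = 2.0) {
  if (!file.exists(path)) {
    abort(paste0("Metadata file not found: ", path), class = "eht_input_error")
  }
  parse_metadata(readLines(path, warn = FALSE), camera_pixel_um, magnification)
}
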