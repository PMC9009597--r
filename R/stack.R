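#' Frame stacks
#'
#' A frame stack is the in-memory form of a bright-field video: an integer
#' array indexed `[frame, row, col]` holding 8-bit grey levels (0-255).
#' `eht_stack()` validates and wraps an array; `load_stack()` reads a
#' multi-page TIFF; `write_stack()` writes one (used by the fixture
#' generator, and round-trips bit-identically for 8-bit data).
#'
#' @param frames Numeric or integer array `[n_frames, height, width]` of grey
#'   levels in 0-255.
#' @return An object of class `eht_stack`: a list with `frames`, `n_frames`,
#'   `height`, `width`.
#' @export
eht_stack <- function(frames) {
  if (length(dim(frames)) != 3) {
    abort("frames must be a 3-D array [frame, row, col].",
          class = "eht_input_error")
  }
  if (dim(frames)[1] < 2) {
    abort("A frame stack needs at least 2 frames.", class = "eht_input_error")
  }
  if (anyNA(frames) || any(!is.finite(frames)) || any(frames < 0)) {
    abort("Frame intensities must be finite and non-negative.",
          class = "eht_input_error")
  }
  storage.mode(frames) <- "integer"
  structure(list(frames = frames,
                 n_frames = dim(frames)[1],
                 height = dim(frames)[2],
                 width = dim(frames)[3]),
            class = "eht_stack")
}

#' @export
print.eht_stack <- function(x, ...) {
  cat(sprintf("<eht_stack> %d frames of %d x %d px (8-bit grey)\n",
              x$n_frames, x$height, x$width))
  invisible(x)
}

#' Extract one frame as a matrix
#'
#' @param stack An `eht_stack`.
#' @param i Frame index (1-based).
#' @return Integer matrix `[height, width]`.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "eht_stack"), i >= 1, i <= stack$n_frames)
  matrix(stack$frames[i, , ], stack$height, stack$width)
}

#' @rdname eht_stack
#' @param path Path to a multi-page grayscale TIFF (8- or 16-bit). Multi-channel
#'   pages are reduced to one channel by the luminance average. 16-bit data is
#'   rescaled to 8-bit grey levels.
#' @export
load_stack <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("TIFF not found: ", path), class = "eht_input_error")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) {
                      abort(paste0("Unreadable TIFF: ", path, " (",
                                   conditionMessage(e), ")"),
                            class = "eht_input_error")
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) {
    abort(paste0("TIFF has fewer than 2 pages: ", path),
          class = "eht_input_error")
  }
  to_grey <- function(p) {
    if (length(dim(p)) == 3) p <- apply(p, c(1, 2), mean)
    # readTIFF returns [0,1]; map back to 8-bit levels
    round(p * 255)
  }
  mats <- lapply(pages, to_grey)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All TIFF pages must share the same dimensions.",
          class = "eht_input_error")
  }
  arr <- array(0L, c(length(mats), dims[1, 1], dims[2, 1]))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  eht_stack(arr)
}

#' @rdname eht_stack
#' @param stack An `eht_stack` to write.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "eht_stack"))
  pages <- lapply(seq_len(stack$n_frames),
                  function(i) get_frame(stack, i) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}
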