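#' Discover recordings in a folder
#'
#' Pairs every multi-page TIFF in `input_dir` (flat scan, subfolders are not
#' descended) with the metadata text file sharing its stem. TIFFs without a
#' sidecar are skipped with a warning and reported in the batch counts.
#'
#' @param input_dir Directory to scan.
#' @return Tibble with `source_name`, `tiff`, `txt`, plus an attribute
#'   `skipped` (stems of unpaired TIFFs).
#' @export
discover_inputs <- function(input_dir) {
  if (!dir.exists(input_dir)) {
    abort(paste0("Input directory does not exist: ", input_dir),
          class = "eht_input_error")
  }
  tiffs <- list.files(input_dir, pattern = "\\.tiff?$", ignore.case = TRUE)
  if (length(tiffs) == 0) {
    warn(paste0("No TIFF files found in ", input_dir))
  }
  stems <- sub("\\.tiff?$", "", tiffs, ignore.case = TRUE)
  txts <- if (length(stems) > 0) {
    file.path(input_dir, paste0(stems, ".txt"))
  } else character(0)
  have_txt <- file.exists(txts)
  if (any(!have_txt)) {
    warn(paste0("Skipping TIFFs without a metadata sidecar: ",
                paste(stems[!have_txt], collapse = ", ")))
  }
  out <- tibble(source_name = stems[have_txt],
                tiff = file.path(input_dir, tiffs)[have_txt],
                txt = txts[have_txt])
  out <- dplyr::arrange(out, .data$source_name)
  attr(out, "skipped") <- stems[!have_txt]
  out
}

#' Analyze one recording end to end
#'
#' Loads the stack and metadata, tracks the pillars (and, in `mser` mode,
#' segments the tissue per frame), and runs the full waveform analysis. Any
#' stage error is rethrown as an `eht_file_error` carrying the stage name,
#' so a batch can record the failure and continue.
#'
#' @param tiff_path,txt_path Paths to the stack and its metadata sidecar.
#' @param config An [eht_config()].
#' @param source_name Recording identifier; defaults to the TIFF stem.
#' @param extrema_override Optional manual-mode override (see
#'   [analyze_trace()]).
#' @return An `eht_analysis`.
#' @export
analyze_file <- function(tiff_path, txt_path, config = eht_config(),
                         source_name = NULL, extrema_override = NULL) {
  if (is.null(source_name)) {
    source_name <- sub("\\.tiff?$", "", basename(tiff_path), ignore.case = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)),
            class = "eht_file_error")
    })
  }
  metadata <- stage("metadata", read_metadata(txt_path, config$camera_pixel_um,
                                              config$magnification))
  stack <- stage("load", load_stack(tiff_path))
  tracking <- stage("tracking", track_stack(stack, metadata, config))
  analysis <- stage("analysis", analyze_trace(
    tracking$trace, config,
    area_tissue_mm2 = tracking$area_mm2,
    frame_rate_fps = metadata$frame_rate_fps,
    pixel_size_um = metadata$pixel_size_um,
    extrema_override = extrema_override,
    source_name = source_name))
  analysis$tracking <- tracking
  analysis$metadata <- metadata
  analysis
}

#' Run a batch analysis over a folder
#'
#' Discovers paired TIFF + metadata recordings, analyzes each one (auto
#' mode, or manual mode with declarative per-file extremum/window overrides),
#' writes per-recording outputs, `summary.csv` and — only if something
#' failed — `errors.txt`. A failure in one recording never affects another;
#' results are ordered by recording name so the outputs are independent of
#' processing order.
#'
#' @param input_dir Folder with the recordings.
#' @param output_dir Folder for results (created if needed).
#' @param config An [eht_config()].
#' @param mode `"auto"` or `"manual"`. Manual mode reads `overrides`: a JSON
#'   file (or named list) mapping recording names to
#'   `{"peaks": [...], "troughs": [...]}` or `{"window": [first, last]}`.
#' @param overrides Path to a JSON overrides file, or an equivalent named
#'   list; only consulted in manual mode.
#' @return A tibble of class `eht_batch_report`: one row per discovered
#'   recording with `source_name`, `status` (`"ok"`/`"failed"`), `message`,
#'   `elapsed_s`; attributes `n_found`, `n_succeeded`, `n_failed`,
#'   `n_skipped` and `results` (the `eht_analysis` objects).
#' @export
run_batch <- function(input_dir, output_dir, config = eht_config(),
                      mode = c("auto", "manual"), overrides = NULL) {
  mode <- match.arg(mode)
  inputs <- discover_inputs(input_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) {
    abort(paste0("Cannot create output directory: ", output_dir),
          class = "eht_io_error")
  }
  ov <- list()
  if (mode == "manual" && !is.null(overrides)) {
    ov <- if (is.character(overrides)) {
      jsonlite::read_json(overrides, simplifyVector = TRUE)
    } else overrides
    missing_refs <- setdiff(names(ov), inputs$source_name)
    if (length(missing_refs) > 0) {
      abort(paste0("Overrides reference unknown recordings: ",
                   paste(missing_refs, collapse = ", ")),
            class = "eht_config_error")
    }
  }

  results <- list()
  status <- vector("list", nrow(inputs))
  for (i in seq_len(nrow(inputs))) {
    nm <- inputs$source_name[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      analyze_file(inputs$tiff[i], inputs$txt[i], config,
                   source_name = nm, extrema_override = ov[[nm]]),
      error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "eht_analysis")) {
      results[[nm]] <- res
      write_file_results(res, output_dir, stem = nm)
      status[[i]] <- tibble(source_name = nm, status = "ok",
                            message = NA_character_, elapsed_s = elapsed)
    } else {
      status[[i]] <- tibble(source_name = nm, status = "failed",
                            message = conditionMessage(res),
                            elapsed_s = elapsed)
    }
  }
  report <- dplyr::bind_rows(status)
  failed <- report$source_name[report$status == "failed"]
  write_batch_summary(results, failed, output_dir)

  structure(report,
            class = c("eht_batch_report", class(report)),
            n_found = nrow(inputs) + length(attr(inputs, "skipped")),
            n_skipped = length(attr(inputs, "skipped")),
            n_succeeded = sum(report$status == "ok"),
            n_failed = length(failed),
            results = results)
}

#' @export
print.eht_batch_report <- function(x, ...) {
  cat(sprintf("<eht_batch_report> %d found, %d analyzed, %d failed, %d skipped\n",
              attr(x, "n_found"), attr(x, "n_succeeded"),
              attr(x, "n_failed"), attr(x, "n_skipped")))
  NextMethod()
}
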