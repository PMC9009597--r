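# CSV/PNG writers for per-recording and batch results.

save_png <- function(plot, path, width = 900, height = 480) {
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

# distinct output stem: append _2, _3, ... when a previous recording in the
# same batch already claimed the name
unique_stem <- function(out_dir, stem) {
  candidate <- stem
  k <- 1
  while (file.exists(file.path(out_dir, paste0(candidate, "_raw.csv")))) {
    k <- k + 1
    candidate <- paste0(stem, "_", k)
  }
  candidate
}

#' Write per-recording results
#'
#' Emits `<stem>_raw.csv` (per-frame time, distance, displacement, smoothed
#' displacement, force, stress and tissue area), `<stem>_cycles.csv`
#' (per-cycle features; header-only when no complete cycle exists) and four
#' PNG plots (displacement with maxima/minima, contraction kinetics,
#' contraction force, force per surface area). Stems are de-duplicated
#' within a batch so two inputs sharing a name never clobber each other.
#'
#' @param analysis An `eht_analysis`.
#' @param out_dir Output directory (created if needed).
#' @param stem File stem; defaults to the recording's source name.
#' @return Invisibly, a character vector of the files written.
#' @export
write_file_results <- function(analysis, out_dir,
                               stem = analysis$source_name) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("Cannot create output directory: ", out_dir),
          class = "eht_io_error")
  }
  stem <- unique_stem(out_dir, stem)
  raw_path <- file.path(out_dir, paste0(stem, "_raw.csv"))
  cyc_path <- file.path(out_dir, paste0(stem, "_cycles.csv"))
  readr::write_csv(analysis$trace, raw_path)
  readr::write_csv(tidy(analysis), cyc_path)
  plots <- c(displacement = "displacement", kinetics = "kinetics",
             force = "force", stress = "stress")
  png_paths <- vapply(plots, function(tp) {
    p <- file.path(out_dir, paste0(stem, "_", tp, ".png"))
    save_png(autoplot(analysis, type = tp), p)
    p
  }, character(1))
  invisible(c(raw_path, cyc_path, png_paths))
}

#' Write the batch summary and error log
#'
#' `summary.csv` holds one row per successfully analyzed recording with the
#' per-recording mean values ([glance.eht_analysis()]). `errors.txt` lists
#' the recordings that failed, one name per line, and is only created when
#' at least one failure occurred.
#'
#' @param results List of `eht_analysis` objects (successes).
#' @param failures Character vector of failed source names (possibly with a
#'   reason after a tab).
#' @param out_dir Output directory.
#' @return Invisibly, the summary path.
#' @export
write_batch_summary <- function(results, failures, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_tbl <- if (length(results) > 0) {
    dplyr::bind_rows(lapply(results, glance))
  } else {
    glance(empty_analysis())[0, ]
  }
  summary_tbl <- dplyr::arrange(summary_tbl, .data$source_name)
  path <- file.path(out_dir, "summary.csv")
  readr::write_csv(summary_tbl, path)
  if (length(failures) > 0) {
    writeLines(failures, file.path(out_dir, "errors.txt"))
  }
  invisible(path)
}

# header template for an empty batch
empty_analysis <- function() {
  structure(list(
    trace = tibble(time_s = numeric(0)),
    cycles = tibble(amplitude_um = numeric(0), peak_force_un = numeric(0),
                    peak_stress_un_mm2 = numeric(0), t_con_10_s = numeric(0),
                    t_con_90_s = numeric(0), t_rel_10_s = numeric(0),
                    t_rel_90_s = numeric(0),
                    contraction_velocity_um_s = numeric(0),
                    relaxation_velocity_um_s = numeric(0),
                    period_s = numeric(0)),
    baseline_um = NA_real_, resting_tension_um = NA_real_,
    area_tissue_mm2 = NA_real_, source_name = NA_character_),
    class = "eht_analysis")
}
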