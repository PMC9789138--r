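#' Run the quantitative validation harness
#'
#' For every fixture the reference percentage of detached cell regions is
#' computed from the truth labels (detached / (attached + detached) labelled
#' pixels) and the automated percentage from the full pipeline (pixel
#' classification, cell-mask post-processing, detached-region extraction);
#' the absolute percentage error is their absolute difference. Fixtures
#' lacking one of the two label classes are flagged, excluded and reported
#' with a warning. The aggregate is mean +/- sample standard deviation.
#'
#' @param fixtures list of fixtures as from [generate_validation_set()]:
#'   each has `pair` and `labels` (0/1/2 = unlabelled/attached/detached).
#' @param model a trained [train_pixel_classifier()] model.
#' @param config a [segmentation_config()].
#' @param oracle if `TRUE`, the automated percentage is computed on the
#'   fixtures' own truth masks instead of the pipeline output (a
#'   self-consistency mode in which every error is exactly zero).
#' @return object of class `validation_report`: `per_image` data frame
#'   (`image_id`, `truth_pct`, `auto_pct`, `abs_error_pct`),
#'   `mean_error_pct`, `std_error_pct`, `regime`, `n`.
#' @export
run_validation <- function(fixtures, model = NULL,
                           config = segmentation_config(),
                           oracle = FALSE) {
  stopifnot(is.list(fixtures), length(fixtures) >= 1L)
  if (!oracle && !inherits(model, "pixel_model")) {
    stop("a trained pixel_model is required unless oracle = TRUE", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    lab <- fx$labels
    n_att <- sum(lab == 1L); n_det <- sum(lab == 2L)
    if (n_att == 0L || n_det == 0L) {
      warning(sprintf("fixture %d lacks one of the two label classes; excluded", i),
              call. = FALSE)
      next
    }
    truth_pct <- 100 * n_det / (n_att + n_det)
    auto_pct <- if (oracle) {
      percent_detached(fx$truth_detached, fx$truth_cell)
    } else {
      cm <- predict_cell_mask(model, fx$pair$phase,
                              source_frame = fx$pair$frame_index)
      cm <- postprocess_cell_mask(cm, config$cell_fill_hole_lt,
                                  config$cell_min_area)
      det <- extract_detached_regions(fx$pair, cm, config)
      percent_detached(det, cm)
    }
    if (is.na(auto_pct)) {
      warning(sprintf("fixture %d yielded no detected cell pixels; excluded", i),
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = i, truth_pct = truth_pct, auto_pct = auto_pct,
      abs_error_pct = absolute_error(truth_pct, auto_pct))
  }
  if (!length(rows)) stop("no usable fixtures", call. = FALSE)
  per_image <- do.call(rbind, rows)
  regime <- tryCatch(fixtures[[1]]$pair$meta$regime, error = function(e) NA)
  structure(list(per_image = per_image,
                 mean_error_pct = mean(per_image$abs_error_pct),
                 std_error_pct = stats::sd(per_image$abs_error_pct),
                 regime = if (is.null(regime)) NA_character_ else regime,
                 n = nrow(per_image)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s regime, n = %d: absolute error %.2f%% +/- %.2f\n",
              x$regime, x$n, x$mean_error_pct, x$std_error_pct))
  invisible(x)
}

#' Write / read a validation report (CSV)
#'
#' Only the per-image rows are stored; the aggregates are recomputed on
#' read, so stored and recomputed statistics cannot diverge.
#'
#' @param report a `validation_report`.
#' @param path CSV path.
#' @return `path` (write) or the reconstructed `validation_report` (read).
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  df <- report$per_image
  df$regime <- report$regime
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "truth_pct", "auto_pct", "abs_error_pct")
  if (!all(need %in% names(df))) {
    stop("not a validation report CSV: ", path, call. = FALSE)
  }
  structure(list(per_image = df[need],
                 mean_error_pct = mean(df$abs_error_pct),
                 std_error_pct = stats::sd(df$abs_error_pct),
                 regime = if ("regime" %in% names(df)) df$regime[1] else NA_character_,
                 n = nrow(df)),
            class = "validation_report")
}
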