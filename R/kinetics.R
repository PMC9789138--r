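#' Build the detachment profile of a time-lapse
#'
#' Runs cell segmentation, post-processing and detached-region extraction on
#' every frame in order and collects the per-frame features. Frames with zero
#' detected cell pixels yield a missing percentage; a failing frame is
#' recorded as missing (with a warning naming the frame) and does not abort
#' the run. No smoothing is applied.
#'
#' @param lapse a [time_lapse()].
#' @param model a trained [train_pixel_classifier()] model.
#' @param config a [segmentation_config()].
#' @param normalize `"auto"` (default: per-frame robust normalization for raw
#'   frames, none for frames already on the reconstructed scale),
#'   `"per_frame"`, `"global"` (percentiles pooled over the whole lapse, for
#'   profile stability), or `"none"`.
#' @param low,high normalization percentiles (fractions).
#' @return a `detachment_profile`: data frame with columns `frame_index`,
#'   `time_s`, `reference`, `cell_area_px`, `detached_area_px`,
#'   `percent_detached`, `mean_circularity`; the frame interval is attached
#'   as attribute `frame_interval_s`.
#' @export
build_profile <- function(lapse, model, config = segmentation_config(),
                          normalize = c("auto", "per_frame", "global", "none"),
                          low = 0.01, high = 0.99) {
  stopifnot(inherits(lapse, "time_lapse"), inherits(model, "pixel_model"))
  normalize <- match.arg(normalize)
  glob <- NULL
  if (normalize == "global") {
    ph <- unlist(lapply(lapse$frames, function(f) as.vector(f$phase)))
    it <- unlist(lapply(lapse$frames, function(f) as.vector(f$intensity)))
    glob <- list(phase = stats::quantile(ph, c(low, high), names = FALSE),
                 intensity = stats::quantile(it, c(low, high), names = FALSE))
  }
  rescale <- function(x, q) {
    if (q[2] <= q[1]) return(matrix(0, nrow(x), ncol(x)))
    pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
  }
  rows <- lapply(seq_along(lapse$frames), function(i) {
    pair <- lapse$frames[[i]]
    out <- data.frame(frame_index = pair$frame_index, time_s = pair$time_s,
                      reference = i <= lapse$reference_count,
                      cell_area_px = NA_integer_, detached_area_px = NA_integer_,
                      percent_detached = NA_real_, mean_circularity = NA_real_)
    tryCatch({
      pr <- switch(normalize,
        auto = if (pair$normalized) pair else normalize_pair(pair, low, high),
        per_frame = normalize_pair(pair, low, high),
        none = { pair$normalized <- TRUE; pair },
        global = {
          pair$phase <- rescale(pair$phase, glob$phase)
          pair$intensity <- rescale(pair$intensity, glob$intensity)
          pair$normalized <- TRUE
          pair
        })
      cm <- predict_cell_mask(model, pr$phase, source_frame = pr$frame_index)
      cm <- postprocess_cell_mask(cm, config$cell_fill_hole_lt,
                                  config$cell_min_area)
      det <- extract_detached_regions(pr, cm, config)
      ft <- frame_features(cm, det)
      out[names(ft)] <- ft
      out
    }, error = function(e) {
      warning(sprintf("frame %d failed and was recorded as missing: %s",
                      pair$frame_index, conditionMessage(e)), call. = FALSE)
      out
    })
  })
  prof <- do.call(rbind, rows)
  attr(prof, "frame_interval_s") <- lapse$frame_interval_s
  class(prof) <- c("detachment_profile", "data.frame")
  prof
}

#' Plot a detachment profile
#'
#' @param x a `detachment_profile`.
#' @param threshold_pct optional horizontal threshold line (default 92.5).
#' @param ... passed to [graphics::plot()].
#' @export
plot.detachment_profile <- function(x, threshold_pct = 92.5, ...) {
  graphics::plot(x$time_s / 60, x$percent_detached, type = "b", pch = 16,
                 xlab = "harvesting time (min)",
                 ylab = "detached cell regions (%)", ylim = c(0, 100), ...)
  graphics::abline(h = threshold_pct, lty = 2, col = "grey40")
  invisible(x)
}

#' Determine the enzymatic-inhibition time from a profile
#'
#' Scans the profile in time order and returns the time of the *first* point
#' whose detached percentage reaches the threshold (inclusive `>=`); missing
#' points are skipped; later dips below the threshold (a re-attachment phase)
#' do not change the result. If the threshold is never reached, the final
#' non-missing percentage is reported instead.
#'
#' @param profile a `detachment_profile` or a data frame with columns
#'   `time_s` and `percent_detached`.
#' @param threshold_pct percentage threshold (default 92.5).
#' @return an `inhibition_result` list: `reached`, `threshold_pct`, and
#'   either `inhibition_time_s` (reached) or `final_percent` (not reached).
#' @export
inhibition_time <- function(profile, threshold_pct = 92.5) {
  check_scalar(threshold_pct, 0, 100)
  stopifnot(is.data.frame(profile), nrow(profile) >= 1L,
            all(c("time_s", "percent_detached") %in% names(profile)))
  pct <- profile$percent_detached
  ok <- which(!is.na(pct))
  if (!length(ok)) {
    stop("all profile points are missing; inhibition time is undefined",
         call. = FALSE)
  }
  hit <- ok[pct[ok] >= threshold_pct]
  if (length(hit)) {
    structure(list(reached = TRUE,
                   inhibition_time_s = profile$time_s[hit[1L]],
                   threshold_pct = threshold_pct),
              class = "inhibition_result")
  } else {
    structure(list(reached = FALSE,
                   final_percent = pct[ok[length(ok)]],
                   threshold_pct = threshold_pct),
              class = "inhibition_result")
  }
}

#' @export
print.inhibition_result <- function(x, ...) {
  if (x$reached) {
    cat(sprintf("inhibition time: %.1f min (threshold %g%%)\n",
                x$inhibition_time_s / 60, x$threshold_pct))
  } else {
    cat(sprintf("threshold not reached (%.1f%%)\n", x$final_percent))
  }
  invisible(x)
}

#' Summarize inhibition results across donors and conditions
#'
#' Mirrors a heat-map layout: one row per (donor, condition) with the
#' inhibition time in minutes where the threshold was reached, otherwise the
#' final percentage.
#'
#' @param results data frame with columns `donor`, `condition`, `reached`,
#'   `inhibition_time_s`, `final_percent` (one row per result; the two value
#'   columns may be `NA` where not applicable).
#' @return list of class `condition_summary` with elements `long` (the long
#'   table with `inhibition_min` and `display`), `minutes` (donor x condition
#'   matrix of inhibition times in minutes, `NA` where unreached) and
#'   `labels` (donor x condition character matrix, e.g. `"10.0 min"` or
#'   `"88.0%"`).
#' @export
summarize_conditions <- function(results) {
  need <- c("donor", "condition", "reached", "inhibition_time_s", "final_percent")
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  if (!all(need %in% names(results))) {
    stop("results needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  key <- paste(results$donor, results$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (donor, condition) keys in results", call. = FALSE)
  }
  long <- results[need]
  long$inhibition_min <- ifelse(long$reached, long$inhibition_time_s / 60, NA_real_)
  long$display <- ifelse(long$reached,
                         sprintf("%.1f min", long$inhibition_min),
                         sprintf("%.1f%%", long$final_percent))
  donors <- unique(long$donor)
  conds <- unique(long$condition)
  minutes <- matrix(NA_real_, length(donors), length(conds),
                    dimnames = list(donors, conds))
  labels <- matrix(NA_character_, length(donors), length(conds),
                   dimnames = list(donors, conds))
  for (i in seq_len(nrow(long))) {
    d <- as.character(long$donor[i]); cn <- as.character(long$condition[i])
    minutes[d, cn] <- long$inhibition_min[i]
    labels[d, cn] <- long$display[i]
  }
  structure(list(long = long, minutes = minutes, labels = labels),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary>\n")
  print(x$labels)
  invisible(x)
}
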