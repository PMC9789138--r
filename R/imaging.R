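#' Construct a reconstructed phase/intensity image pair
#'
#' One frame of a lens-free time-lapse: the reconstructed phase image
#' (equivalent to phase contrast, where both attached and detached cells are
#' visible) and the reconstructed intensity image (equivalent to bright field,
#' where only detached cells appear as bright regions).
#'
#' @param phase,intensity numeric matrices of identical dimensions.
#' @param frame_index non-negative integer frame number.
#' @param frame_interval_s acquisition interval in seconds (default 20).
#' @param time_s seconds since the first acquisition; defaults to
#'   `frame_index * frame_interval_s` for a regular time-lapse.
#' @param meta free-form list of metadata (e.g. reconstruction method,
#'   iteration count, focus depth), carried as pass-through text.
#' @param normalized logical; `TRUE` when both images already live on the
#'   reconstructed \[0,1\] scale that the segmentation thresholds refer to.
#'   Images loaded from files are raw (`FALSE`) until [normalize_pair()] is
#'   applied; synthetic frames are generated on that scale directly.
#' @return an object of class `reconstructed_pair`.
#' @seealso [load_pair()], [normalize_pair()]
#' @export
reconstructed_pair <- function(phase, intensity, frame_index = 0L,
                               frame_interval_s = 20,
                               time_s = frame_index * frame_interval_s,
                               meta = list(), normalized = FALSE) {
  if (!is.matrix(phase) || !is.matrix(intensity)) {
    stop("phase and intensity must be 2-D matrices", call. = FALSE)
  }
  check_same_dim(phase, intensity, "phase and intensity")
  check_scalar(frame_index, 0)
  check_scalar(frame_interval_s, .Machine$double.eps)
  structure(
    list(phase = phase, intensity = intensity,
         frame_index = as.integer(frame_index), time_s = time_s,
         meta = meta, normalized = isTRUE(normalized)),
    class = "reconstructed_pair"
  )
}

#' @export
print.reconstructed_pair <- function(x, ...) {
  cat(sprintf("<reconstructed_pair> frame %d, t = %gs, %dx%d, %s\n",
              x$frame_index, x$time_s, nrow(x$phase), ncol(x$phase),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Read a single-channel grayscale image (TIFF or PNG)
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @return numeric matrix with values in \[0,1\] (integer data divided by the
#'   type maximum, as the underlying readers do).
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else {
      stop("multi-channel image not supported (expected single-channel grayscale): ",
           path, call. = FALSE)
    }
  }
  img
}

#' Write a grayscale image (TIFF or PNG)
#'
#' Values are clipped to \[0,1\] and quantized to the requested bit depth so
#' that integer imagery round-trips bit-exactly.
#'
#' @param img numeric matrix in \[0,1\].
#' @param path output path (`.tif`/`.tiff`/`.png`).
#' @param bits bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path, bits = 16L) {
  stopifnot(is.matrix(img), bits %in% c(8L, 16L))
  img <- pmin(pmax(img, 0), 1)
  mx <- 2^bits - 1
  img <- round(img * mx) / mx
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
    png = png::writePNG(img, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Load a phase/intensity pair from image files
#'
#' @inheritParams reconstructed_pair
#' @param phase_path,intensity_path image files of identical dimensions.
#' @return a raw (un-normalized) [reconstructed_pair()] with
#'   `time_s = frame_index * frame_interval_s`.
#' @export
load_pair <- function(phase_path, intensity_path, frame_index = 0L,
                      frame_interval_s = 20) {
  phase <- read_gray(phase_path)
  intensity <- read_gray(intensity_path)
  check_same_dim(phase, intensity, "phase and intensity")
  reconstructed_pair(phase, intensity, frame_index = frame_index,
                     frame_interval_s = frame_interval_s,
                     meta = list(phase_path = phase_path,
                                 intensity_path = intensity_path),
                     normalized = FALSE)
}

#' Robust percentile min-max normalization to \[0,1\]
#'
#' Maps the `low` percentile of the image to 0 and the `high` percentile to 1,
#' linearly in between, clipping outside. The defaults (1st/99th percentile)
#' make the mapping robust to isolated extreme pixels. A constant image maps
#' to all zeros.
#'
#' @param image numeric matrix.
#' @param low,high percentile bounds as fractions in \[0,1\], `high > low`.
#' @return numeric matrix with values in \[0,1\].
#' @export
normalize_image <- function(image, low = 0.01, high = 0.99) {
  if (!is.matrix(image) || length(image) == 0L) {
    stop("image must be a non-empty matrix", call. = FALSE)
  }
  check_scalar(low, 0, 1)
  check_scalar(high, 0, 1)
  if (high <= low) stop("high percentile must exceed low percentile", call. = FALSE)
  q <- stats::quantile(image, c(low, high), names = FALSE, type = 7)
  if (q[2] <= q[1]) return(matrix(0, nrow(image), ncol(image)))
  out <- (image - q[1]) / (q[2] - q[1])
  pmin(pmax(out, 0), 1)
}

#' Normalize both images of a pair
#'
#' @param pair a [reconstructed_pair()].
#' @inheritParams normalize_image
#' @return the pair with both channels normalized and `normalized = TRUE`.
#' @export
normalize_pair <- function(pair, low = 0.01, high = 0.99) {
  stopifnot(inherits(pair, "reconstructed_pair"))
  pair$phase <- normalize_image(pair$phase, low, high)
  pair$intensity <- normalize_image(pair$intensity, low, high)
  pair$normalized <- TRUE
  pair
}

#' Default acquisition crop window
#'
#' The fixed window used to trim the reconstructed full-sensor image to its
#' well-centred usable area, in 0-based half-open `[start, stop)` slice
#' notation, rows then columns.
#'
#' @return list with integer vectors `rows` and `cols`.
#' @export
default_crop_window <- function() {
  list(rows = c(836L, 2236L), cols = c(1198L, 2898L))
}

#' Crop an image by 0-based half-open index ranges
#'
#' Ranges follow slice convention: `rows = c(a, b)` keeps rows `a .. b-1`
#' (0-based), so the result has `b - a` rows. Pixel values are never altered.
#'
#' @param image numeric matrix.
#' @param rows,cols integer length-2 vectors `c(start, stop)`, 0-based,
#'   half-open; defaults are the full image.
#' @return the cropped matrix.
#' @export
crop_image <- function(image, rows = c(0L, nrow(image)),
                       cols = c(0L, ncol(image))) {
  stopifnot(is.matrix(image), length(rows) == 2L, length(cols) == 2L)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows[1] < 0L || cols[1] < 0L || rows[2] > nrow(image) ||
      cols[2] > ncol(image) || rows[1] >= rows[2] || cols[1] >= cols[2]) {
    stop(sprintf("crop window [%d:%d, %d:%d) out of bounds for %dx%d image",
                 rows[1], rows[2], cols[1], cols[2], nrow(image), ncol(image)),
         call. = FALSE)
  }
  image[(rows[1] + 1L):rows[2], (cols[1] + 1L):cols[2], drop = FALSE]
}

#' Extract seeded square validation crops around the image centre
#'
#' Draws `count` square crops whose centres are sampled uniformly from the
#' central region of the image (the middle half of each dimension, shrunk so
#' every crop fits). Deterministic for a fixed seed.
#'
#' @param image numeric matrix.
#' @param crop_size side length in pixels.
#' @param count number of crops.
#' @param seed integer seed.
#' @return list of `count` matrices of size `crop_size x crop_size`, with the
#'   sampled (row, col) centres attached as attribute `"centers"`.
#' @export
extract_validation_crops <- function(image, crop_size, count = 16L, seed = 1L) {
  stopifnot(is.matrix(image))
  check_scalar(crop_size, 1)
  check_scalar(count, 1)
  if (crop_size > nrow(image) || crop_size > ncol(image)) {
    stop("crop_size exceeds image dimensions", call. = FALSE)
  }
  half_lo <- (crop_size - 1L) %/% 2L
  half_hi <- crop_size - 1L - half_lo
  range_for <- function(n) {
    lo <- max(1L + half_lo, floor(n / 4))
    hi <- min(n - half_hi, ceiling(3 * n / 4))
    if (lo > hi) c(1L + half_lo, n - half_hi) else c(lo, hi)
  }
  rr <- range_for(nrow(image)); cr <- range_for(ncol(image))
  centers <- with_seed(seed, cbind(
    row = sample(seq.int(rr[1], rr[2]), count, replace = TRUE),
    col = sample(seq.int(cr[1], cr[2]), count, replace = TRUE)
  ))
  crops <- lapply(seq_len(count), function(i) {
    r0 <- centers[i, 1] - half_lo; c0 <- centers[i, 2] - half_lo
    image[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L), drop = FALSE]
  })
  attr(crops, "centers") <- centers
  crops
}

#' Assemble frames into a time-lapse
#'
#' @param frames list of [reconstructed_pair()] objects with strictly
#'   increasing `frame_index`.
#' @param frame_interval_s acquisition interval in seconds (default 20).
#' @param reference_count number of pre-enzyme reference frames at the start
#'   of the sequence (default 1); they are carried in the profile but can be
#'   flagged by downstream consumers.
#' @return an object of class `time_lapse`.
#' @export
time_lapse <- function(frames, frame_interval_s = 20, reference_count = 1L) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  ok <- vapply(frames, inherits, logical(1), "reconstructed_pair")
  if (!all(ok)) stop("all frames must be reconstructed_pair objects", call. = FALSE)
  check_scalar(frame_interval_s, .Machine$double.eps)
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (any(diff(idx) <= 0L)) {
    stop("frame_index must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 reference_count = as.integer(reference_count)),
            class = "time_lapse")
}

#' @export
print.time_lapse <- function(x, ...) {
  cat(sprintf("<time_lapse> %d frames, interval %gs, %d reference frame(s)\n",
              length(x$frames), x$frame_interval_s, x$reference_count))
  invisible(x)
}

#' @export
length.time_lapse <- function(x) length(x$frames)

#' Write a time-lapse manifest (CSV)
#'
#' The manifest is a plain-text table mapping `frame_index` to the phase and
#' intensity image paths and the acquisition time.
#'
#' @param manifest data frame with columns `frame_index`, `phase`,
#'   `intensity`, `time_s`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("frame_index", "phase", "intensity", "time_s")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(manifest[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time-lapse manifest (CSV)
#'
#' @param path manifest CSV written by [write_manifest()].
#' @return data frame with columns `frame_index`, `phase`, `intensity`,
#'   `time_s`, ordered by `frame_index`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "phase", "intensity", "time_s")
  if (!all(need %in% names(m))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  m[order(m$frame_index), need]
}

#' Load a full time-lapse from a manifest
#'
#' Relative image paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param frame_interval_s acquisition interval in seconds.
#' @param reference_count number of pre-enzyme reference frames.
#' @return a [time_lapse()] of raw pairs.
#' @export
load_time_lapse <- function(path, frame_interval_s = 20, reference_count = 1L) {
  m <- read_manifest(path)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  frames <- lapply(seq_len(nrow(m)), function(i) {
    pr <- load_pair(resolve(m$phase[i]), resolve(m$intensity[i]),
                    frame_index = m$frame_index[i],
                    frame_interval_s = frame_interval_s)
    pr$time_s <- m$time_s[i]
    pr
  })
  time_lapse(frames, frame_interval_s = frame_interval_s,
             reference_count = reference_count)
}
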