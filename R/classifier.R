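#' Train the random-forest pixel classifier
#'
#' Fits a probability random forest on the filter-bank responses of the
#' labelled pixels only. Label images use 0 = unlabelled, 1 = background,
#' 2 = cell; sparse (brush-style) annotation is expected. Training is
#' deterministic for a fixed seed.
#'
#' @param images list of normalized phase images (numeric matrices).
#' @param labels list of integer label matrices matching `images` in length
#'   and dimensions.
#' @param bank a [feature_bank()]; recorded in the model and reused verbatim
#'   at prediction time.
#' @param seed integer training seed, stored in the model.
#' @param num_trees number of trees (default 100).
#' @return an object of class `pixel_model`.
#' @export
train_pixel_classifier <- function(images, labels, bank = feature_bank(),
                                   seed = 1L, num_trees = 100L) {
  stopifnot(is.list(images), is.list(labels),
            length(images) == length(labels), length(images) >= 1L)
  classes <- c("background", "cell")
  feats <- list(); ys <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]; lab <- labels[[i]]
    check_same_dim(img, lab, "image and label image")
    if (!all(lab %in% 0:2)) {
      stop("label values must be 0 (unlabelled), 1 (background) or 2 (cell)",
           call. = FALSE)
    }
    sel <- which(lab > 0L)
    if (!length(sel)) next
    stack <- stack_to_matrix(compute_feature_stack(img, bank))
    feats[[length(feats) + 1L]] <- stack[sel, , drop = FALSE]
    ys[[length(ys) + 1L]] <- lab[sel]
  }
  if (!length(feats)) stop("no labelled pixels in the training set", call. = FALSE)
  X <- do.call(rbind, feats)
  y <- unlist(ys)
  for (k in 1:2) {
    if (!any(y == k)) {
      stop(sprintf("no labelled pixels for class '%s'", classes[k]), call. = FALSE)
    }
  }
  yf <- factor(classes[y], levels = classes)
  forest <- ranger::ranger(
    x = as.data.frame(X), y = yf,
    num.trees = num_trees, probability = TRUE,
    seed = as.integer(seed), num.threads = 1L,
    verbose = FALSE
  )
  structure(list(forest = forest, bank = bank, classes = classes,
                 training_seed = as.integer(seed),
                 num_trees = as.integer(num_trees),
                 version = 1L),
            class = "pixel_model")
}

#' @export
print.pixel_model <- function(x, ...) {
  cat(sprintf("<pixel_model> %d trees, %d channels, seed %d (OOB error %.4f)\n",
              x$num_trees, x$bank$n_channels, x$training_seed,
              x$forest$prediction.error))
  invisible(x)
}

#' Predict the raw cell mask of a phase image
#'
#' Per pixel, the class is the argmax of the forest's class probabilities
#' (equivalent to a 0.5 threshold for two classes; probability ties go to
#' background). The returned mask is the raw classifier output, *before*
#' [postprocess_cell_mask()].
#'
#' @param model a trained [train_pixel_classifier()] model.
#' @param phase normalized phase image (numeric matrix), on the same
#'   normalization convention as the training imagery.
#' @param source_frame frame index recorded on the mask.
#' @return an object of class `cell_mask` with elements `mask` (logical
#'   matrix) and `source_frame`.
#' @export
predict_cell_mask <- function(model, phase, source_frame = NA_integer_) {
  stopifnot(inherits(model, "pixel_model"), is.matrix(phase))
  stack <- stack_to_matrix(compute_feature_stack(phase, model$bank))
  pred <- stats::predict(model$forest, data = as.data.frame(stack),
                         num.threads = 1L, verbose = FALSE)
  p_cell <- pred$predictions[, "cell"]
  mask <- matrix(p_cell > 0.5, nrow(phase), ncol(phase))
  cell_mask(mask, source_frame = source_frame)
}

#' Construct a cell mask object
#'
#' @param mask logical matrix.
#' @param source_frame frame index the mask belongs to.
#' @return object of class `cell_mask`.
#' @export
cell_mask <- function(mask, source_frame = NA_integer_) {
  structure(list(mask = as_mask_matrix(mask),
                 source_frame = as.integer(source_frame)),
            class = "cell_mask")
}

#' Post-process a raw cell mask
#'
#' First fills enclosed background holes (4-connectivity) with area strictly
#' smaller than `fill_hole_lt`, then removes foreground objects
#' (8-connectivity) with area strictly smaller than `remove_object_lt` —
#' in exactly this order. The operation is idempotent.
#'
#' @param mask a `cell_mask` or logical matrix.
#' @param fill_hole_lt hole-area limit in pixels (default 200, strict `<`).
#' @param remove_object_lt object-area limit in pixels (default 50, strict `<`).
#' @return same type as the input.
#' @export
postprocess_cell_mask <- function(mask, fill_hole_lt = 200L,
                                  remove_object_lt = 50L) {
  obj <- inherits(mask, "cell_mask")
  m <- as_mask_matrix(mask)
  m <- fill_holes(m, max_area = fill_hole_lt, connectivity = 4L)
  m <- remove_small_objects(m, min_area = remove_object_lt, connectivity = 8L)
  if (obj) {
    mask$mask <- m
    mask
  } else {
    m
  }
}

#' Save / load a trained pixel model
#'
#' The archive stores the forest state, bank configuration, class order and
#' training seed under a versioned header.
#'
#' @param model a `pixel_model`.
#' @param path file path.
#' @return `path` (save) or the restored `pixel_model` (load).
#' @export
save_pixel_model <- function(model, path) {
  stopifnot(inherits(model, "pixel_model"))
  saveRDS(list(format = "detachmon_pixel_model", version = model$version,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_pixel_model
#' @export
load_pixel_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "detachmon_pixel_model")) {
    stop("not a detachmon pixel model archive: ", path, call. = FALSE)
  }
  structure(obj$model, class = "pixel_model")
}
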