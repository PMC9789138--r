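#' Label connected components of a binary mask
#'
#' Components are computed over the pixel adjacency graph (4- or
#' 8-connectivity) and relabelled in raster-scan order of their first pixel,
#' so labels are deterministic.
#'
#' @param mask logical matrix (or mask object).
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- as_mask_matrix(mask)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(out)
  id <- integer(nr * nc)
  id[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ef <- vector("list", length(offs)); et <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    ef[[k]] <- id[idx[ok]][keep]
    et[[k]] <- id[j][keep]
  }
  ef <- unlist(ef); et <- unlist(et)
  g <- igraph::make_graph(rbind(ef, et), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel by first occurrence in raster (column-major) pixel order
  relab <- integer(max(memb))
  first <- !duplicated(memb)
  relab[memb[first]] <- seq_len(sum(first))
  out[idx] <- relab[memb]
  out
}

#' Fill enclosed background holes below an area limit
#'
#' A hole is a connected background component (default 4-connectivity) that
#' does not touch the image border. Holes with area strictly smaller than
#' `max_area` become foreground; larger holes and border-touching background
#' are untouched. Foreground is never removed.
#'
#' @param mask logical matrix.
#' @param max_area fill holes with area `< max_area` (strict); `Inf` fills all.
#' @param connectivity background connectivity, 4 (default) or 8.
#' @return logical matrix.
#' @export
fill_holes <- function(mask, max_area = Inf, connectivity = 4L) {
  mask <- as_mask_matrix(mask)
  lab <- label_components(!mask, connectivity)
  if (max(lab) == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  sizes <- tabulate(lab, nbins = max(lab))
  fill <- setdiff(which(sizes < max_area), border)
  if (length(fill)) mask[lab %in% fill] <- TRUE
  mask
}

#' Remove foreground objects below an area limit
#'
#' Deletes every connected foreground component (default 8-connectivity) with
#' area strictly smaller than `min_area`.
#'
#' @param mask logical matrix.
#' @param min_area remove objects with area `< min_area` (strict).
#' @param connectivity 4 or 8 (default).
#' @return logical matrix.
#' @export
remove_small_objects <- function(mask, min_area, connectivity = 8L) {
  mask <- as_mask_matrix(mask)
  check_scalar(min_area, 0)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab, nbins = max(lab))
  drop <- which(sizes < min_area)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

# structuring element: Euclidean disk of given radius (pixels at distance <= r)
disk_kernel <- function(radius) {
  check_scalar(radius, 1)
  radius <- as.integer(radius)
  d <- seq.int(-radius, radius)
  k <- outer(d, d, function(y, x) (x^2 + y^2) <= radius^2)
  storage.mode(k) <- "double"
  k
}

#' Dilate a binary mask with a Euclidean disk
#'
#' The structuring element contains every pixel at Euclidean distance
#' `<= radius` from its centre. Pixels outside the image count as background
#' (zero padding), so structure never wraps around the border.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels.
#' @return logical matrix.
#' @export
dilate_disk <- function(mask, radius) {
  mask <- as_mask_matrix(mask)
  k <- disk_kernel(radius)
  r <- as.integer(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- mask
  conv <- EBImage::filter2(pad, k, boundary = "circular")
  out <- conv[(r + 1L):(r + nr), (r + 1L):(r + nc)] > 0.5
  out
}
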