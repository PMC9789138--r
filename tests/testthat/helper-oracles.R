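# Brute-force reference implementations of the morphological primitives,
# independent of the package's graph-based labeling and FFT-based dilation:
# labels spread by iterated min-propagation over shifted copies, dilation is
# an explicit offset-list OR.

shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- intersect(seq_len(nr), seq_len(nr) + dr)
  cs <- intersect(seq_len(nc), seq_len(nc) + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

oracle_label <- function(mask, conn = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  w <- matrix(Inf, nr, nc)
  w[mask] <- which(mask)  # unique provisional labels
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (conn == 8) {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  repeat {
    new <- w
    for (o in offs) new <- pmin(new, shift_mat(w, o[1], o[2], Inf))
    new[!mask] <- Inf
    if (identical(new, w)) break
    w <- new
  }
  lab <- matrix(0L, nr, nc)
  v <- w[mask]
  lab[mask] <- match(v, unique(v))  # canonical raster-first-occurrence order
  lab
}

oracle_fill_holes <- function(mask, max_area = Inf, conn = 4) {
  lab <- oracle_label(!mask, conn)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab, nbins = max(lab))
  for (k in seq_len(max(lab))) {
    if (!(k %in% border) && sizes[k] < max_area) mask[lab == k] <- TRUE
  }
  mask
}

oracle_remove_small <- function(mask, min_area, conn = 8) {
  lab <- oracle_label(mask, conn)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab, nbins = max(lab))
  for (k in seq_len(max(lab))) {
    if (sizes[k] < min_area) mask[lab == k] <- FALSE
  }
  mask
}

oracle_dilate_disk <- function(mask, radius) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr^2 + dc^2 <= radius^2) {
        out <- out | shift_mat(mask, dr, dc, FALSE)
      }
    }
  }
  out
}

# reference first-crossing scan for the inhibition rule, independent of the
# package implementation
scan_oracle <- function(pct, times, threshold) {
  for (i in seq_along(pct)) {
    if (!is.na(pct[i]) && pct[i] >= threshold) return(list(TRUE, times[i]))
  }
  last <- rev(pct[!is.na(pct)])
  list(FALSE, if (length(last)) last[1] else NA_real_)
}

# randomized binary masks mixing textures: bernoulli fields, blob/hole
# compositions, and sparse speckle
random_mask <- function(nr = 64, nc = 64) {
  kind <- sample(3, 1)
  if (kind == 1) {
    matrix(runif(nr * nc) < runif(1, 0.25, 0.65), nr, nc)
  } else if (kind == 2) {
    m <- matrix(FALSE, nr, nc)
    for (i in seq_len(sample(3:8, 1))) {
      r0 <- runif(1, 1, nr); c0 <- runif(1, 1, nc); rad <- runif(1, 3, 14)
      d2 <- outer(seq_len(nr) - r0, rep(1, nc))^2 +
            outer(rep(1, nr), seq_len(nc) - c0)^2
      m <- m | (d2 <= rad^2)
    }
    for (i in seq_len(sample(1:4, 1))) {
      r0 <- runif(1, 1, nr); c0 <- runif(1, 1, nc); rad <- runif(1, 2, 7)
      d2 <- outer(seq_len(nr) - r0, rep(1, nc))^2 +
            outer(rep(1, nr), seq_len(nc) - c0)^2
      m <- m & !(d2 <= rad^2)
    }
    m
  } else {
    m <- matrix(runif(nr * nc) < 0.05, nr, nc)
    r <- sample(4:12, 1)
    m[seq(10, 10 + r), seq(10, 10 + r)] <- TRUE
    m
  }
}
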