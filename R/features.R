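#' Multi-scale filter bank configuration for pixel classification
#'
#' The bank pairs six filter families (Gaussian smoothing, Laplacian of
#' Gaussian, Gaussian gradient magnitude, difference of Gaussians,
#' structure-tensor eigenvalues, Hessian-of-Gaussian eigenvalues) with six
#' smoothing scales, giving a 6 x 6 selection grid of 36 features. The two
#' eigenvalue families contribute two image channels each, so with the default
#' selection the classifier consumes 48 channels.
#'
#' @param sigmas strictly increasing positive smoothing scales in pixels.
#' @param families subset of
#'   `c("gaussian", "laplacian", "gradient", "dog", "structure", "hessian")`.
#' @return an object of class `feature_bank`.
#' @export
feature_bank <- function(sigmas = c(0.7, 1, 1.6, 3.5, 5, 10),
                         families = c("gaussian", "laplacian", "gradient",
                                      "dog", "structure", "hessian")) {
  families <- match.arg(families, several.ok = TRUE,
                        choices = c("gaussian", "laplacian", "gradient",
                                    "dog", "structure", "hessian"))
  if (!is.numeric(sigmas) || length(sigmas) == 0L || any(sigmas <= 0) ||
      any(diff(sigmas) <= 0)) {
    stop("sigmas must be strictly positive and strictly increasing", call. = FALSE)
  }
  per_family <- c(gaussian = 1L, laplacian = 1L, gradient = 1L, dog = 1L,
                  structure = 2L, hessian = 2L)
  structure(list(
    sigmas = sigmas,
    families = families,
    n_features = length(sigmas) * length(families),
    n_channels = length(sigmas) * sum(per_family[families])
  ), class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  cat(sprintf("<feature_bank> %d families x %d sigmas = %d features (%d channels)\n",
              length(x$families), length(x$sigmas), x$n_features, x$n_channels))
  invisible(x)
}

# 1-D sampled Gaussian kernel and its derivatives.
# order 0: normalized to unit sum; order 1: exact odd symmetry (zero sum);
# order 2: shifted to exact zero sum so flat fields give exactly zero response.
gauss_kernel_1d <- function(sigma, order = 0L) {
  r <- max(2L, ceiling(3.5 * sigma))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g,
    "2" = {
      h <- (x^2 / sigma^2 - 1) / sigma^2 * g
      h - mean(h)
    },
    stop("order must be 0, 1 or 2")
  )
}

# pad matrix by reflection (without repeating the edge sample)
reflect_pad <- function(img, pad) {
  nr <- nrow(img); nc <- ncol(img)
  if (pad >= nr || pad >= nc) stop("image too small for requested padding", call. = FALSE)
  ri <- c(rev(seq_len(pad) + 1L), seq_len(nr), nr - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1L), seq_len(nc), nc - seq_len(pad))
  img[ri, ci]
}

# separable convolution on an already padded canvas via FFT;
# ky filters rows (first index), kx filters columns
conv_sep_padded <- function(padded, ky, kx) {
  EBImage::filter2(padded, outer(ky, kx), boundary = "circular")
}

#' Compute the per-pixel feature stack
#'
#' Every channel is a linear or pointwise-combined filter response computed
#' with reflective boundary handling; the result is deterministic. Eigenvalue
#' channels are ordered largest first. The structure tensor uses the bank
#' sigma as gradient (inner) scale and half that sigma as tensor-smoothing
#' (outer) scale; the difference of Gaussians subtracts the response at
#' `0.66 * sigma` from the response at `sigma`.
#'
#' @param image numeric matrix (normalized phase image).
#' @param bank a [feature_bank()].
#' @return numeric array `nrow x ncol x n_channels` with channel names.
#' @export
compute_feature_stack <- function(image, bank = feature_bank()) {
  stopifnot(is.matrix(image))
  if (!inherits(bank, "feature_bank")) stop("bank must be a feature_bank", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  smax <- max(bank$sigmas)
  pad <- ceiling(3.5 * smax) + ceiling(3.5 * 0.5 * smax) + 2L
  P <- reflect_pad(image, pad)
  core_r <- (pad + 1L):(pad + nr)
  core_c <- (pad + 1L):(pad + nc)
  crop <- function(m) m[core_r, core_c]

  chans <- list()
  for (s in bank$sigmas) {
    g0 <- gauss_kernel_1d(s, 0L)
    g1 <- gauss_kernel_1d(s, 1L)
    g2 <- gauss_kernel_1d(s, 2L)
    sm <- NULL
    need_sm <- any(c("gaussian", "dog") %in% bank$families)
    if (need_sm) sm <- conv_sep_padded(P, g0, g0)
    if ("gaussian" %in% bank$families) {
      chans[[sprintf("gaussian_s%g", s)]] <- crop(sm)
    }
    if ("dog" %in% bank$families) {
      g0b <- gauss_kernel_1d(0.66 * s, 0L)
      chans[[sprintf("dog_s%g", s)]] <- crop(sm - conv_sep_padded(P, g0b, g0b))
    }
    need_hess <- any(c("laplacian", "hessian") %in% bank$families)
    if (need_hess) {
      hrr <- conv_sep_padded(P, g2, g0)   # second derivative along rows
      hcc <- conv_sep_padded(P, g0, g2)   # second derivative along columns
      if ("laplacian" %in% bank$families) {
        chans[[sprintf("laplacian_s%g", s)]] <- crop(hrr + hcc)
      }
      if ("hessian" %in% bank$families) {
        hrc <- conv_sep_padded(P, g1, g1)
        tr2 <- (hrr + hcc) / 2
        dt <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
        chans[[sprintf("hessian_e1_s%g", s)]] <- crop(tr2 + dt)
        chans[[sprintf("hessian_e2_s%g", s)]] <- crop(tr2 - dt)
      }
    }
    need_grad <- any(c("gradient", "structure") %in% bank$families)
    if (need_grad) {
      gr <- conv_sep_padded(P, g1, g0)    # derivative along rows
      gc <- conv_sep_padded(P, g0, g1)    # derivative along columns
      if ("gradient" %in% bank$families) {
        chans[[sprintf("gradient_s%g", s)]] <- crop(sqrt(gr^2 + gc^2))
      }
      if ("structure" %in% bank$families) {
        go <- gauss_kernel_1d(0.5 * s, 0L)
        srr <- conv_sep_padded(gr * gr, go, go)
        scc <- conv_sep_padded(gc * gc, go, go)
        src <- conv_sep_padded(gr * gc, go, go)
        tr2 <- (srr + scc) / 2
        dt <- sqrt(((srr - scc) / 2)^2 + src^2)
        chans[[sprintf("structure_e1_s%g", s)]] <- crop(tr2 + dt)
        chans[[sprintf("structure_e2_s%g", s)]] <- crop(tr2 - dt)
      }
    }
  }
  stack <- array(unlist(chans, use.names = FALSE),
                 dim = c(nr, nc, length(chans)),
                 dimnames = list(NULL, NULL, names(chans)))
  stack
}

# flatten a feature stack to a pixels x channels matrix
stack_to_matrix <- function(stack) {
  d <- dim(stack)
  m <- matrix(stack, nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- dimnames(stack)[[3]]
  m
}
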