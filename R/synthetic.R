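#' Detachment kinetics parameters
#'
#' Parametric model of enzymatic detachment with two hazard compartments
#' (fast / slow responders), an optional transient re-attachment window and a
#' never-detaching residual, reproducing the qualitative phases seen during
#' harvesting: a strong initial detachment phase, a short stationary or
#' re-attachment phase, a slower second response, and a plateau.
#'
#' Defaults are chosen so that an "average" culture crosses ~92% detachment
#' around 10 minutes: 75% fast responders at 0.01/s, slow responders at
#' 0.003/s, a re-attachment window in minutes 2–4 affecting 15% of the cells
#' that detach inside it, and a 97% plateau.
#'
#' @param n_cells number of cells.
#' @param fast_fraction fraction of fast responders in \[0,1\].
#' @param fast_rate,slow_rate exponential detachment hazards per second
#'   (`fast_rate >= slow_rate >= 0`).
#' @param reattach_window `c(start_s, end_s)` of the transient re-attachment
#'   phase.
#' @param reattach_prob probability that a cell detaching inside the window
#'   re-attaches.
#' @param plateau_pct percentage of cells that ever detach (the rest never
#'   do).
#' @param seed integer seed.
#' @return object of class `kinetics_params`.
#' @export
kinetics_params <- function(n_cells = 150L, fast_fraction = 0.75,
                            fast_rate = 0.01, slow_rate = 0.003,
                            reattach_window = c(120, 240),
                            reattach_prob = 0.15, plateau_pct = 97,
                            seed = 1L) {
  check_scalar(n_cells, 1)
  check_scalar(fast_fraction, 0, 1)
  check_scalar(fast_rate, 0)
  check_scalar(slow_rate, 0)
  if (fast_rate < slow_rate) stop("fast_rate must be >= slow_rate", call. = FALSE)
  check_scalar(reattach_prob, 0, 1)
  check_scalar(plateau_pct, 0, 100)
  if (length(reattach_window) != 2L || reattach_window[1] >= reattach_window[2]) {
    stop("reattach_window must be c(start, end) with start < end", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), fast_fraction = fast_fraction,
                 fast_rate = fast_rate, slow_rate = slow_rate,
                 reattach_window = reattach_window,
                 reattach_prob = reattach_prob, plateau_pct = plateau_pct,
                 seed = as.integer(seed)),
            class = "kinetics_params")
}

# exponential waiting time that tolerates a zero hazard
rexp0 <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

#' Simulate per-cell detachment state trajectories
#'
#' Each cell is a fast responder with probability `fast_fraction` and draws
#' its detachment time from an exponential with its compartment's hazard.
#' Cells detaching inside the re-attachment window re-attach with probability
#' `reattach_prob` (at a uniform time between detachment and the window end)
#' and later re-detach under the slow hazard. A `1 - plateau_pct/100`
#' fraction never detaches. Fully deterministic given the seed.
#'
#' @param params a [kinetics_params()].
#' @param frame_interval_s frame interval in seconds (default 20).
#' @param duration_s total duration in seconds (default 1200); frames are at
#'   `0, interval, ..., < duration`.
#' @return object of class `kinetics_sim`: list with `cells` (per-cell event
#'   table), `times`, `states` (cells x frames logical matrix, `TRUE` =
#'   detached) and `detached_fraction` per frame.
#' @export
simulate_kinetics <- function(params, frame_interval_s = 20,
                              duration_s = 1200) {
  stopifnot(inherits(params, "kinetics_params"))
  check_scalar(frame_interval_s, .Machine$double.eps)
  check_scalar(duration_s, frame_interval_s)
  n_frames <- max(1L, floor(duration_s / frame_interval_s + 1e-9))
  times <- seq(0, by = frame_interval_s, length.out = n_frames)
  n <- params$n_cells
  cells <- with_seed(params$seed, {
    never <- stats::runif(n) >= params$plateau_pct / 100
    fast <- stats::runif(n) < params$fast_fraction
    rate <- ifelse(fast, params$fast_rate, params$slow_rate)
    t_det <- vapply(rate, function(r) rexp0(1L, r), numeric(1))
    t_det[never] <- Inf
    w <- params$reattach_window
    in_win <- is.finite(t_det) & t_det >= w[1] & t_det <= w[2]
    reatt <- in_win & stats::runif(n) < params$reattach_prob
    t_re <- rep(Inf, n)
    t_re[reatt] <- stats::runif(sum(reatt), t_det[reatt], w[2])
    t_redet <- rep(Inf, n)
    t_redet[reatt] <- t_re[reatt] + rexp0(sum(reatt), params$slow_rate)
    data.frame(cell = seq_len(n), fast = fast, never = never,
               t_detach = t_det, reattaches = reatt,
               t_reattach = t_re, t_redetach = t_redet)
  })
  states <- vapply(times, function(t) {
    det <- t >= cells$t_detach
    re <- cells$reattaches & t >= cells$t_reattach & t < cells$t_redetach
    det & !re
  }, logical(n))
  states <- matrix(states, nrow = n, ncol = length(times))
  structure(list(cells = cells, times = times, states = states,
                 detached_fraction = colMeans(states), params = params),
            class = "kinetics_sim")
}

#' Rendering appearance parameters
#'
#' Pixel-value conventions of the synthetic reconstructed domain (all on the
#' \[0,1\] scale the segmentation thresholds refer to). Attached cells are
#' elongated mid-contrast blobs visible in the phase image only; detached
#' cells are round, carry a bright core in the phase image and a co-located
#' bright halo core in the intensity image. The 0.65 level set of a detached
#' cell's phase core sits about one dilation radius inside the cell rim
#' (`core = max(core_min_r, radius - core_inset)`), mirroring the real
#' imagery for which the pipeline's 5-px seeded dilation was calibrated.
#'
#' @param phase_bg,intensity_bg background levels.
#' @param attached_level_range attached-cell plateau range (uniform per cell).
#' @param cell_plateau in-cell plateau of detached cells in the phase image.
#' @param detached_peak,transition_peak phase core peak values.
#' @param halo_peak,transition_halo_peak intensity halo core peak values.
#' @param halo_base intensity base level inside a detached footprint.
#' @param core_min_r,core_inset bright-core geometry in pixels (see above).
#' @param blur_sigma Gaussian blur in pixels applied to the rendered frame.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @return list of class `render_params`.
#' @export
render_params <- function(phase_bg = 0.15, intensity_bg = 0.08,
                          attached_level_range = c(0.40, 0.52),
                          cell_plateau = 0.45,
                          detached_peak = 0.98, transition_peak = 0.80,
                          halo_peak = 0.90, transition_halo_peak = 0.55,
                          halo_base = 0.15,
                          core_min_r = 3.6, core_inset = 5,
                          blur_sigma = 1, noise_sd = 0.025) {
  structure(as.list(environment()), class = "render_params")
}

# cells per pixel for the three density regimes
regime_density <- function(regime) {
  switch(regime,
    medium = 0.00085,
    high = 0.0018,
    overconfluent = 0.0028,
    stop("unknown density regime: ", regime, call. = FALSE))
}

#' @rdname render_params
#' @param regime density regime.
#' @param canvas `c(rows, cols)` canvas size.
#' @return `regime_cell_count()`: integer number of cells for a canvas.
#' @export
regime_cell_count <- function(regime, canvas) {
  max(1L, round(regime_density(regime) * prod(canvas)))
}

# sample cell centres: minimum-distance darts for monolayers (medium/high),
# cluster process for overconfluent cultures (touching cells, clumps)
sample_positions <- function(n, canvas, regime) {
  h <- canvas[1]; w <- canvas[2]
  if (regime == "overconfluent") {
    k <- max(1L, ceiling(n / 4))
    cr <- stats::runif(k, 1, h); cc <- stats::runif(k, 1, w)
    g <- sample.int(k, n, replace = TRUE)
    pos <- cbind(row = pmin(pmax(cr[g] + stats::rnorm(n, 0, 12), 1), h),
                 col = pmin(pmax(cc[g] + stats::rnorm(n, 0, 12), 1), w))
    return(list(pos = pos, clump_id = g))
  }
  min_d <- if (regime == "medium") 16 else 10
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  got <- 0L
  tries <- 0L
  while (got < n && tries < n * 60L) {
    tries <- tries + 1L
    p <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    if (got == 0L ||
        min((pos[seq_len(got), 1] - p[1])^2 + (pos[seq_len(got), 2] - p[2])^2) >= min_d^2) {
      got <- got + 1L
      pos[got, ] <- p
    }
  }
  while (got < n) {  # density infeasible under the spacing: relax
    got <- got + 1L
    pos[got, ] <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
  }
  list(pos = pos, clump_id = rep(NA_integer_, n))
}

# sample cell geometry: per-cell attached (elongated) and detached (round)
# shape parameters; all randomness from the caller's seeded stream
sample_cell_geometry <- function(n, canvas, regime) {
  p <- sample_positions(n, canvas, regime)
  data.frame(
    cell = seq_len(n),
    row = p$pos[, 1], col = p$pos[, 2],
    att_major = stats::runif(n, 16, 24),
    att_minor = stats::runif(n, 4.5, 6.5),
    att_theta = stats::runif(n, 0, pi),
    det_major = stats::runif(n, 7, 10),
    det_ratio = stats::runif(n, 0.88, 1),
    att_level_u = stats::runif(n),
    clump_id = p$clump_id
  )
}

# per-frame view of the cells at given states ("attached"/"transitioning"/"detached")
cells_at_state <- function(geom, state) {
  det <- state != "attached"
  data.frame(
    cell = geom$cell,
    row = geom$row, col = geom$col,
    major = ifelse(det, geom$det_major, geom$att_major),
    minor = ifelse(det, geom$det_major * geom$det_ratio, geom$att_minor),
    orientation = ifelse(det, 0, geom$att_theta),
    state = state,
    att_level_u = geom$att_level_u,
    clump_id = geom$clump_id
  )
}

# gaussian blur with reflective boundaries
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- gauss_kernel_1d(sigma, 0L)
  pad <- (length(g) - 1L) %/% 2L
  P <- reflect_pad(img, pad)
  out <- conv_sep_padded(P, g, g)
  out[(pad + 1L):(pad + nrow(img)), (pad + 1L):(pad + ncol(img))]
}

#' Render one synthetic frame
#'
#' Rasterizes the cells onto a phase/intensity pair: attached cells as
#' elongated mid-contrast ellipses in the phase image only; detached (and
#' transitioning) cells as round regions with a bright phase core and a
#' co-located bright core ("halo") in the intensity image. The rendered
#' images are blurred and carry additive Gaussian noise; the returned ground
#' truth masks are exact (pre-blur) rasterizations. Deterministic for a
#' fixed seed.
#'
#' @param cells data frame with columns `row`, `col`, `major`, `minor`
#'   (semi-axes in pixels), `orientation` (radians), `state` (one of
#'   `"attached"`, `"transitioning"`, `"detached"`), and optionally
#'   `att_level_u` (per-cell brightness quantile) and `clump_id`.
#' @param canvas `c(rows, cols)`.
#' @param regime density regime label recorded in the frame metadata.
#' @param seed integer seed for the noise.
#' @param params a [render_params()].
#' @param frame_index,frame_interval_s frame bookkeeping for the pair.
#' @return list with `pair` (a normalized [reconstructed_pair()]),
#'   `truth_cell` and `truth_detached` (logical matrices).
#' @export
render_frame <- function(cells, canvas = c(301L, 301L), regime = "medium",
                         seed = 1L, params = render_params(),
                         frame_index = 0L, frame_interval_s = 20) {
  h <- as.integer(canvas[1]); w <- as.integer(canvas[2])
  if (nrow(cells) > 0 && prod(canvas) < 40 * nrow(cells)) {
    stop("requested cell density infeasible on this canvas", call. = FALSE)
  }
  phase <- matrix(params$phase_bg, h, w)
  intensity <- matrix(params$intensity_bg, h, w)
  truth_cell <- matrix(FALSE, h, w)
  truth_detached <- matrix(FALSE, h, w)

  n <- nrow(cells)
  for (i in seq_len(n)) {
    a <- cells$major[i]; b <- cells$minor[i]
    th <- cells$orientation[i]
    r0 <- cells$row[i]; c0 <- cells$col[i]
    ext <- ceiling(max(a, b)) + 1L
    rr <- max(1L, floor(r0 - ext)):min(h, ceiling(r0 + ext))
    cc <- max(1L, floor(c0 - ext)):min(w, ceiling(c0 + ext))
    if (!length(rr) || !length(cc)) next
    dr <- outer(rr - r0, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - c0)
    u <- (dr * cos(th) + dc * sin(th)) / a
    v <- (-dr * sin(th) + dc * cos(th)) / b
    inside <- (u^2 + v^2) <= 1
    if (!any(inside)) next
    st <- cells$state[i]
    truth_cell[rr, cc] <- truth_cell[rr, cc] | inside
    if (st == "attached") {
      lu <- if ("att_level_u" %in% names(cells)) cells$att_level_u[i] else stats::runif(1)
      lev <- params$attached_level_range[1] +
        lu * diff(params$attached_level_range)
      phase[rr, cc] <- pmax(phase[rr, cc], ifelse(inside, lev, -Inf))
    } else {
      truth_detached[rr, cc] <- truth_detached[rr, cc] | inside
      d2 <- dr^2 + dc^2
      core <- max(params$core_min_r, a - params$core_inset)
      peak <- if (st == "detached") params$detached_peak else params$transition_peak
      # phase core: plateau + Gaussian bump whose 0.65 level set has radius `core`
      s2 <- core^2 / (2 * log((peak - params$cell_plateau) /
                              (0.65 - params$cell_plateau)))
      val <- params$cell_plateau + (peak - params$cell_plateau) * exp(-d2 / (2 * s2))
      phase[rr, cc] <- pmax(phase[rr, cc], ifelse(inside, val, -Inf))
      # intensity halo core: 0.35 level set at the same radius
      hpeak <- if (st == "detached") params$halo_peak else params$transition_halo_peak
      si2 <- core^2 / (2 * log((hpeak - params$halo_base) /
                               (0.35 - params$halo_base)))
      hval <- params$halo_base + (hpeak - params$halo_base) * exp(-d2 / (2 * si2))
      intensity[rr, cc] <- pmax(intensity[rr, cc], ifelse(inside, hval, -Inf))
    }
  }
  phase <- blur_image(phase, params$blur_sigma)
  intensity <- blur_image(intensity, params$blur_sigma)
  with_seed(seed, {
    phase <- phase + stats::rnorm(length(phase), 0, params$noise_sd)
    intensity <- intensity + stats::rnorm(length(intensity), 0, params$noise_sd)
  })
  phase <- matrix(pmin(pmax(phase, 0), 1), h, w)
  intensity <- matrix(pmin(pmax(intensity, 0), 1), h, w)
  pair <- reconstructed_pair(phase, intensity, frame_index = frame_index,
                             frame_interval_s = frame_interval_s,
                             meta = list(regime = regime, synthetic = TRUE),
                             normalized = TRUE)
  list(pair = pair, truth_cell = truth_cell, truth_detached = truth_detached)
}

#' Simulate and render a full detachment time-lapse
#'
#' Combines [simulate_kinetics()] with [render_frame()]: cell positions and
#' geometries are sampled once, every frame renders the per-cell states at
#' that time (a newly detached cell spends its first frame in the
#' `"transitioning"` state), and exact truth masks are kept per frame.
#'
#' @param params a [kinetics_params()]; `n_cells` may be overridden by
#'   `n_cells`.
#' @param canvas `c(rows, cols)`.
#' @param regime density regime (`"medium"`, `"high"`, `"overconfluent"`).
#' @param frame_interval_s,duration_s time-lapse timing (defaults 20 s /
#'   1200 s).
#' @param n_cells number of cells; default derived from the regime density
#'   and the canvas.
#' @param render a [render_params()].
#' @return object of class `scene_series`: `frames` (list of normalized
#'   pairs), `truth_cell_masks`, `truth_detached_masks`, `truth_percent`
#'   (pixel-based, `NA` where no cell pixels), `sim`, `params`, `regime`,
#'   `frame_interval_s`.
#' @export
simulate_scene <- function(params = kinetics_params(), canvas = c(256L, 256L),
                           regime = "medium", frame_interval_s = 20,
                           duration_s = 1200,
                           n_cells = regime_cell_count(regime, canvas),
                           render = render_params()) {
  params$n_cells <- as.integer(n_cells)
  sim <- simulate_kinetics(params, frame_interval_s, duration_s)
  geom <- with_seed(params$seed + 1L, sample_cell_geometry(n_cells, canvas, regime))
  nT <- length(sim$times)
  frames <- vector("list", nT)
  tc <- vector("list", nT); td <- vector("list", nT)
  pct <- numeric(nT)
  for (j in seq_len(nT)) {
    det <- sim$states[, j]
    prev <- if (j == 1L) rep(FALSE, n_cells) else sim$states[, j - 1L]
    state <- ifelse(det & !prev, "transitioning",
                    ifelse(det, "detached", "attached"))
    fr <- render_frame(cells_at_state(geom, state), canvas, regime,
                       seed = params$seed + 7919L * j, params = render,
                       frame_index = j - 1L,
                       frame_interval_s = frame_interval_s)
    fr$pair$time_s <- sim$times[j]
    frames[[j]] <- fr$pair
    tc[[j]] <- fr$truth_cell
    td[[j]] <- fr$truth_detached
    pct[j] <- if (sum(fr$truth_cell) == 0L) NA_real_ else
      100 * sum(fr$truth_detached) / sum(fr$truth_cell)
  }
  structure(list(frames = frames, truth_cell_masks = tc,
                 truth_detached_masks = td, truth_percent = pct,
                 sim = sim, params = params, regime = regime,
                 frame_interval_s = frame_interval_s),
            class = "scene_series")
}

#' @export
print.scene_series <- function(x, ...) {
  cat(sprintf("<scene_series> %d frames, %s regime, %d cells, %dx%d\n",
              length(x$frames), x$regime, x$params$n_cells,
              nrow(x$frames[[1]]$phase), ncol(x$frames[[1]]$phase)))
  invisible(x)
}

#' Convert a synthetic scene to a time-lapse
#'
#' @param scene a [simulate_scene()] result.
#' @param reference_count pre-enzyme reference frames (default 0: the
#'   simulation starts at enzyme addition).
#' @return a [time_lapse()].
#' @export
scene_time_lapse <- function(scene, reference_count = 0L) {
  stopifnot(inherits(scene, "scene_series"))
  time_lapse(scene$frames, frame_interval_s = scene$frame_interval_s,
             reference_count = reference_count)
}

#' Ground-truth detachment profile of a scene
#'
#' The per-frame percentage of detached cell regions computed directly on the
#' scene's exact truth masks.
#'
#' @param scene a [simulate_scene()] result.
#' @return a `detachment_profile` data frame.
#' @export
profile_from_truth <- function(scene) {
  stopifnot(inherits(scene, "scene_series"))
  prof <- data.frame(
    frame_index = vapply(scene$frames, `[[`, integer(1), "frame_index"),
    time_s = vapply(scene$frames, `[[`, numeric(1), "time_s"),
    reference = FALSE,
    cell_area_px = vapply(scene$truth_cell_masks, sum, numeric(1)),
    detached_area_px = vapply(scene$truth_detached_masks, sum, numeric(1)),
    percent_detached = scene$truth_percent,
    mean_circularity = NA_real_
  )
  attr(prof, "frame_interval_s") <- scene$frame_interval_s
  class(prof) <- c("detachment_profile", "data.frame")
  prof
}

#' Generate a seeded synthetic validation set
#'
#' Emulates the quantitative-validation protocol: `count` square frames with
#' pixel-level ground-truth labels, at the regime's density and crop size
#' (401 px for the medium regime, 301 px for high and overconfluent). The
#' per-image detached cell fractions are spread over (0.05, 0.95) so the set
#' spans early to late harvesting. Deterministic for a fixed seed.
#'
#' @param regime `"medium"`, `"high"` or `"overconfluent"`.
#' @param count number of images (default 16).
#' @param crop_size square side in pixels; default by regime.
#' @param seed integer seed.
#' @param render a [render_params()].
#' @return list of `count` fixtures, each a list with `pair`, `labels`
#'   (0 = unlabelled, 1 = attached, 2 = detached), `truth_cell`,
#'   `truth_detached`, `truth_percent`.
#' @export
generate_validation_set <- function(regime = c("medium", "high", "overconfluent"),
                                    count = 16L,
                                    crop_size = NULL, seed = 7L,
                                    render = render_params()) {
  regime <- match.arg(regime)
  if (is.null(crop_size)) crop_size <- if (regime == "medium") 401L else 301L
  check_scalar(count, 1)
  canvas <- c(crop_size, crop_size)
  n <- regime_cell_count(regime, canvas)
  fracs <- with_seed(seed, sample(seq(0.05, 0.95, length.out = count)))
  lapply(seq_len(count), function(i) {
    si <- seed + 1000L * i
    geom <- with_seed(si, sample_cell_geometry(n, canvas, regime))
    det <- with_seed(si + 1L, stats::runif(n) < fracs[i])
    state <- ifelse(det, "detached", "attached")
    fr <- render_frame(cells_at_state(geom, state), canvas, regime,
                       seed = si + 2L, params = render, frame_index = i - 1L)
    labels <- matrix(0L, canvas[1], canvas[2])
    labels[fr$truth_cell] <- 1L
    labels[fr$truth_detached] <- 2L
    tp <- if (sum(fr$truth_cell) == 0L) NA_real_ else
      100 * sum(fr$truth_detached) / sum(fr$truth_cell)
    list(pair = fr$pair, labels = labels, truth_cell = fr$truth_cell,
         truth_detached = fr$truth_detached, truth_percent = tp)
  })
}

#' Generate a sparse-labelled synthetic training set
#'
#' Renders one or more frames per regime with roughly half the cells
#' detached and samples a fixed number of labelled pixels per class from the
#' exact ground truth, emulating brush-style sparse annotation
#' (0 = unlabelled, 1 = background, 2 = cell).
#'
#' @param regimes density regimes to draw training frames from.
#' @param images_per_regime frames per regime.
#' @param canvas square canvas side in pixels.
#' @param labels_per_class labelled pixels per class per frame.
#' @param seed integer seed.
#' @param render a [render_params()].
#' @return list with `images` (phase matrices) and `labels` (label matrices).
#' @export
synthetic_training_set <- function(regimes = c("medium", "high", "overconfluent"),
                                   images_per_regime = 1L, canvas = 301L,
                                   labels_per_class = 1500L, seed = 11L,
                                   render = render_params()) {
  images <- list(); labels <- list()
  k <- 0L
  for (rg in regimes) {
    for (j in seq_len(images_per_regime)) {
      k <- k + 1L
      si <- seed + 100L * k
      n <- regime_cell_count(rg, c(canvas, canvas))
      geom <- with_seed(si, sample_cell_geometry(n, c(canvas, canvas), rg))
      det <- with_seed(si + 1L, stats::runif(n) < 0.5)
      state <- ifelse(det, "detached", "attached")
      fr <- render_frame(cells_at_state(geom, state), c(canvas, canvas), rg,
                         seed = si + 2L, params = render)
      lab <- matrix(0L, canvas, canvas)
      bg <- which(!fr$truth_cell); fg <- which(fr$truth_cell)
      with_seed(si + 3L, {
        lab[sample(bg, min(labels_per_class, length(bg)))] <- 1L
        lab[sample(fg, min(labels_per_class, length(fg)))] <- 2L
      })
      images[[k]] <- fr$pair$phase
      labels[[k]] <- lab
    }
  }
  list(images = images, labels = labels)
}
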