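test_that("kinetics parameters are validated", {
  expect_error(kinetics_params(fast_rate = 0.001, slow_rate = 0.01), ">=")
  expect_error(kinetics_params(reattach_window = c(300, 100)), "start < end")
  expect_error(kinetics_params(plateau_pct = 150), "\\[0, 100\\]")
})

test_that("zero hazards keep every cell attached", {
  sim <- simulate_kinetics(kinetics_params(n_cells = 50, fast_rate = 0,
                                           slow_rate = 0, seed = 4))
  expect_false(any(sim$states))
  expect_equal(sim$detached_fraction, rep(0, length(sim$times)))
})

test_that("a single exponential compartment follows its closed form", {
  r <- 0.05
  sim <- simulate_kinetics(kinetics_params(n_cells = 1000, fast_fraction = 1,
                                           fast_rate = r, slow_rate = 0.003,
                                           reattach_prob = 0, plateau_pct = 100,
                                           seed = 12))
  expected <- 1 - exp(-r * sim$times)
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / 1000)
  expect_true(all(abs(sim$detached_fraction - expected) <= 3 * se + 1e-9))
})

test_that("re-attachment inside the window makes the curve dip", {
  sim <- simulate_kinetics(kinetics_params(n_cells = 500, fast_fraction = 1,
                                           fast_rate = 0.02, slow_rate = 0.001,
                                           reattach_window = c(100, 300),
                                           reattach_prob = 1, plateau_pct = 100,
                                           seed = 6))
  frac <- sim$detached_fraction
  win <- sim$times > 100 & sim$times <= 320
  expect_true(any(diff(frac[win]) < 0))
  # determinism
  sim2 <- simulate_kinetics(kinetics_params(n_cells = 500, fast_fraction = 1,
                                            fast_rate = 0.02, slow_rate = 0.001,
                                            reattach_window = c(100, 300),
                                            reattach_prob = 1, plateau_pct = 100,
                                            seed = 6))
  expect_identical(sim$states, sim2$states)
})

test_that("rendering honours states, truth masks and the appearance contract", {
  empty <- render_static_frame(0, 0, canvas = 96, seed = 31)
  expect_false(any(empty$truth_cell))
  expect_false(any(empty$truth_detached))
  expect_equal(dim(empty$pair$phase), c(96, 96))
  expect_true(empty$pair$normalized)
  expect_lt(max(empty$pair$intensity), 0.35)

  # one detached cell: exactly one bright intensity region, inside the truth
  one <- render_static_frame(1, 1, canvas = 96, seed = 32)
  bright <- threshold_mask(one$pair$intensity, 0.35)
  expect_true(all(one$truth_detached[bright]))
  expect_equal(max(label_components(bright, 8L)), 1)
  # detached cells are rendered round
  px <- which(one$truth_detached, arr.ind = TRUE)
  expect_lte(diff(range(px[, 1])) / diff(range(px[, 2])), 1.35)
  expect_gte(diff(range(px[, 1])) / diff(range(px[, 2])), 1 / 1.35)

  # attached cells are elongated and dark in the intensity image
  att <- render_static_frame(1, 0, canvas = 96, seed = 33)
  expect_false(any(att$truth_detached))
  expect_false(any(threshold_mask(att$pair$intensity, 0.35)))

  # appearance contract: detached regions are brighter in the intensity image
  mix <- render_static_frame(24, 0.5, canvas = 160, seed = 34)
  m_det <- mean(mix$pair$intensity[mix$truth_detached])
  m_att <- mean(mix$pair$intensity[mix$truth_cell & !mix$truth_detached])
  expect_gt(m_det, m_att + 0.15)
  # truth partition by construction
  expect_true(all(mix$truth_detached <= mix$truth_cell))

  expect_error(render_frame(data.frame(row = 1, col = 1, major = 2, minor = 2,
                                       orientation = 0, state = "detached")[rep(1, 50), ],
                            canvas = c(20, 20)), "infeasible")
})

test_that("scenes are seeded, reproducible and internally consistent", {
  p <- kinetics_params(n_cells = 20, seed = 9)
  s1 <- simulate_scene(p, canvas = c(96L, 96L), duration_s = 80, n_cells = 20)
  s2 <- simulate_scene(p, canvas = c(96L, 96L), duration_s = 80, n_cells = 20)
  expect_identical(s1$frames[[3]]$phase, s2$frames[[3]]$phase)
  expect_identical(s1$truth_detached_masks, s2$truth_detached_masks)
  for (j in seq_along(s1$frames)) {
    expect_true(all(s1$truth_detached_masks[[j]] <= s1$truth_cell_masks[[j]]))
  }
  # rendered intensity responds to the truth state over time
  expect_equal(length(s1$frames), 4)
})

test_that("validation sets are deterministic and span the detachment range", {
  fx <- generate_validation_set("medium", count = 16, seed = 7)
  expect_length(fx, 16)
  expect_true(all(vapply(fx, function(f) all(dim(f$pair$phase) == c(401, 401)),
                         logical(1))))
  tp <- vapply(fx, `[[`, numeric(1), "truth_percent")
  expect_lte(min(tp), 10)
  expect_gte(max(tp), 90)
  # labels agree with the truth masks
  f1 <- fx[[1]]
  expect_identical(f1$labels == 2L, f1$truth_detached)
  expect_identical(f1$labels > 0L, f1$truth_cell)

  fx2 <- generate_validation_set("medium", count = 16, seed = 7)
  expect_identical(fx2[[5]]$pair$intensity, fx[[5]]$pair$intensity)
  expect_identical(fx2[[5]]$labels, fx[[5]]$labels)

  fx301 <- generate_validation_set("overconfluent", count = 2, seed = 3)
  expect_true(all(dim(fx301[[1]]$pair$phase) == c(301, 301)))
  # overconfluent scenes carry clump structure
  expect_true(any(!is.na(detachmon:::sample_cell_geometry(
    50, c(301, 301), "overconfluent")$clump_id)))
})
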