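mk_profile <- function(pct, interval = 20) {
  data.frame(frame_index = seq_along(pct) - 1L,
             time_s = (seq_along(pct) - 1L) * interval,
             percent_detached = pct)
}

test_that("inhibition time is the first inclusive crossing", {
  pct <- c(seq(5, 90, length.out = 30), rep(95, 11))
  prof <- mk_profile(pct)  # first >= 92.5 at frame 30
  res <- inhibition_time(prof)
  expect_true(res$reached)
  expect_equal(res$inhibition_time_s, 600)
  expect_equal(res$threshold_pct, 92.5)

  # plateau below threshold: final percentage is reported instead
  res88 <- inhibition_time(mk_profile(c(seq(10, 88, length.out = 40), 88)))
  expect_false(res88$reached)
  expect_equal(res88$final_percent, 88)
  expect_null(res88$inhibition_time_s)

  # a re-attachment dip after the first crossing is ignored
  dip <- mk_profile(c(50, 80, 93, 85, 70, 94, 95))
  expect_equal(inhibition_time(dip)$inhibition_time_s, 2 * 20)

  # missing points are skipped
  gaps <- mk_profile(c(NA, 50, NA, 93, NA, 95))
  expect_equal(inhibition_time(gaps)$inhibition_time_s, 3 * 20)
  expect_error(inhibition_time(mk_profile(c(NA, NA))), "undefined")
  expect_error(inhibition_time(mk_profile(c(1, 2)), threshold_pct = 150),
               "\\[0, 100\\]")
})

test_that("inhibition time matches the scan oracle and is threshold-monotone", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    pct <- pmin(pmax(cumsum(rnorm(n, 3, 8)), 0), 100)
    pct[sample(n, sample(0:3, 1))] <- NA
    prof <- mk_profile(pct)
    th <- runif(1, 0, 100)
    if (all(is.na(pct))) next
    ref <- scan_oracle(pct, prof$time_s, th)
    res <- inhibition_time(prof, th)
    expect_identical(res$reached, ref[[1]])
    if (ref[[1]]) expect_equal(res$inhibition_time_s, ref[[2]])
    else expect_equal(res$final_percent, ref[[2]])

    # monotone in the threshold; threshold 0 gives the first non-missing point
    lo <- inhibition_time(prof, 0)
    expect_equal(lo$inhibition_time_s, prof$time_s[which(!is.na(pct))[1]])
    hi <- inhibition_time(prof, min(th + 20, 100))
    if (hi$reached) expect_gte(hi$inhibition_time_s, res$inhibition_time_s)
  }
})

test_that("profiles are built per frame and commute with subsetting", {
  model <- cached_model()
  scene <- simulate_scene(kinetics_params(fast_rate = 0.02, seed = 2),
                          canvas = c(128L, 128L), regime = "medium",
                          duration_s = 120)  # 6 frames
  lapse <- scene_time_lapse(scene)
  prof <- build_profile(lapse, model)
  expect_s3_class(prof, "detachment_profile")
  expect_equal(nrow(prof), 6)
  expect_equal(prof$time_s, seq(0, 100, by = 20))
  expect_false(any(is.na(prof$percent_detached)))

  sub <- time_lapse(lapse$frames[1:4], frame_interval_s = 20)
  prof_sub <- build_profile(sub, model)
  expect_equal(prof_sub$percent_detached, prof$percent_detached[1:4])

  # ground-truth profile equals the generator's per-frame detached fraction
  truth <- profile_from_truth(scene)
  expect_identical(truth$percent_detached, scene$truth_percent)
  for (j in seq_along(scene$frames)) {
    expect_equal(truth$percent_detached[j],
                 percent_detached(scene$truth_detached_masks[[j]],
                                  scene$truth_cell_masks[[j]]))
  }
})

test_that("a background-only lapse yields all-missing points", {
  model <- cached_model()
  scene <- simulate_scene(kinetics_params(seed = 3), canvas = c(96L, 96L),
                          regime = "medium", duration_s = 60, n_cells = 0)
  prof <- suppressWarnings(build_profile(scene_time_lapse(scene), model))
  expect_true(all(is.na(prof$percent_detached)))
  expect_error(inhibition_time(prof), "undefined")
})

test_that("condition summaries convert units and reject duplicates", {
  res <- data.frame(donor = c("d1", "d1", "d2"),
                    condition = c("day3", "day5", "day3"),
                    reached = c(TRUE, FALSE, TRUE),
                    inhibition_time_s = c(600, NA, 780),
                    final_percent = c(NA, 88, NA))
  s <- summarize_conditions(res)
  expect_equal(s$minutes["d1", "day3"], 10)
  expect_equal(s$minutes["d2", "day3"], 13)
  expect_true(is.na(s$minutes["d1", "day5"]))
  expect_equal(s$labels["d1", "day5"], "88.0%")
  expect_equal(s$labels["d1", "day3"], "10.0 min")

  dup <- rbind(res, res[1, ])
  expect_error(summarize_conditions(dup), "duplicate")

  # a 7 x 5 grid round-trips through CSV unchanged
  grid <- expand.grid(donor = paste0("d", 1:7), condition = paste0("c", 1:5),
                      stringsAsFactors = FALSE)
  set.seed(8)
  grid$reached <- runif(35) < 0.7
  grid$inhibition_time_s <- ifelse(grid$reached, sample(seq(120, 1180, 20), 35, TRUE), NA)
  grid$final_percent <- ifelse(grid$reached, NA, round(runif(35, 60, 92), 1))
  s2 <- summarize_conditions(grid)
  f <- tempfile(fileext = ".csv")
  write.csv(s2$long, f, row.names = FALSE)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$inhibition_min, s2$long$inhibition_min)
  expect_equal(back$display, s2$long$display)
  expect_identical(summarize_conditions(back)$minutes, s2$minutes)
})
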