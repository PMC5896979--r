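test_that("ratio series is computed per frame and is bleach-invariant", {
  obs <- obs_from_ratio(1, rep(1.2, 6))
  ser <- compute_ratio_series(obs)
  expect_equal(ser$ratio, rep(1.2, 6))
  expect_equal(ser$delta[-1], rep(0, 5))
  expect_true(is.na(ser$delta[1]))
  # photobleaching multiplies both channels: the ratio is unchanged
  bleach <- 0.97^(0:5)
  obs2 <- obs
  obs2$mean_nuclear <- obs$mean_nuclear * bleach
  obs2$mean_reporter <- obs$mean_reporter * bleach
  expect_equal(compute_ratio_series(obs2)$ratio, ser$ratio)
  # zero reporter frames are skipped with a warning
  obs3 <- obs; obs3$mean_reporter[3] <- 0
  expect_warning(ser3 <- compute_ratio_series(obs3), "reporter")
  expect_equal(nrow(ser3), 5)
})

test_that("jump and sustained-rise triggers fire per the 20% / 5-point rules", {
  # 1.0, 1.0, 1.3: delta 0.3 > 0.2 x 1.0 -> jump at frame 3
  s1 <- compute_ratio_series(obs_from_ratio(1, c(1.0, 1.0, 1.3, 1.25, 1.2)))
  st1 <- detect_rupture_start(s1)
  expect_equal(st1$frame, 3L)
  expect_equal(st1$trigger, "jump")
  # exactly 20% is not an exceedance
  s2 <- compute_ratio_series(obs_from_ratio(1, c(1.0, 1.2, 1.2, 1.2)))
  expect_equal(nrow(detect_rupture_start(s2)), 0)
  # five strictly increasing points trigger a rise starting at the run start
  s3 <- compute_ratio_series(obs_from_ratio(
    1, c(1.00, 1.00, 1.03, 1.06, 1.09, 1.12, 1.15, 1.15)))
  st3 <- detect_rupture_start(s3)
  expect_equal(st3$trigger, "sustained_rise")
  expect_equal(st3$frame, 2L)
  # four increasing points are not enough
  s4 <- compute_ratio_series(obs_from_ratio(
    1, c(1.00, 1.03, 1.06, 1.09, 1.09, 1.09)))
  expect_equal(nrow(detect_rupture_start(s4)), 0)
  # flat series never fires
  s5 <- compute_ratio_series(obs_from_ratio(1, rep(1, 10)))
  expect_equal(nrow(detect_rupture_start(s5)), 0)
  # sub-floor creep does not count as a rise
  s6 <- compute_ratio_series(obs_from_ratio(
    1, 1 + cumsum(rep(0.002, 10))))
  expect_equal(nrow(detect_rupture_start(s6)), 0)
})

test_that("a jump inside a sustained rise is merged into one event", {
  r <- c(1.00, 1.02, 1.05, 1.08, 1.40, 1.45, 1.3, 1.1, 1.0, 1.0)
  ser <- compute_ratio_series(obs_from_ratio(1, r))
  st <- detect_rupture_start(ser)
  expect_equal(nrow(st), 1)
  expect_equal(st$frame, 1L)   # earlier frame (rise onset) wins on merge
  expect_equal(st$trigger, "sustained_rise")
})

test_that("rupture end closes on baseline return with settled delta", {
  r <- c(1.0, 1.0, 1.5, 1.4, 1.25, 1.12, 1.05, 1.03, 1.02, 1.02)
  ser <- compute_ratio_series(obs_from_ratio(1, r))
  e <- detect_rupture_end(ser, start_frame = 3L)
  expect_equal(e$baseline_ratio, 1.0)
  expect_equal(e$end_frame, 8L)   # frame 7 is <= 1.1 but delta is still 0.07
  # recovery only to 1.05 x baseline closes at the first qualifying frame
  r2 <- c(1.0, 1.0, 1.5, 1.3, 1.05, 1.05, 1.05)
  e2 <- detect_rupture_end(compute_ratio_series(obs_from_ratio(1, r2)), 3L)
  expect_equal(e2$end_frame, 6L)  # frame 5 still has delta 0.25
  # a trace that never recovers stays open
  r3 <- c(1.0, 1.0, 1.5, 1.45, 1.4, 1.38)
  e3 <- detect_rupture_end(compute_ratio_series(obs_from_ratio(1, r3)), 3L)
  expect_true(is.na(e3$end_frame))
})

test_that("two ruptures on one track are kept separate, overlaps merged", {
  r <- c(1, 1, 1.4, 1.2, 1.04, 1, 1, 1, 1.5, 1.3, 1.04, 1)
  ev <- detect_ruptures(obs_from_ratio(1, r), frame_interval_min = 2)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_frame, c(3L, 9L))
  expect_true(all(ev$end_frame > ev$start_frame))
  expect_equal(ev$duration_min, (ev$end_frame - ev$start_frame) * 2)
  # a second trigger during an open event is absorbed
  r2 <- c(1, 1, 1.4, 1.75, 1.5, 1.2, 1.05, 1)
  ev2 <- detect_ruptures(obs_from_ratio(1, r2), frame_interval_min = 2)
  expect_equal(nrow(ev2), 1)
})

test_that("global rescaling of both channels changes no detected event", {
  set.seed(8)
  r <- c(rep(1, 6), 1.45, 1.3, 1.15, 1.05, 1.02, rep(1, 5)) +
    rnorm(16, 0, 0.003)
  obs <- obs_from_ratio(1, r)
  base <- detect_ruptures(obs, 2)
  scale <- runif(16, 0.5, 1.5)   # arbitrary per-frame illumination factor
  obs2 <- obs
  obs2$mean_nuclear <- obs$mean_nuclear * scale
  obs2$mean_reporter <- obs$mean_reporter * scale
  expect_equal(detect_ruptures(obs2, 2), base)
})

test_that("division-like events are reclassified as mitosis by vicinity", {
  # parent track 1 with a ratio doubling at frame 5; daughter appears frame 6
  parent <- obs_from_ratio(1, c(1, 1, 1, 1, 2, 1, 1, 1), x = 100, y = 100)
  daughter <- obs_from_ratio(2, rep(1, 3), x = 100, y = 113)
  daughter$frame <- 6:8
  obs <- rbind(parent, daughter)
  tracks <- data.frame(track_id = c(1L, 2L), start_frame = c(1L, 6L),
                       end_frame = c(8L, 8L), n_obs = c(8L, 3L),
                       parent_id = NA_integer_)
  cand <- detect_ruptures(obs, 2)
  expect_equal(cand$start_frame, 5L)
  rec <- reclassify_mitosis(obs, tracks, cand, vicinity_um = 40,
                            pixel_size_um = 0.8)
  expect_equal(nrow(rec$ruptures), 0)
  expect_equal(rec$mitoses$parent_track_id, 1L)
  expect_equal(rec$mitoses$division_frame, 5L)
  expect_equal(rec$tracks$parent_id[rec$tracks$track_id == 2L], 1L)
  # a distant new track does not trigger reclassification
  far <- daughter; far$x <- 300; far$track_id <- 3L
  obs_far <- rbind(parent, far)
  tracks_far <- tracks; tracks_far$track_id <- c(1L, 3L)
  rec2 <- reclassify_mitosis(obs_far, tracks_far, cand, 40, 0.8)
  expect_equal(nrow(rec2$ruptures), 1)
  expect_equal(nrow(rec2$mitoses), 0)
  # no new track at all: rupture stands (vacuous reclassification)
  rec3 <- reclassify_mitosis(parent, tracks[1, ], cand, 40, 0.8)
  expect_equal(nrow(rec3$ruptures), 1)
})

test_that("rupture traces normalize to 0 at onset and 1 at peak", {
  r <- c(1.1, 1.1, 1.65, 1.5, 1.3, 1.2, 1.15, 1.12)
  ser <- compute_ratio_series(obs_from_ratio(1, r))
  nt <- normalize_rupture_trace(ser, start_frame = 3L)
  expect_equal(nt$value[1], 0)
  expect_equal(max(nt$value), 1)
  expect_equal(nt$value[2], 1)   # peak at the jump frame
  expect_true(all(nt$value >= 0 & nt$value <= 1))
  expect_equal(nt$t_rel, 0:(nrow(nt) - 1))
})

test_that("scripted rupture suite is reproduced end to end", {
  stats <- list()
  for (k in 1:3) {
    res <- suite_result("rupture_suite", k, 2)
    s <- score_ruptures(res$bundle$ruptures, res$bundle$observations,
                        res$rendered$truth)
    expect_equal(s$recall, 1)
    expect_equal(s$n_false_positive, 0)
    expect_lte(s$max_duration_err_frames, 1)
  }
  div <- suite_result("rupture_suite", 4, 2)
  expect_equal(nrow(div$bundle$ruptures), 0)
  expect_equal(nrow(div$bundle$mitoses), 10)
  flat <- suite_result("rupture_suite", 5, 2)
  expect_equal(nrow(flat$bundle$ruptures), 0)
})
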