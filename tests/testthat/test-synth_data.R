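test_that("rendering is bit-identical under a fixed seed", {
  sc <- scenario(name = "d", frames = 3L, width = 200, height = 160,
                 device = device_spec(pillars_per_row = 3, pitch_px = 40,
                                      radius_px = 8, row_spacing_px = 50,
                                      first_row_y = 30, first_pillar_x = 40),
                 nuclei = list(script_stationary(1, 1:3, 100, 100)),
                 noise_sigma = 0.02, seed = 5L)
  r1 <- render_scenario(sc)
  r2 <- render_scenario(sc)
  expect_identical(r1$sequence$frames, r2$sequence$frames)
  expect_identical(r1$truth$tracks, r2$truth$tracks)
})

test_that("noise-free renders reproduce scripted centroids and areas", {
  sc <- scenario(name = "gt", frames = 1L, width = 200, height = 160,
                 device = device_spec(pillars_per_row = 2, pitch_px = 40,
                                      radius_px = 8, row_spacing_px = 50,
                                      first_row_y = 20, first_pillar_x = 30),
                 nuclei = list(script_stationary(1, 1L, 100.3, 99.6)),
                 noise_sigma = 0, seed = 5L)
  r <- render_scenario(sc)
  nuc <- get_frame(r$sequence, 1, "nuclear")
  # intensity-weighted centroid of the rendered ellipse
  idx <- which(nuc > 0.25)
  w <- nuc[idx]
  ys <- (idx - 1) %% 160 + 1; xs <- (idx - 1) %/% 160 + 1
  expect_lt(abs(sum(xs * w) / sum(w) - 100.3), 0.5)
  expect_lt(abs(sum(ys * w) / sum(w) - 99.6), 0.5)
  # segmented area within 5% of pi * a * b (on the half-maximum contour)
  area <- sum(nuc > 0.25)
  expect_lt(abs(area - pi * 9 * 7) / (pi * 9 * 7), 0.05)
})

test_that("scripted rupture traces carry self-consistent channel means", {
  tr <- script_rupture_trace(1, frames = 20, x = 50, y = 50,
                             start_frame = 8, jump_frac = 0.4, tau = 2)
  s <- tr$script
  ratio <- s$nuclear_level / s$reporter_level
  expect_equal(ratio[7], 1)
  expect_equal(ratio[8], 1.4)
  expect_equal(ratio[9], 1 + 0.4 * exp(-1 / 2))
  expect_true(tr$rupture$expected_detected)
  # scripted end = first frame where the closure rule holds on the script
  e <- tr$rupture$end_frame
  expect_true(ratio[e] <= 1.1 && abs(ratio[e] - ratio[e - 1]) <= 0.05)
  expect_true(any(ratio[8:(e - 1)] > 1.1))
  # sub-threshold jump flagged as not expected
  expect_false(script_rupture_trace(2, 20, 50, 50, 8, 0.15)$rupture$expected_detected)
})

test_that("nuclei scripted outside the frame are rejected", {
  sc <- scenario(name = "oob", frames = 1L, width = 100, height = 100,
                 nuclei = list(script_stationary(1, 1L, 98, 50)),
                 device = device_spec(pillars_per_row = 2, pitch_px = 30,
                                      radius_px = 6, first_row_y = 20,
                                      first_pillar_x = 20,
                                      row_spacing_px = 30),
                 seed = 1L)
  expect_error(render_scenario(sc), "outside the frame")
})

test_that("standard suites are fixed, complete and deterministic", {
  s1 <- standard_suites()
  s2 <- standard_suites()
  expect_identical(names(s1), c("registration_suite", "tracking_suite",
                                "transit_suite", "rupture_suite"))
  expect_identical(s1, s2)
  # registration: rotations span -5..+5 deg, 12-24 pillars
  rots <- vapply(s1$registration_suite, function(sc) sc$device$rotation_deg,
                 numeric(1))
  expect_equal(range(rots), c(-5, 5))
  np <- vapply(s1$registration_suite, function(sc) {
    sc$device$pillars_per_row * sc$device$n_rows
  }, numeric(1))
  expect_true(all(np >= 12 & np <= 24))
  # transit: 20 trajectories, at least one scripted failure and one graze
  truth1 <- s1$transit_suite[[1]]$truth$transits
  expect_true(any(truth1$outcome == "failure"))
  has_graze <- any(vapply(s1$transit_suite[[1]]$nuclei, function(n) {
    nrow(n$script) > 0 && all(n$script$y[1] == n$script$y)
  }, logical(1)))
  # grazes are the trajectories that poke the band for one frame; verify by
  # construction through the script helper instead
  g <- script_transit(99, 100, 190, type = "graze", start_frame = 1,
                      total_frames = 12)
  expect_equal(sum(abs(g$script$y - 190) <= 15), 1)  # single poke frame
  # rupture suite: 30 rupture traces (jumps 10-60%), 10 divisions, 10 flat
  rups <- do.call(rbind, lapply(s1$rupture_suite[1:3],
                                function(sc) sc$truth$ruptures))
  expect_equal(nrow(rups), 30)
  expect_equal(range(rups$jump_frac), c(0.10, 0.60))
  expect_equal(sum(rups$expected_detected), 24)
  expect_equal(nrow(s1$rupture_suite[[4]]$truth$divisions), 10)
  expect_equal(length(s1$rupture_suite[[5]]$nuclei), 10)
})

test_that("division scripts hand one nucleus over to two daughters", {
  d <- script_division(3, frames = 30, x = 100, y = 100, division_frame = 12)
  expect_equal(d$division$division_frame, 12)
  # parent reporter halves exactly at the division frame (ratio doubles)
  s <- d$parent$script
  expect_equal(s$reporter_level[12], s$nuclear_level[12] / 2)
  expect_equal(s$reporter_level[13], s$nuclear_level[13])
  # daughter exists only after division, displaced from the parent
  expect_equal(min(d$daughter$script$frame), 13)
  expect_gt(abs(d$daughter$script$y[1] - s$y[13]), 10)
})
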