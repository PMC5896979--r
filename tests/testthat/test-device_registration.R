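test_that("pillars in a rendered device are found within 2 px of truth", {
  sc <- scenario(name = "reg", frames = 1L, width = 300, height = 240,
                 device = device_spec(pillars_per_row = 4, pitch_px = 42,
                                      radius_px = 8, row_spacing_px = 80,
                                      first_row_y = 50, first_pillar_x = 70),
                 noise_sigma = 0.01, seed = 7L)
  r <- render_scenario(sc)
  pil <- detect_pillars(get_frame(r$sequence, 1, "transmitted"))
  expect_equal(nrow(pil), 12)
  err <- vapply(seq_len(12), function(i) {
    min(sqrt((pil$x - r$truth$pillars$x[i])^2 +
               (pil$y - r$truth$pillars$y[i])^2))
  }, numeric(1))
  expect_lt(max(err), 2)
  # sorted by (y, x)
  expect_true(!is.unsorted(pil$y))
})

test_that("registration fails informatively without enough circles", {
  blank <- matrix(0.7, 120, 160)
  expect_error(detect_pillars(blank), "registration failure")
  one <- matrix(0.8, 120, 160)
  one <- confinetrack:::add_soft_disk(one, 50, 50, 8, -0.5)
  expect_error(detect_pillars(one), "registration failure")
})

test_that("rotation estimate matches hand-computed two-pillar angle", {
  pil <- data.frame(x = c(0, 100), y = c(0, 10), r = c(8, 8))
  # a row sloping down by atan(10/100) needs the opposite correction
  expect_equal(estimate_rotation(pil), -atan2(10, 100) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(estimate_rotation(data.frame(x = c(0, 100), y = c(50, 50),
                                            r = 8)), 0)
  expect_error(estimate_rotation(data.frame(x = c(5, 5), y = c(9, 9),
                                            r = c(8, 8))), "degenerate")
})

test_that("applied grid rotations are recovered within 0.2 degrees", {
  for (rot in c(-4, 3)) {
    sc <- scenario(name = "rot", frames = 1L, width = 360, height = 280,
                   device = device_spec(pillars_per_row = 6, pitch_px = 40,
                                        radius_px = 8, row_spacing_px = 90,
                                        first_row_y = 50, first_pillar_x = 80,
                                        rotation_deg = rot),
                   noise_sigma = 0.01, seed = 11L)
    r <- render_scenario(sc)
    pil <- detect_pillars(get_frame(r$sequence, 1, "transmitted"))
    expect_equal(estimate_rotation(pil), -rot, tolerance = 0.2)
  }
})

test_that("rotation round-trip preserves content and re-levels rows", {
  sc <- scenario(name = "rt", frames = 2L, width = 360, height = 280,
                 device = device_spec(pillars_per_row = 6, pitch_px = 40,
                                      radius_px = 8, row_spacing_px = 90,
                                      first_row_y = 50, first_pillar_x = 80,
                                      rotation_deg = 3),
                 noise_sigma = 0.005, seed = 13L)
  r <- render_scenario(sc)
  # identity rotation is a no-op
  expect_identical(rotate_sequence(r$sequence, 0), r$sequence)
  # +3 then -3 returns close to the original away from borders
  fr0 <- get_frame(r$sequence, 1, "transmitted")
  back <- confinetrack:::rotate_frame(
    confinetrack:::rotate_frame(fr0, 3, fill = stats::median(fr0)),
    -3, fill = stats::median(fr0))
  core <- 40:240
  expect_lt(mean(abs(back[core, core] - fr0[core, core])),
            0.02 * diff(range(fr0)))
  # correcting the device rotation leaves rows horizontal within 0.5 px RMS
  pil <- detect_pillars(fr0)
  ang <- estimate_rotation(pil)
  corrected <- rotate_sequence(r$sequence, ang)
  pil2 <- detect_pillars(get_frame(corrected, 1, "transmitted"))
  rows <- confinetrack:::cluster_pillar_rows(pil2)
  rms <- sqrt(mean(unlist(lapply(rows, function(rw) {
    (rw$y - mean(rw$y))^2
  }))))
  expect_lt(rms, 0.5)
})

test_that("geometry boundaries sit exactly at the unit-converted offset", {
  pil <- data.frame(x = c(20, 60, 100), y = c(100, 100, 100), r = 8)
  expect_warning(g <- build_geometry(pil, boundary_offset_um = 7,
                                     pixel_size_um = 0.5),
                 "expected 3")
  expect_equal(g$rows[[1]]$upper_boundary_y, 86)
  expect_equal(g$rows[[1]]$lower_boundary_y, 114)
  expect_equal(g$rows[[1]]$x_centers, c(40, 80))
  # boundary symmetry holds for every row of a full device
  pil3 <- rbind(pil, transform(pil, y = 200), transform(pil, y = 300))
  g3 <- build_geometry(pil3, 7, 0.8)
  for (rw in g3$rows) {
    expect_equal(rw$centerline_y - rw$upper_boundary_y,
                 rw$lower_boundary_y - rw$centerline_y)
  }
  expect_error(build_geometry(pil, boundary_offset_um = 0, pixel_size_um = 1))
})

test_that("registration is deterministic and survives a JSON round-trip", {
  sc <- scenario(name = "det", frames = 1L, width = 300, height = 240,
                 device = device_spec(pillars_per_row = 4, pitch_px = 42,
                                      radius_px = 8, row_spacing_px = 80,
                                      first_row_y = 50, first_pillar_x = 70,
                                      rotation_deg = -2),
                 noise_sigma = 0.01, seed = 7L)
  fr <- get_frame(render_scenario(sc)$sequence, 1, "transmitted")
  g1 <- register_device(fr)
  g2 <- register_device(fr)
  expect_identical(g1, g2)
  tf <- tempfile(fileext = ".json")
  write_geometry(g1$geometry, tf)
  g3 <- read_geometry(tf)
  expect_equal(g3$rotation_deg, g1$geometry$rotation_deg)
  expect_equal(g3$rows[[2]]$centerline_y, g1$geometry$rows[[2]]$centerline_y)
  expect_equal(g3$rows[[1]]$x_centers, g1$geometry$rows[[1]]$x_centers)
})
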