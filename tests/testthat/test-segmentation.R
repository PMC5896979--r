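test_that("adaptive threshold finds ellipses and resists illumination gradients", {
  expect_equal(sum(binarize_nuclei(matrix(0.5, 60, 60))), 0)
  sc <- scenario(name = "seg5", frames = 1L, width = 300, height = 200,
                 device = device_spec(pillars_per_row = 2, pitch_px = 40,
                                      radius_px = 8, row_spacing_px = 60,
                                      first_row_y = 20, first_pillar_x = 20),
                 nuclei = lapply(1:5, function(i) {
                   script_stationary(i, 1L, 40 + 50 * i, 60 + 25 * (i %% 3))
                 }),
                 noise_sigma = 0.01, seed = 31L)
  r <- render_scenario(sc)
  nuc <- get_frame(r$sequence, 1, "nuclear")
  count_and_iou <- function(frame) {
    mask <- binarize_nuclei(smooth_fluorescence(frame))
    labels <- as.matrix(EBImage::bwlabel(mask))
    tru <- subset(r$truth$tracks, frame == 1)
    ious <- vapply(seq_len(5), function(i) {
      gt <- ellipse_mask(data.frame(x = tru$x[i], y = tru$y[i]), 9, 7,
                         H = 200, W = 300)
      lab_at <- labels[round(tru$y[i]), round(tru$x[i])]
      if (lab_at == 0) return(0)
      det <- labels == lab_at
      sum(det & gt) / sum(det | gt)
    }, numeric(1))
    list(n = max(labels), iou = ious)
  }
  flat <- count_and_iou(nuc)
  expect_equal(flat$n, 5)
  expect_true(all(flat$iou >= 0.7))
  # 2x linear illumination gradient changes nothing structurally
  grad <- nuc * matrix(rep(seq(1, 2, length.out = 300), each = 200), 200, 300)
  withgrad <- count_and_iou(grad)
  expect_equal(withgrad$n, 5)
  expect_true(all(withgrad$iou >= 0.7))
})

test_that("watershed splits touching pairs but not single nuclei", {
  # two overlapping ellipses 1.5 minor-axes apart -> exactly 2 labels
  m2 <- ellipse_mask(data.frame(x = c(45, 45), y = c(30, 40.5)), a = 9, b = 7)
  lab2 <- split_touching(m2, h_depth = 0.5)
  expect_equal(max(lab2), 2)
  # the dividing line lies within 2 px of the true bisector (y = 35.25)
  border_y <- vapply(seq_len(ncol(lab2)), function(x) {
    col <- lab2[, x]
    i <- which(col[-length(col)] == 1 & col[-1] == 2)
    if (length(i) == 0) NA_real_ else i[1] + 0.5
  }, numeric(1))
  expect_lt(max(abs(stats::na.omit(border_y) - 35.25)), 2)
  # a single ellipse is a single catchment basin at any h
  m1 <- ellipse_mask(data.frame(x = 45, y = 35), a = 9, b = 7)
  expect_equal(max(split_touching(m1, h_depth = 0.5)), 1)
  # foreground preserved
  expect_equal(sum(lab2 > 0), sum(m2))
})

test_that("h-minima depth controls over-segmentation of a dented ellipse", {
  m <- ellipse_mask(data.frame(x = 50, y = 40), a = 16, b = 10)
  m[38:42, 48:50] <- 0   # boundary dent reaching the midline
  m <- as.matrix(EBImage::fillHull(m)); storage.mode(m) <- "double"
  m[38:40, 49:50] <- 0   # keep an open notch
  expect_gt(max(split_touching(m, h_depth = 1e-6)), 1)
  expect_equal(max(split_touching(m, h_depth = 4)), 1)
  # monotonicity: labels never increase with h
  hs <- c(0.25, 0.5, 1, 2, 4, 8)
  ns <- vapply(hs, function(h) max(split_touching(m, h)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("dumbbell nuclei in constriction bands stay whole, others split", {
  geom <- toy_geometry()
  sc <- scenario(name = "db", frames = 1L, width = 520, height = 360,
                 nuclei = list(list(id = 1, script = confinetrack:::new_script(
                   1L, x = 120, y = 190, shape = "dumbbell", sep = 14))),
                 noise_sigma = 0.01, seed = 41L)
  r <- render_scenario(sc)
  nuc <- get_frame(r$sequence, 1, "nuclear")
  mask <- binarize_nuclei(smooth_fluorescence(nuc))
  raw_labels <- split_touching(mask, h_depth = 2)
  kept <- suppress_splitting_in_constrictions(raw_labels, mask, geom)
  # count objects near the scripted dumbbell
  near <- function(lab) length(setdiff(unique(lab[160:220, 95:145]), 0L))
  expect_equal(near(kept), 1)
  # the same dumbbell far from any row may split, suppression inactive
  sc2 <- scenario(name = "db2", frames = 1L, width = 520, height = 360,
                  nuclei = list(list(id = 1, script = confinetrack:::new_script(
                    1L, x = 120, y = 135, shape = "dumbbell", sep = 14))),
                  noise_sigma = 0.01, seed = 41L)
  nuc2 <- get_frame(render_scenario(sc2)$sequence, 1, "nuclear")
  mask2 <- binarize_nuclei(smooth_fluorescence(nuc2))
  lab2 <- suppress_splitting_in_constrictions(split_touching(mask2, 2),
                                              mask2, geom)
  expect_gte(length(setdiff(unique(lab2[105:165, 95:145]), 0L)), 1)
  # two genuinely touching nuclei outside any band still split
  sc3 <- scenario(name = "db3", frames = 1L, width = 520, height = 360,
                  nuclei = list(script_stationary(1, 1L, 300, 135),
                                script_stationary(2, 1L, 321, 135)),
                  noise_sigma = 0.01, seed = 43L)
  nuc3 <- get_frame(render_scenario(sc3)$sequence, 1, "nuclear")
  mask3 <- binarize_nuclei(smooth_fluorescence(nuc3))
  lab3 <- suppress_splitting_in_constrictions(split_touching(mask3, 2),
                                              mask3, geom)
  expect_equal(length(setdiff(unique(lab3[105:165, 270:350]), 0L)), 2)
})

test_that("object filters remove specks and streaks but keep nuclei", {
  lab <- matrix(0L, 100, 150)
  lab[50:51, 30] <- 1L                      # 2-px speck
  lab[20:90, 100:101] <- 2L                 # long thin streak
  el <- ellipse_mask(data.frame(x = 60, y = 60), 9, 7, H = 100, W = 150)
  lab[el == 1] <- 3L
  out <- filter_objects(lab, geometry = NULL, pixel_size_um = 0.8)
  expect_equal(sort(unique(as.vector(out))), c(0L, 1L))
  expect_equal(sum(out > 0), sum(el))
  # deformed object inside a constriction band is exempt from circularity
  geom <- toy_geometry(rows_y = 60, offset_px = 8.75, x_centers = 100)
  lab2 <- matrix(0L, 100, 150)
  lab2[53:67, 80:120] <- 1L   # elongated block straddling the band at x ~100
  expect_equal(max(filter_objects(lab2, geom, 0.8)), 1)
  lab3 <- matrix(0L, 100, 150)
  lab3[13:27, 80:120] <- 1L   # same shape far from the band
  circ <- 4 * pi * sum(lab3 == 1) / 112^2
  if (circ < 0.3) expect_equal(max(filter_objects(lab3, geom, 0.8)), 0)
})

test_that("measurements match hand arithmetic on a square patch", {
  lab <- matrix(0L, 60, 60)
  lab[30:39, 20:29] <- 1L   # rows 30..39 (y), cols 20..29 (x)
  nucch <- matrix(0, 60, 60); nucch[lab == 1L] <- 100
  repch <- matrix(0, 60, 60); repch[lab == 1L] <- 50
  obs <- measure_objects(lab, nucch, repch, frame_index = 3L)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$area_px2, 100)
  expect_equal(obs$x, 24.5)
  expect_equal(obs$y, 34.5)
  expect_equal(obs$mean_nuclear, 100)
  expect_equal(obs$mean_reporter, 50)
  expect_equal(obs$frame, 3L)
  expect_equal(unname(c(obs$min_x, obs$min_y, obs$max_x, obs$max_y)),
               c(20L, 30L, 29L, 39L))
  expect_equal(nrow(measure_objects(matrix(0L, 10, 10),
                                    matrix(0, 10, 10), matrix(0, 10, 10))), 0)
})

test_that("per-frame detection on the standard scene is near-perfect", {
  res <- suite_result("tracking_suite", 1, 10)
  sc <- score_detections(res$bundle$observations, res$rendered$truth$tracks)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
  # centroids within 1 px and areas within 10% of scripted truth
  m <- sc$matches
  obs <- res$bundle$observations
  tru <- res$rendered$truth$tracks
  errs <- vapply(seq_len(nrow(m)), function(i) {
    o <- obs[obs$frame == m$frame[i] & obs$label == m$label[i] &
               obs$track_id == m$track_id[i], ][1, ]
    t <- tru[tru$frame == m$frame[i] & tru$id == m$true_id[i], ]
    sqrt((o$x - t$x)^2 + (o$y - t$y)^2)
  }, numeric(1))
  expect_lt(stats::quantile(errs, 0.99), 1.5)
})

test_that("label maps are clean partitions", {
  res <- suite_result("tracking_suite", 1, 10)
  seq1 <- res$rendered$sequence
  seg <- segment_frame(get_frame(seq1, 1, "nuclear"),
                       get_frame(seq1, 1, "reporter"), 1L, NULL,
                       analysis_config())
  lab <- seg$labels
  ids <- sort(unique(as.vector(lab)))
  expect_equal(ids, 0:max(lab))   # compact positive labels + background
})
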