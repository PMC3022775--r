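# ROI intensity scoring, spot detection and band counting.

roi_at <- function(cx, cy, side = 48L, W = 320L, H = 200L, score = 1)
  chinassay:::.new_roi(cx, cy, side, W, H, score)

test_that("ROI mean relative intensity matches direct pixel oracles", {
  red <- matrix(0, 200, 320)
  r <- roi_at(100, 100)
  # uniform patch of 500, zero background
  red[r$y0:r$y1, r$x0:r$x1] <- 500
  expect_equal(roi_red_intensity(red, r, 0), 500)
  # half 100 / half 0
  red2 <- matrix(0, 200, 320)
  mid <- (r$x0 + r$x1 - 1) / 2
  red2[r$y0:r$y1, r$x0:floor(mid)] <- 100
  oracle <- mean(red2[r$y0:r$y1, r$x0:r$x1])
  expect_equal(roi_red_intensity(red2, r, 0), oracle)
  # signal equal to background -> zero relative intensity
  flat <- matrix(123, 200, 320)
  m <- score_larva_intensity(flat, list(r))
  expect_equal(m$inflammation_score, 0)
  # background floor: never negative
  expect_equal(roi_red_intensity(red2, r, 1e6), 0)
})

test_that("per-larva intensity score averages the ROI scores", {
  red <- matrix(0, 200, 320)
  rois <- list(roi_at(60, 100), roi_at(150, 100), roi_at(250, 100))
  vals <- c(10, 20, 30)
  for (i in 1:3)
    red[rois[[i]]$y0:rois[[i]]$y1, rois[[i]]$x0:rois[[i]]$x1] <- vals[i]
  m <- score_larva_intensity(red, rois, larva_id = "L1", condition = "c")
  expect_equal(m$roi_scores, vals)
  expect_equal(m$inflammation_score, 20)
  expect_equal(m$n_rois, 3L)
  expect_true(m$qc$data_producing)
})

test_that("zero-ROI larvae get no score and are flagged", {
  m <- score_larva_intensity(matrix(0, 50, 50), list())
  expect_true(is.na(m$inflammation_score))
  expect_equal(m$n_rois, 0L)
  expect_false(m$qc$data_producing)
  df <- as.data.frame(m)
  expect_false(df$data_producing)
})

test_that("adding intensity inside an ROI raises the score; outside it does not", {
  set.seed(81)
  red <- matrix(rpois(200 * 320, 40), 200, 320)
  rois <- list(roi_at(80, 100), roi_at(200, 100))
  base <- score_larva_intensity(red, rois)$inflammation_score
  up <- red
  up[rois[[1]]$y0:rois[[1]]$y1, rois[[1]]$x0:rois[[1]]$x1] <-
    up[rois[[1]]$y0:rois[[1]]$y1, rois[[1]]$x0:rois[[1]]$x1] + 100
  expect_gt(score_larva_intensity(up, rois)$inflammation_score, base)
  out <- red
  out[150:199, 1:40] <- out[150:199, 1:40] + 5000   # outside both squares
  expect_lte(score_larva_intensity(out, rois)$inflammation_score, base)
})

test_that("degenerate ROI input is rejected", {
  red <- matrix(0, 50, 50)
  bad <- roi_at(25, 25, side = 8L, W = 50L, H = 50L)
  bad$x0 <- 40L; bad$x1 <- 30L
  expect_error(roi_red_intensity(red, bad), "zero area")
})

test_that("spot detection finds planted spots and merges unresolved pairs", {
  expect_equal(nrow(detect_leukocyte_spots(matrix(0, 100, 150))), 0)
  set.seed(83)
  img <- matrix(0, 200, 320)
  truth <- cbind(x = seq(30, 290, length.out = 12),
                 y = rep(c(60, 140), 6))
  for (i in 1:12) img <- plant_spot(img, truth[i, 1], truth[i, 2], 3, 2000)
  sp <- detect_leukocyte_spots(img)
  expect_equal(nrow(sp), 12)
  err <- vapply(1:12, function(i)
    min(sqrt((sp[, "x"] - truth[i, 1])^2 + (sp[, "y"] - truth[i, 2])^2)),
    numeric(1))
  expect_lt(max(err), 2)
  # two spots one pixel apart are below the resolution limit -> one spot
  pair <- plant_spot(plant_spot(matrix(0, 100, 100), 50, 50, 3, 1000),
                     51, 50, 3, 1000)
  expect_equal(nrow(detect_leukocyte_spots(pair)), 1)
})

test_that("band membership matches a brute-force oracle, boundary inclusive", {
  b <- band_spec(c(40, 100), c(280, 100), half_width = 50)
  expect_equal(count_in_band(cbind(x = 150, y = 100), b), 1L)  # on the axis
  expect_equal(count_in_band(cbind(x = 150, y = 150), b), 1L)  # exactly at edge
  expect_equal(count_in_band(cbind(x = 150, y = 151), b), 0L)  # just outside
  expect_equal(count_in_band(cbind(x = 39, y = 100), b), 0L)   # before segment
  expect_equal(count_in_band(matrix(numeric(0), 0, 2), b), 0L)

  # rotated band, 20 random spots vs an independent point-in-band check
  set.seed(84)
  p0 <- c(50, 60); p1 <- c(250, 170); hw <- 30
  bb <- band_spec(p0, p1, hw)
  spots <- cbind(x = runif(20, 0, 320), y = runif(20, 0, 200))
  oracle <- sum(apply(spots, 1, function(s) {
    d <- p1 - p0; L <- sqrt(sum(d^2))
    # distance from point to segment axis via the cross-product formula
    perp <- abs(d[1] * (s[2] - p0[2]) - d[2] * (s[1] - p0[1])) / L
    along <- sum((s - p0) * d) / L
    perp <= hw && along >= 0 && along <= L
  }))
  expect_equal(count_in_band(spots, bb), oracle)
  expect_error(band_spec(c(0, 0), c(0, 0)), "zero length")
  expect_error(band_spec(c(0, 0), c(1, 1), half_width = 0), "positive")
})

test_that("count mode recovers the true in-band count on separated fixtures", {
  set.seed(85)
  p <- test_scene(noise_sd = 0, baseline_count = 0,
                  lateral_orientation_prob = 1)
  l <- generate_larva(p, "copper", dose = 0)
  # plant well-separated cells, some inside and some outside the band
  xs <- seq(60, 280, length.out = 8)
  ys <- rep(c(0, 30, -20, 80), 2) + l$p0[2]   # offsets from the myoseptum
  l$leukocytes <- data.frame(x = xs, y = ys, peak = 2500, radius = 3,
                             recruited = FALSE)
  pr <- extended_focus_project(render_zstack(l, p), 3)
  band <- band_spec(l$p0, l$p1, half_width = 50)
  m <- score_larva_count(pr$red, band, condition = "copper")
  truth <- count_in_band(cbind(x = xs, y = ys), band)
  expect_identical(as.integer(m$band_count), as.integer(truth))
  expect_equal(m$mode, "count")
  expect_gt(truth, 0)
  expect_lt(truth, length(xs))
})

test_that("intensity and count modes agree across a dose ladder", {
  set.seed(86)
  p <- test_scene(lateral_orientation_prob = 1)
  doses <- c(0, 0.5, 2, 8, 32)
  mean_int <- mean_cnt <- numeric(length(doses))
  for (di in seq_along(doses)) {
    ints <- cnts <- numeric(12)
    for (i in 1:12) {
      l <- generate_larva(p, "d", dose = doses[di])
      st <- render_zstack(l, p)
      m <- quantify_stack(st, mode = "both", central_plane = 3,
                          band = band_spec(l$p0, l$p1, 50))
      ints[i] <- m$inflammation_score
      cnts[i] <- m$band_count
    }
    mean_int[di] <- mean(ints, na.rm = TRUE)
    mean_cnt[di] <- mean(cnts, na.rm = TRUE)
  }
  expect_gte(cor(mean_int, mean_cnt, method = "spearman"), 0.9)
})
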