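# Synthetic larva/plate generator: ground-truth statistics, rendering
# physics and determinism.

test_that("scene parameters are validated", {
  expect_error(scene_params(dose = -1), "non-negative")
  expect_error(scene_params(lateral_orientation_prob = 1.5), "\\[0, 1\\]")
  expect_error(generate_larva(test_scene(), dose = -2), "non-negative")
  expect_equal(recruit_mean_at(scene_params(recruit_rmax = 8,
                                            recruit_k50 = 2), 0), 0)
})

test_that("dose-response curve is zero at dose 0 and non-decreasing", {
  p <- test_scene(recruit_rmax = 8, recruit_k50 = 2)
  doses <- c(0, 0.1, 0.5, 2, 8, 32, 128)
  lam <- recruit_mean_at(p, doses)
  expect_equal(lam[1], 0)
  expect_true(all(diff(lam) >= 0))
  expect_lt(lam[length(lam)], p$recruit_rmax)
})

test_that("zero-dose larvae have only baseline leukocytes, away from neuromasts", {
  set.seed(101)
  p <- test_scene(baseline_count = 10)
  counts <- numeric(200); near <- 0
  for (i in 1:200) {
    l <- generate_larva(p, "control", dose = 0)
    counts[i] <- nrow(l$leukocytes)
    expect_true(all(!l$leukocytes$recruited))
    if (nrow(l$leukocytes)) {
      d <- sapply(seq_len(nrow(l$neuromast_centers)), function(j)
        sqrt((l$leukocytes$x - l$neuromast_centers[j, 1])^2 +
               (l$leukocytes$y - l$neuromast_centers[j, 2])^2))
      near <- near + sum(apply(as.matrix(d), 1, min) <= 2 * l$neuromast_radius)
    }
  }
  # Poisson(10): mean within 3 SE; essentially no cells at the neuromasts
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 200))
  expect_lt(near / sum(counts), 0.02)
})

test_that("treated larvae recruit Poisson(recruit_mean) per neuromast", {
  set.seed(202)
  p <- test_scene(baseline_count = 0)
  total <- vapply(1:1000, function(i) {
    l <- generate_larva(p, "copper", recruit_mean = 5)
    nrow(l$leukocytes)
  }, numeric(1))
  # 7 neuromasts x mean 5 = 35; Monte-Carlo mean within 3 SE
  expect_lt(abs(mean(total) - 35), 3 * sqrt(35 / 1000))
  set.seed(203)
  l <- generate_larva(p, "copper", recruit_mean = 5)
  d <- sapply(seq_len(nrow(l$neuromast_centers)), function(j)
    sqrt((l$leukocytes$x - l$neuromast_centers[j, 1])^2 +
           (l$leukocytes$y - l$neuromast_centers[j, 2])^2))
  expect_true(all(apply(as.matrix(d), 1, min) <= 2 * l$neuromast_radius + 1))
})

test_that("orientation flag follows the mounting probability", {
  set.seed(7)
  p1 <- test_scene(lateral_orientation_prob = 1)
  expect_true(all(vapply(1:25, function(i)
    generate_larva(p1)$orientation_ok, logical(1))))
  p0 <- test_scene(lateral_orientation_prob = 0)
  expect_false(any(vapply(1:25, function(i)
    generate_larva(p0)$orientation_ok, logical(1))))
})

test_that("larva geometry invariants hold", {
  set.seed(33)
  p <- test_scene()
  for (i in 1:30) {
    l <- generate_larva(p, "copper", dose = 10)
    cen <- l$neuromast_centers
    expect_true(all(cen[, 1] >= 1 & cen[, 1] <= p$img_width))
    expect_true(all(cen[, 2] >= 1 & cen[, 2] <= p$img_height))
    expect_true(all(l$leukocytes$x >= 1 & l$leukocytes$x <= p$img_width))
    expect_true(all(l$leukocytes$y >= 1 & l$leukocytes$y <= p$img_height))
    # centres within 1 px of the axis, ordered along it
    u <- (l$p1 - l$p0) / sqrt(sum((l$p1 - l$p0)^2))
    v <- c(-u[2], u[1])
    perp <- (cen[, 1] - l$p0[1]) * v[1] + (cen[, 2] - l$p0[2]) * v[2]
    along <- (cen[, 1] - l$p0[1]) * u[1] + (cen[, 2] - l$p0[2]) * u[2]
    expect_true(all(abs(perp) <= 1 + 1e-9))
    expect_true(all(diff(along) > 0))
    if (l$orientation_ok)
      expect_true(all(diff(along) >= 4 * l$neuromast_radius))
  }
})

test_that("rendering validates slice counts", {
  set.seed(1)
  p <- test_scene()
  l <- generate_larva(p)
  expect_error(render_zstack(l, p, n_slices = 4), "odd")
  expect_error(render_zstack(l, p, n_slices = 3), "odd")
})

test_that("no defocus and no noise give identical slices", {
  set.seed(5)
  p <- test_scene(noise_sd = 0, defocus_sigma_per_slice = 0)
  l <- generate_larva(p, "copper", dose = 10)
  st <- render_zstack(l, p)
  for (ch in 1:3) {
    a <- zstack_channel(st, ch)
    for (k in 2:dim(a)[3]) expect_equal(a[, , k], a[, , 1])
  }
})

test_that("rendered peak reads back and flux is conserved", {
  p <- test_scene(noise_sd = 0, offset = 0, baseline_count = 0,
                  lateral_orientation_prob = 1)
  set.seed(9)
  l <- generate_larva(p, "control", dose = 0)
  # one leukocyte at a pixel centre, away from edges
  l$leukocytes <- data.frame(x = 150, y = 60, peak = 1000, radius = 3,
                             recruited = FALSE)
  st <- render_zstack(l, p)
  central <- zstack_channel(st, "red", slice = st$central_plane)
  expect_lt(abs(max(central) - 1000) / 1000, 0.01)
  # flux: peak * 2*pi*sigma0^2 with sigma0^2 = spot^2 + psf^2, every slice
  expected_flux <- 1000 * 2 * pi * (3^2 + p$psf_sigma^2)
  for (k in seq_len(p$n_slices)) {
    sl <- zstack_channel(st, "red", slice = k)
    expect_lt(abs(sum(sl) - expected_flux) / expected_flux, 0.01)
  }
})

test_that("same seed renders bit-identical stacks", {
  p <- test_scene()
  set.seed(77); l1 <- generate_larva(p, "copper", 10)
  set.seed(77); l2 <- generate_larva(p, "copper", 10)
  expect_identical(l1, l2)
  set.seed(78); s1 <- render_zstack(l1, p)
  set.seed(78); s2 <- render_zstack(l2, p)
  expect_identical(s1$data, s2$data)
})

test_that("mean recruited count near neuromasts is non-decreasing in dose", {
  p <- test_scene(baseline_count = 5)
  doses <- c(0, 0.5, 2, 8, 32)
  means <- vapply(seq_along(doses), function(di) {
    set.seed(4000 + di)
    mean(vapply(1:150, function(i)
      sum(generate_larva(p, "d", dose = doses[di])$leukocytes$recruited),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= -0.2))   # monotone up to MC jitter
  expect_gt(means[5], means[1])
})

test_that("generate_plate writes files, manifest and ground truth consistently", {
  dir1 <- file.path(tempdir(), "plate_a")
  dir2 <- file.path(tempdir(), "plate_b")
  unlink(c(dir1, dir2), recursive = TRUE)
  lay <- plate_layout(data.frame(condition = c("control", "copper"),
                                 dose = c(0, 10)),
                      larvae_per_condition = 2, replicates = 2)
  p <- test_scene()
  res1 <- generate_plate(lay, p, dir1, seed = 42)
  expect_equal(nrow(res1$manifest), 2 * 2 * 2)
  expect_true(all(file.exists(file.path(dir1, res1$manifest$file))))
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_true(file.exists(file.path(dir1, "ground_truth_cells.json")))
  expect_equal(nrow(res1$ground_truth), nrow(res1$manifest))
  # reproducible from seed
  res2 <- generate_plate(lay, p, dir2, seed = 42)
  expect_identical(res1$ground_truth, res2$ground_truth)
  expect_identical(readBin(file.path(dir1, res1$manifest$file[1]), "raw", 1e6),
                   readBin(file.path(dir2, res2$manifest$file[1]), "raw", 1e6))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("an empty layout yields a valid empty plate", {
  d <- file.path(tempdir(), "plate_empty")
  unlink(d, recursive = TRUE)
  lay <- plate_layout(data.frame(condition = "control", dose = 0),
                      larvae_per_condition = 0, replicates = 1)
  res <- generate_plate(lay, test_scene(), d, seed = 1)
  expect_equal(nrow(res$manifest), 0)
  expect_equal(nrow(res$ground_truth), 0)
  m <- load_manifest(file.path(d, "manifest.csv"))
  expect_equal(nrow(m), 0)
  unlink(d, recursive = TRUE)
})
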