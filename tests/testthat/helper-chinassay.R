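# Shared helpers for the chinassay test suite.
#
# Tests run the simulator at a desk-scale field of view (320 x 200 px,
# 5 optical sections) instead of the camera's full 1300 x 1024 x 9; all
# rendered structures keep their absolute pixel sizes, so detector
# behaviour is unchanged.

test_scene <- function(...) {
  args <- list(img_width = 320, img_height = 200, n_slices = 5)
  user <- list(...)
  args[names(user)] <- user
  do.call(scene_params, args)
}

# Match detected ROI centroids against true neuromast centres.
# Returns per-larva recall, precision and the matched centroid errors.
match_detections <- function(rois, truth, radius = 24) {
  cen <- if (length(rois))
    t(vapply(rois, function(r) r$centroid, numeric(2)))
  else matrix(numeric(0), 0, 2)
  if (nrow(cen) == 0)
    return(list(recall = 0, precision = NA_real_, errors = numeric(0)))
  d_true <- vapply(seq_len(nrow(truth)), function(j)
    min(sqrt((cen[, 1] - truth[j, 1])^2 + (cen[, 2] - truth[j, 2])^2)),
    numeric(1))
  d_det <- vapply(seq_len(nrow(cen)), function(j)
    min(sqrt((cen[j, 1] - truth[, 1])^2 + (cen[j, 2] - truth[, 2])^2)),
    numeric(1))
  list(recall = mean(d_true <= radius),
       precision = mean(d_det <= radius),
       errors = d_true[d_true <= radius])
}

# Plant an isotropic Gaussian spot on a plain matrix (independent of the
# package's rendering kernel; used to build oracle fixtures).
plant_spot <- function(img, x, y, sigma, peak) {
  H <- nrow(img); W <- ncol(img)
  dx <- outer(rep(1, H), (seq_len(W) - x)^2)
  dy <- outer((seq_len(H) - y)^2, rep(1, W))
  img + peak * exp(-(dx + dy) / (2 * sigma^2))
}

# Render one larva and quantify it through the standard chain.
quantify_larva <- function(larva, params, mode = "intensity",
                           central_plane = (params$n_slices + 1) %/% 2) {
  stack <- render_zstack(larva, params)
  quantify_stack(stack, mode = mode, central_plane = central_plane,
                 orientation_ok = larva$orientation_ok,
                 condition = larva$condition)
}
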