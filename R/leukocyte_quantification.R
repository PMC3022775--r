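#' Band specification for count-mode quantification
#'
#' The manual assay counts leukocytes within five cell diameters above and
#' below the horizontal myoseptum (ten cell diameters total), from the
#' first somite to the end of the tail. With the simulator's convention of
#' a 10 px cell diameter the default half-width is 50 px.
#'
#' @param p0,p1 axis segment endpoints `c(x, y)` in pixels (first-somite
#'   point and tail end).
#' @param half_width band half-width in px (default 5 cell diameters of
#'   10 px).
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(p0, p1, half_width = 50) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 2L || length(p1) != 2L)
    .chin_stop("'p0' and 'p1' must be points c(x, y)")
  if (half_width <= 0) .chin_stop("'half_width' must be positive")
  if (sum((p1 - p0)^2) == 0) .chin_stop("band axis has zero length")
  structure(list(p0 = p0, p1 = p1, half_width = half_width),
            class = "band_spec")
}

#' Mean relative red intensity within one neuromast ROI
#'
#' Returns `mean(red pixels in the ROI square) - background`, floored at
#' zero. "Relative" means background-subtracted: the zero point is the
#' unstained tissue level, making the score invariant to the camera
#' offset.
#'
#' @param red_projection 2D matrix of projected red intensities.
#' @param roi a `neuromast_roi`.
#' @param background background level in camera counts (typically from
#'   [roi_background()], computed once per larva).
#' @return non-negative mean relative intensity.
#' @export
roi_red_intensity <- function(red_projection, roi, background = 0) {
  stopifnot(inherits(roi, "neuromast_roi"))
  H <- nrow(red_projection); W <- ncol(red_projection)
  x0 <- max(1L, roi$x0); x1 <- min(W, roi$x1)
  y0 <- max(1L, roi$y0); y1 <- min(H, roi$y1)
  if (x1 < x0 || y1 < y0)
    .chin_stop("ROI has zero area after clipping to the image")
  max(mean(red_projection[y0:y1, x0:x1]) - background, 0)
}

#' Background red level outside all ROIs
#'
#' Median of the red pixels lying outside every ROI square; if the squares
#' cover the whole frame, the global median is used.
#'
#' @param red_projection 2D matrix of projected red intensities.
#' @param rois list of `neuromast_roi`.
#' @return scalar background level in camera counts.
#' @export
roi_background <- function(red_projection, rois) {
  if (!length(rois)) return(median(red_projection))
  mask <- matrix(TRUE, nrow(red_projection), ncol(red_projection))
  for (r in rois) mask[r$y0:r$y1, r$x0:r$x1] <- FALSE
  if (!any(mask)) return(median(red_projection))
  median(red_projection[mask])
}

.new_measurement <- function(larva_id, condition, mode, roi_scores,
                             inflammation_score, band_count, n_rois,
                             orientation_ok, data_producing) {
  structure(list(larva_id = larva_id, condition = condition, mode = mode,
                 roi_scores = roi_scores,
                 inflammation_score = inflammation_score,
                 band_count = band_count, n_rois = n_rois,
                 qc = list(orientation_ok = orientation_ok,
                           data_producing = data_producing)),
            class = "larva_measurement")
}

#' @export
print.larva_measurement <- function(x, ...) {
  cat(sprintf("<larva_measurement> %s [%s] mode=%s: score=%s, band_count=%s, n_rois=%d, orientation_ok=%s, data_producing=%s\n",
              x$larva_id, x$condition, x$mode,
              ifelse(is.na(x$inflammation_score), "NA",
                     sprintf("%.2f", x$inflammation_score)),
              ifelse(is.na(x$band_count), "NA", x$band_count),
              x$n_rois, x$qc$orientation_ok, x$qc$data_producing))
  invisible(x)
}

#' @export
as.data.frame.larva_measurement <- function(x, ...) {
  data.frame(larva_id = x$larva_id, condition = x$condition, mode = x$mode,
             n_rois = x$n_rois, inflammation_score = x$inflammation_score,
             band_count = x$band_count,
             orientation_ok = x$qc$orientation_ok,
             data_producing = x$qc$data_producing,
             stringsAsFactors = FALSE)
}

#' Intensity-mode larva score
#'
#' Computes [roi_red_intensity()] for every detected neuromast ROI (with a
#' shared per-larva background from [roi_background()]) and averages the
#' per-square scores into the larva's inflammation score. Larvae with zero
#' ROIs are flagged not data-producing and receive no score.
#'
#' @param red_projection 2D matrix of projected red intensities.
#' @param rois list of `neuromast_roi` from [detect_neuromasts()].
#' @param orientation_ok larva mounting QC flag (from the plate's manual
#'   check or the simulator's ground truth).
#' @param larva_id,condition identifiers carried into the measurement.
#' @return a `larva_measurement` (mode `"intensity"`).
#' @export
score_larva_intensity <- function(red_projection, rois,
                                  orientation_ok = TRUE,
                                  larva_id = NA_character_,
                                  condition = NA_character_) {
  if (!larva_is_data_producing(rois))
    return(.new_measurement(larva_id, condition, "intensity",
                            numeric(0), NA_real_, NA_integer_, 0L,
                            orientation_ok, FALSE))
  bg <- roi_background(red_projection, rois)
  scores <- vapply(rois, function(r)
    roi_red_intensity(red_projection, r, bg), numeric(1))
  .new_measurement(larva_id, condition, "intensity", scores, mean(scores),
                   NA_integer_, length(rois), orientation_ok, TRUE)
}

#' Spot-detection parameters for count mode
#'
#' @param sigma difference-of-Gaussians inner sigma (px), matched to the
#'   leukocyte spot width.
#' @param ratio outer/inner sigma ratio.
#' @param threshold absolute DoG response threshold; `NULL` (default) uses
#'   Otsu's threshold on the positive DoG response.
#' @return an object of class `spot_params`.
#' @export
spot_params <- function(sigma = 2.2, ratio = 1.6, threshold = NULL) {
  if (sigma <= 0 || ratio <= 1) .chin_stop("need sigma > 0 and ratio > 1")
  structure(list(sigma = sigma, ratio = ratio, threshold = threshold),
            class = "spot_params")
}

#' Detect leukocyte spots on the projected red channel
#'
#' Difference-of-Gaussians blob detection with an intensity threshold:
#' local maxima of the DoG response above threshold are reported as spot
#' centroids (plateaus and touching maxima are resolved by connected
#' components, so two cells closer than the resolution limit merge into a
#' single detection — the automated analogue of what an observer counts as
#' one cell).
#'
#' @param red_projection 2D matrix of projected red intensities.
#' @param params a [spot_params()].
#' @return a matrix with columns `x`, `y` (0 rows when nothing is found).
#' @export
detect_leukocyte_spots <- function(red_projection,
                                   params = spot_params()) {
  if (!is.matrix(red_projection) || !all(is.finite(red_projection)))
    .chin_stop("'red_projection' must be a finite-valued 2D matrix")
  stopifnot(inherits(params, "spot_params"))
  none <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  im <- red_projection - median(red_projection)
  im[im < 0] <- 0
  if (max(im) <= 0) return(none)
  dog <- cpp_gauss_blur(im, params$sigma) -
    cpp_gauss_blur(im, params$sigma * params$ratio)
  mx <- max(dog)
  if (mx <= 0) return(none)
  th <- params$threshold %||%
    (EBImage::otsu(EBImage::Image(pmax(dog, 0) / mx), range = c(0, 1)) * mx)

  H <- nrow(dog); W <- ncol(dog)
  # local maxima (>= all 8 neighbours) via shifted comparisons
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- dog
  is_max <- dog > th
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2:(H + 1L)) + dy, (2:(W + 1L)) + dx]
    is_max <- is_max & (dog >= nb)
  }
  if (!any(is_max)) return(none)
  lab <- EBImage::bwlabel(is_max)
  n <- max(lab)
  out <- t(vapply(seq_len(n), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  }, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}

#' Count spots inside the myoseptum band
#'
#' A spot counts when its perpendicular distance to the band axis is at
#' most `half_width` (boundary inclusive) and its projection onto the axis
#' falls within the segment.
#'
#' @param spots matrix with columns `x`, `y` (e.g. from
#'   [detect_leukocyte_spots()]).
#' @param band a [band_spec()].
#' @return integer count.
#' @export
count_in_band <- function(spots, band) {
  stopifnot(inherits(band, "band_spec"))
  if (is.null(spots) || NROW(spots) == 0L) return(0L)
  spots <- as.matrix(spots)
  d <- band$p1 - band$p0
  L <- sqrt(sum(d^2))
  u <- d / L
  wx <- spots[, 1] - band$p0[1]
  wy <- spots[, 2] - band$p0[2]
  t_ax <- wx * u[1] + wy * u[2]
  perp <- abs(wx * (-u[2]) + wy * u[1])
  sum(t_ax >= 0 & t_ax <= L & perp <= band$half_width)
}

#' Count-mode larva score
#'
#' Detects leukocyte spots on the projected red channel and counts those
#' inside the myoseptum band — the automated analogue of the manual assay
#' (counts on one side of the larva, which a 2D projection inherently
#' gives).
#'
#' @param red_projection 2D matrix of projected red intensities.
#' @param band a [band_spec()].
#' @param params a [spot_params()].
#' @param orientation_ok larva mounting QC flag.
#' @param larva_id,condition identifiers carried into the measurement.
#' @return a `larva_measurement` (mode `"count"`).
#' @export
score_larva_count <- function(red_projection, band,
                              params = spot_params(),
                              orientation_ok = TRUE,
                              larva_id = NA_character_,
                              condition = NA_character_) {
  spots <- detect_leukocyte_spots(red_projection, params)
  .new_measurement(larva_id, condition, "count", numeric(0), NA_real_,
                   count_in_band(spots, band), 0L, orientation_ok, TRUE)
}

#' Estimate the myoseptum band from detected neuromast ROIs
#'
#' The primary lateral line sits on the horizontal myoseptum, so a
#' least-squares line through the detected neuromast centroids estimates
#' the band axis; the segment spans the extreme centroids extended by one
#' mean inter-neuromast spacing on each side.
#'
#' @param rois list of at least two `neuromast_roi`.
#' @param half_width band half-width in px.
#' @return a [band_spec()].
#' @export
estimate_band <- function(rois, half_width = 50) {
  if (length(rois) < 2L)
    .chin_stop("need at least two ROIs to estimate the band axis")
  xs <- vapply(rois, function(r) r$centroid[1], numeric(1))
  ys <- vapply(rois, function(r) r$centroid[2], numeric(1))
  fit <- stats::lm.fit(cbind(1, xs), ys)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  ext <- if (length(xs) > 1) mean(diff(sort(xs))) else 0
  x0 <- min(xs) - ext; x1 <- max(xs) + ext
  band_spec(c(x0, a + b * x0), c(x1, a + b * x1), half_width)
}
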