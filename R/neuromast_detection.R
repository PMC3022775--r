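#' Detection parameters for neuromast blob detection
#'
#' The detector finds GFP-labelled neuromast rosettes on the projected
#' green channel. Defaults were tuned on the synthetic generator (the
#' analysis region around a neuromast is an empirical choice, not a
#' measured constant): a 48 px square is roughly three rosette diameters,
#' wide enough to capture infiltrating leukocytes around the organ.
#'
#' @param smoothing_sigma Gaussian smoothing sigma (px) before
#'   thresholding; merges the rosette's cell-spots into one blob.
#' @param threshold_method only `"otsu"` is currently implemented: Otsu's
#'   threshold computed on the log-transformed, background-subtracted,
#'   smoothed image. The log transform makes the cut robust to the wide
#'   brightness range across rosettes (a threshold on the raw scale rides
#'   up on the brightest rosette and misses dim ones).
#' @param split_tolerance watershed tolerance (log-intensity units) used
#'   to split touching blobs into individual rosettes; brightness-scale
#'   invariant because it acts on the log image.
#' @param min_blob_area,max_blob_area area gate in px^2.
#' @param min_circularity minimum `4*pi*A/P^2`; rejects elongated
#'   autofluorescence streaks (neuromasts are compact rosettes).
#' @param roi_side side of the square analysis region (px).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(smoothing_sigma = 3,
                             threshold_method = "otsu",
                             split_tolerance = 0.4,
                             min_blob_area = 40,
                             max_blob_area = 4000,
                             min_circularity = 0.4,
                             roi_side = 48) {
  if (min_blob_area >= max_blob_area)
    .chin_stop("'min_blob_area' must be smaller than 'max_blob_area'")
  if (min_circularity < 0 || min_circularity > 1)
    .chin_stop("'min_circularity' must lie in [0, 1]")
  if (roi_side < 1) .chin_stop("'roi_side' must be positive")
  if (split_tolerance <= 0) .chin_stop("'split_tolerance' must be positive")
  threshold_method <- match.arg(threshold_method, "otsu")
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 split_tolerance = split_tolerance,
                 min_blob_area = min_blob_area,
                 max_blob_area = max_blob_area,
                 min_circularity = min_circularity,
                 roi_side = as.integer(roi_side)),
            class = "detection_params")
}

# Square of side 'side' centred on (cx, cy), clipped/shifted to stay inside
# a W x H frame while keeping its full side length where possible.
.roi_square <- function(cx, cy, side, W, H) {
  half <- side %/% 2L
  x0 <- max(1L, min(round(cx) - half, W - side + 1L))
  y0 <- max(1L, min(round(cy) - half, H - side + 1L))
  x1 <- min(W, x0 + side - 1L)
  y1 <- min(H, y0 + side - 1L)
  c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

.new_roi <- function(cx, cy, side, W, H, score) {
  sq <- .roi_square(cx, cy, side, W, H)
  structure(list(centroid = c(x = cx, y = cy),
                 x0 = sq[["x0"]], y0 = sq[["y0"]],
                 x1 = sq[["x1"]], y1 = sq[["y1"]],
                 area_px = (sq[["x1"]] - sq[["x0"]] + 1L) *
                   (sq[["y1"]] - sq[["y0"]] + 1L),
                 detection_score = score),
            class = "neuromast_roi")
}

#' @export
print.neuromast_roi <- function(x, ...) {
  cat(sprintf("<neuromast_roi> centroid (%.1f, %.1f); square [%d..%d] x [%d..%d]; score %.3g\n",
              x$centroid[1], x$centroid[2], x$x0, x$x1, x$y0, x$y1,
              x$detection_score))
  invisible(x)
}

#' Detect neuromasts on the projected green channel
#'
#' Pipeline: background subtraction (image median) -> Gaussian smoothing ->
#' Otsu threshold on the log-intensity image -> connected components, with
#' touching blobs split by an intensity watershed -> area and circularity
#' gates -> intensity-weighted centroid -> square analysis region of side
#' `roi_side` centred on the centroid (clipped to the frame). The returned
#' list is sorted along the image x-axis (anterior to posterior for a
#' horizontally mounted larva) for deterministic output.
#'
#' @param green_projection 2D matrix of projected green intensities.
#' @param params a [detection_params()].
#' @return (possibly empty) list of `neuromast_roi` objects, with the image
#'   dimensions in attribute `img_dim` (c(H, W)).
#' @export
detect_neuromasts <- function(green_projection,
                              params = detection_params()) {
  if (!is.matrix(green_projection) || !all(is.finite(green_projection)))
    .chin_stop("'green_projection' must be a finite-valued 2D matrix")
  stopifnot(inherits(params, "detection_params"))
  H <- nrow(green_projection); W <- ncol(green_projection)
  empty <- structure(list(), img_dim = c(H, W))

  im <- green_projection - median(green_projection)
  im[im < 0] <- 0
  sm <- if (params$smoothing_sigma > 0)
    cpp_gauss_blur(im, params$smoothing_sigma) else im
  L <- log1p(sm)
  mxL <- max(L)
  if (mxL <= 0) return(empty)
  th <- EBImage::otsu(EBImage::Image(L / mxL), range = c(0, 1)) * mxL
  mask <- L > th
  if (!any(mask)) return(empty)
  lab <- EBImage::imageData(EBImage::watershed(EBImage::Image(L * mask),
                                               tolerance =
                                                 params$split_tolerance,
                                               ext = 1))
  if (max(lab) == 0L) return(empty)
  shape <- EBImage::computeFeatures.shape(lab)
  if (is.null(shape) || nrow(shape) == 0L) return(empty)

  area <- shape[, "s.area"]
  perim <- pmax(shape[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1)
  keep <- which(area >= params$min_blob_area &
                  area <= params$max_blob_area &
                  circ >= params$min_circularity)
  if (!length(keep)) return(empty)

  rois <- lapply(keep, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    wts <- sm[idx]
    cx <- sum(idx[, 2] * wts) / sum(wts)
    cy <- sum(idx[, 1] * wts) / sum(wts)
    .new_roi(cx, cy, params$roi_side, W, H, score = sum(wts))
  })
  rois <- rois[order(vapply(rois, function(r) r$centroid[1], numeric(1)))]
  attr(rois, "img_dim") <- c(H, W)
  rois
}

# Fractional overlap of two ROI squares relative to the smaller square.
.roi_overlap_frac <- function(a, b) {
  ix <- max(0L, min(a$x1, b$x1) - max(a$x0, b$x0) + 1L)
  iy <- max(0L, min(a$y1, b$y1) - max(a$y0, b$y0) + 1L)
  inter <- as.numeric(ix) * iy
  inter / min(a$area_px, b$area_px)
}

#' Merge overlapping neuromast ROIs
#'
#' ROIs whose squares overlap by more than half of the smaller square are
#' merged (transitively) into a single ROI at the detection-score-weighted
#' centroid; the merged square keeps the ROI side length and is re-clipped
#' to the frame.
#'
#' @param rois list of `neuromast_roi` (e.g. from [detect_neuromasts()]).
#' @param img_dim image dimensions `c(H, W)`; defaults to the `img_dim`
#'   attribute attached by the detector.
#' @param min_frac overlap fraction above which ROIs merge (default 0.5).
#' @return list of `neuromast_roi`, never longer than the input.
#' @export
merge_overlapping_rois <- function(rois, img_dim = attr(rois, "img_dim"),
                                   min_frac = 0.5) {
  n <- length(rois)
  if (n <= 1L) return(rois)
  if (is.null(img_dim))
    img_dim <- c(max(vapply(rois, `[[`, 0, "y1")),
                 max(vapply(rois, `[[`, 0, "x1")))
  side <- max(vapply(rois, function(r) r$x1 - r$x0 + 1L, numeric(1)))
  # union-find over the overlap graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (.roi_overlap_frac(rois[[i]], rois[[j]]) > min_frac) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  out <- lapply(groups, function(g) {
    if (length(g) == 1L) return(rois[[g]])
    w <- vapply(rois[g], `[[`, 0, "detection_score")
    if (sum(w) <= 0) w <- rep(1, length(g))
    cx <- sum(vapply(rois[g], function(r) r$centroid[1], 0) * w) / sum(w)
    cy <- sum(vapply(rois[g], function(r) r$centroid[2], 0) * w) / sum(w)
    .new_roi(cx, cy, side, img_dim[2], img_dim[1], score = sum(w))
  })
  out <- out[order(vapply(out, function(r) r$centroid[1], numeric(1)))]
  attr(out, "img_dim") <- img_dim
  out
}

#' Is a larva data-producing?
#'
#' A larva yields data when the software detects at least one neuromast
#' ROI; larvae with none are excluded from scoring and tallied in the QC
#' accounting.
#'
#' @param rois list of `neuromast_roi`.
#' @return logical scalar.
#' @export
larva_is_data_producing <- function(rois) length(rois) >= 1L
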