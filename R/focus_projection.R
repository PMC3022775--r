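#' Autofocus: find the central focal plane of a stack
#'
#' Object-detection autofocus on one channel: each slice is scored by the
#' variance of its Laplacian-of-Gaussian response (the Gaussian
#' pre-smoothing suppresses the per-pixel camera noise, whose Laplacian
#' variance is identical in every slice and would otherwise drown the
#' object signal), and the slice with the highest score wins. Exact ties
#' are broken toward the middle of the stack, so a featureless stack
#' yields its middle slice.
#'
#' @param stack a [zstack()].
#' @param channel channel label (default `"green"`, the neuromast channel).
#' @param smoothing Gaussian pre-smoothing sigma in px (0 disables it).
#' @return a list with `central_plane` (slice index) and `focus_scores`
#'   (one sharpness value per slice).
#' @export
autofocus_central_plane <- function(stack, channel = "green",
                                    smoothing = 2) {
  stopifnot(inherits(stack, "zstack"))
  arr <- zstack_channel(stack, channel)           # H x W x Z
  Z <- dim(arr)[3]
  scores <- vapply(seq_len(Z), function(k) {
    m <- arr[, , k]
    if (!is.matrix(m)) m <- matrix(m, dim(arr)[1], dim(arr)[2])
    if (smoothing > 0) m <- cpp_gauss_blur(m, smoothing)
    .laplacian_var(m)
  }, numeric(1))
  best <- which(scores == max(scores))
  mid <- (Z + 1) / 2
  central <- best[which.min(abs(best - mid))]
  list(central_plane = as.integer(central), focus_scores = scores)
}

# Variance of the 4-neighbour Laplacian over the image interior.
.laplacian_var <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (H < 3 || W < 3) return(0)
  i <- 2:(H - 1); j <- 2:(W - 1)
  lap <- 4 * m[i, j] - m[i - 1, j] - m[i + 1, j] - m[i, j - 1] - m[i, j + 1]
  var(as.numeric(lap))
}

#' Plate-wide focus policy
#'
#' Under the default `"first-well"` policy the autofocus runs on the first
#' well only and its plane index is applied to every well of the plate —
#' the acquisition protocol of the automated assay. The `"per-well"` policy
#' refocuses each well independently.
#'
#' @param stacks a non-empty named list of [zstack()] objects, in well
#'   order.
#' @param policy `"first-well"` (default) or `"per-well"`.
#' @param channel channel used for the sharpness score.
#' @return named integer vector of central plane indices, one per well.
#' @export
plate_focus_policy <- function(stacks, policy = c("first-well", "per-well"),
                               channel = "green") {
  policy <- match.arg(policy)
  if (length(stacks) < 1L) .chin_stop("need at least one well")
  if (policy == "first-well") {
    first <- tryCatch(autofocus_central_plane(stacks[[1]], channel),
                      error = function(e)
                        .chin_stop("autofocus failed on the first well, ",
                                   "cannot set the plate-wide plane: ",
                                   conditionMessage(e)))
    out <- rep(first$central_plane, length(stacks))
  } else {
    out <- vapply(stacks, function(s)
      autofocus_central_plane(s, channel)$central_plane, integer(1))
  }
  names(out) <- names(stacks)
  out
}

#' Extended focus projection of five optical sections
#'
#' Per-pixel maximum-intensity projection of the green and red channels
#' over `min(5, Z)` contiguous slices centred on the focal plane (two in
#' each direction). At stack edges the window is clipped and re-centred so
#' that exactly `min(5, Z)` real slices are always used.
#'
#' @param stack a [zstack()].
#' @param central_plane focal slice index (e.g. from
#'   [autofocus_central_plane()]); defaults to the stack's recorded plane.
#' @param focus_scores optional per-slice sharpness values to carry along.
#' @return an object of class `projection_result`: matrices `green` and
#'   `red`, `central_plane`, `slices_used`, `focus_scores`.
#' @export
extended_focus_project <- function(stack, central_plane = stack$central_plane,
                                   focus_scores = NULL) {
  stopifnot(inherits(stack, "zstack"))
  Z <- .zstack_dim(stack)[2]
  if (is.na(central_plane) || central_plane < 1 || central_plane > Z)
    .chin_stop("'central_plane' must be a slice index in 1..", Z)
  central_plane <- as.integer(central_plane)
  w <- min(5L, Z)
  start <- min(max(central_plane - 2L, 1L), Z - w + 1L)
  slices <- start:(start + w - 1L)
  proj_one <- function(channel)
    cpp_max_project(zstack_channel(stack, channel), slices)
  structure(list(green = proj_one("green"), red = proj_one("red"),
                 central_plane = central_plane, slices_used = slices,
                 focus_scores = focus_scores),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %d x %d px; central plane %d; slices used: %s\n",
              nrow(x$green), ncol(x$green), x$central_plane,
              paste(x$slices_used, collapse = ", ")))
  invisible(x)
}
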