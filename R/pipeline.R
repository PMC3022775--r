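#' Quantify one larva's z-stack
#'
#' Runs the per-well chain: focal-plane selection (autofocus unless a
#' plate-wide plane is supplied) -> five-slice extended focus projection ->
#' neuromast detection and ROI merging -> intensity and/or count scoring.
#'
#' @param stack a [zstack()].
#' @param detection a [detection_params()].
#' @param mode `"intensity"` (default), `"count"`, or `"both"`.
#' @param central_plane optional plate-wide focal plane; `NULL` runs the
#'   autofocus on this stack's green channel.
#' @param band optional [band_spec()] for count mode; `NULL` estimates the
#'   myoseptum axis from the detected ROIs (needs >= 2 ROIs).
#' @param spot a [spot_params()] for count mode.
#' @param orientation_ok larva mounting QC flag.
#' @param larva_id,condition identifiers carried into the measurement.
#' @return a `larva_measurement`; for mode `"both"` the intensity
#'   measurement additionally carries the band count.
#' @export
quantify_stack <- function(stack, detection = detection_params(),
                           mode = c("intensity", "count", "both"),
                           central_plane = NULL, band = NULL,
                           spot = spot_params(), orientation_ok = TRUE,
                           larva_id = NA_character_,
                           condition = NA_character_) {
  mode <- match.arg(mode)
  if (is.null(central_plane))
    central_plane <- autofocus_central_plane(stack, "green")$central_plane
  proj <- extended_focus_project(stack, central_plane)
  rois <- merge_overlapping_rois(detect_neuromasts(proj$green, detection))

  if (mode == "count") {
    if (is.null(band)) {
      if (length(rois) < 2L)
        return(.new_measurement(larva_id, condition, "count", numeric(0),
                                NA_real_, NA_integer_, length(rois),
                                orientation_ok, FALSE))
      band <- estimate_band(rois)
    }
    return(score_larva_count(proj$red, band, spot, orientation_ok,
                             larva_id, condition))
  }
  meas <- score_larva_intensity(proj$red, rois, orientation_ok,
                                larva_id, condition)
  if (mode == "both" && length(rois) >= 2L) {
    b <- band %||% estimate_band(rois)
    spots <- detect_leukocyte_spots(proj$red, spot)
    meas$band_count <- count_in_band(spots, b)
  }
  meas
}

#' Collect larva measurements into a data.frame
#'
#' @param measurements list of `larva_measurement` objects.
#' @return data.frame with one row per larva.
#' @export
measurements_df <- function(measurements) {
  do.call(rbind, lapply(measurements, as.data.frame))
}

#' Quantify a whole plate from its manifest
#'
#' For each well: read the TIFF -> focus -> project -> detect -> score.
#' Under the default `"first-well"` policy the focal plane is determined
#' on the first readable well and applied plate-wide (per replicate).
#' Unreadable wells are logged and skipped rather than fatal, unless more
#' than half the plate fails, which aborts with a summary (a systematically
#' wrong configuration, not a bad well). Orientation QC flags come from a
#' manifest column `orientation_ok` or the `qc` table (e.g. the
#' simulator's ground truth); wells absent from both pass by default.
#'
#' @param manifest a [load_manifest()] result, or a path to a manifest CSV.
#' @param detection a [detection_params()].
#' @param mode `"intensity"`, `"count"`, or `"both"`.
#' @param focus_policy `"first-well"` (default) or `"per-well"`.
#' @param qc optional data.frame with `well_id`, `replicate`,
#'   `orientation_ok`.
#' @param spot a [spot_params()] for count mode.
#' @param band_half_width half-width (px) of the estimated myoseptum band.
#' @param verbose log per-well progress via [message()].
#' @return data.frame of per-larva measurements (one row per readable
#'   well), with attribute `n_failed` counting skipped wells.
#' @export
quantify_plate <- function(manifest, detection = detection_params(),
                           mode = c("intensity", "count", "both"),
                           focus_policy = c("first-well", "per-well"),
                           qc = NULL, spot = spot_params(),
                           band_half_width = 50, verbose = FALSE) {
  mode <- match.arg(mode)
  focus_policy <- match.arg(focus_policy)
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  image_dir <- attr(manifest, "image_dir") %||% "."
  if (!nrow(manifest)) {
    out <- measurements_df(list())
    return(out)
  }

  orient_for <- function(i) {
    if (!is.null(manifest$orientation_ok))
      return(isTRUE(as.logical(manifest$orientation_ok[i])))
    if (!is.null(qc)) {
      j <- which(qc$well_id == manifest$well_id[i] &
                   qc$replicate == manifest$replicate[i])
      if (length(j)) return(isTRUE(as.logical(qc$orientation_ok[j[1]])))
    }
    TRUE
  }

  plane_by_rep <- list()   # plate-wide plane per replicate (first-well)
  rows <- list(); n_failed <- 0L
  for (i in seq_len(nrow(manifest))) {
    fn <- manifest$file[i]
    path <- if (.is_abs_path(fn)) fn else file.path(image_dir, fn)
    wid <- sprintf("rep%s_%s", manifest$replicate[i], manifest$well_id[i])
    res <- tryCatch({
      stack <- read_zstack(path)
      cp <- NULL
      if (focus_policy == "first-well") {
        key <- as.character(manifest$replicate[i])
        if (is.null(plane_by_rep[[key]]))
          plane_by_rep[[key]] <-
            autofocus_central_plane(stack, "green")$central_plane
        cp <- plane_by_rep[[key]]
      }
      quantify_stack(stack, detection, mode, central_plane = cp,
                     spot = spot, orientation_ok = orient_for(i),
                     larva_id = wid, condition = manifest$condition[i])
    }, error = function(e) {
      message("well ", wid, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L
    else rows[[length(rows) + 1L]] <- res
    if (verbose && i %% 24 == 0)
      message("processed ", i, "/", nrow(manifest), " wells")
  }
  if (n_failed > nrow(manifest) / 2)
    .chin_stop(n_failed, " of ", nrow(manifest), " wells unreadable; ",
               "aborting (check the input configuration)")
  out <- measurements_df(rows)
  attr(out, "n_failed") <- n_failed
  out
}

#' Simulate and quantify one condition in memory
#'
#' Convenience wrapper used for power analyses and calibration: generates
#' `n` larvae under one condition, renders their stacks and runs the
#' standard quantification chain without touching disk. The focal plane is
#' determined on the first larva and applied to the rest (the plate
#' protocol).
#'
#' @param params a [scene_params()].
#' @param n number of larvae.
#' @param condition condition label.
#' @param dose treatment dose (default `params$dose`).
#' @param recruit_mean optional direct recruitment mean.
#' @param detection a [detection_params()].
#' @param mode quantification mode.
#' @param apply_orientation_qc if `TRUE` (default) the simulator's
#'   orientation flag is carried into the measurements.
#' @return data.frame of per-larva measurements.
#' @export
simulate_condition <- function(params, n, condition = "control",
                               dose = params$dose, recruit_mean = NULL,
                               detection = detection_params(),
                               mode = "intensity",
                               apply_orientation_qc = TRUE) {
  rows <- vector("list", n)
  plane <- NULL
  for (i in seq_len(n)) {
    larva <- generate_larva(params, condition, dose, recruit_mean)
    stack <- render_zstack(larva, params)
    if (is.null(plane))
      plane <- autofocus_central_plane(stack, "green")$central_plane
    rows[[i]] <- quantify_stack(
      stack, detection, mode, central_plane = plane,
      orientation_ok = if (apply_orientation_qc) larva$orientation_ok
        else TRUE,
      larva_id = sprintf("%s_%03d", condition, i), condition = condition)
  }
  measurements_df(rows)
}
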