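#' Scene parameters for the synthetic larva generator
#'
#' Bundles every tunable of the simulator: larva geometry, neuromast and
#' leukocyte rendering, the recruitment model (how many leukocytes cluster at
#' each neuromast under treatment), mounting/orientation statistics and the
#' camera model. Defaults emulate the acquisition setup of the automated
#' assay: a 1300 x 1024 px field of view, 9 optical sections, a 16-bit
#' camera, and a larva whose primary lateral line carries 7 regularly spaced
#' neuromasts on the horizontal myoseptum.
#'
#' Recruitment under treatment follows a saturating dose-response
#' `recruit(dose) = recruit_rmax * dose / (dose + recruit_k50)`, which is 0
#' at dose 0 and non-decreasing; `recruit_mean` (when non-NULL) bypasses the
#' curve and fixes the expected number of recruited leukocytes per neuromast
#' directly.
#'
#' @param n_neuromasts number of posterior lateral-line neuromasts (5-9).
#' @param neuromast_radius rosette radius in px; rendered as a ring of 8
#'   cell-spots at this radius.
#' @param neuromast_cell_sigma Gaussian width (px) of one rosette cell.
#' @param neuromast_peak median in-focus peak brightness (camera counts) of a
#'   rosette cell; per-rosette brightness is lognormal with
#'   `neuromast_peak_sdlog`.
#' @param neuromast_peak_sdlog lognormal spread of rosette brightness.
#' @param leukocyte_sigma Gaussian width (px) of a leukocyte spot.
#' @param leukocyte_peak median in-focus leukocyte peak (camera counts).
#' @param leukocyte_peak_sdlog lognormal spread of leukocyte brightness.
#' @param recruit_mean expected recruited leukocytes per neuromast, or NULL
#'   to derive it from `dose` via the saturating curve.
#' @param baseline_count expected leukocytes in the ventral/posterior
#'   baseline pool (the caudal haematopoietic territory) per larva.
#' @param dose default treatment concentration surrogate (arbitrary
#'   units, non-negative).
#' @param recruit_rmax,recruit_k50 saturating dose-response parameters.
#' @param lateral_orientation_prob probability a larva is mounted laterally
#'   and therefore scoreable.
#' @param noise_sd additive Gaussian camera noise (counts).
#' @param offset camera baseline offset (counts).
#' @param psf_sigma in-focus blur sigma (px).
#' @param defocus_sigma_per_slice extra blur sigma per z-step away from the
#'   focal plane (px).
#' @param img_width,img_height image size in px.
#' @param n_slices default number of optical sections (odd, >= 5).
#' @param body_half_height half-height of the body silhouette (px); default
#'   `img_height / 6`.
#' @return an object of class `scene_params` (a validated list).
#' @export
scene_params <- function(n_neuromasts = 7,
                         neuromast_radius = 8,
                         neuromast_cell_sigma = 3,
                         neuromast_peak = 2200,
                         neuromast_peak_sdlog = 0.35,
                         leukocyte_sigma = 3,
                         leukocyte_peak = 3000,
                         leukocyte_peak_sdlog = 0.3,
                         recruit_mean = NULL,
                         baseline_count = 10,
                         dose = 0,
                         recruit_rmax = 8,
                         recruit_k50 = 2,
                         lateral_orientation_prob = 0.75,
                         noise_sd = 50,
                         offset = 100,
                         psf_sigma = 1,
                         defocus_sigma_per_slice = 1.5,
                         img_width = 1300,
                         img_height = 1024,
                         n_slices = 9,
                         body_half_height = NULL) {
  p <- list(
    n_neuromasts = as.integer(n_neuromasts),
    neuromast_radius = neuromast_radius,
    neuromast_cell_sigma = neuromast_cell_sigma,
    neuromast_peak = neuromast_peak,
    neuromast_peak_sdlog = neuromast_peak_sdlog,
    leukocyte_sigma = leukocyte_sigma,
    leukocyte_peak = leukocyte_peak,
    leukocyte_peak_sdlog = leukocyte_peak_sdlog,
    recruit_mean = recruit_mean,
    baseline_count = baseline_count,
    dose = dose,
    recruit_rmax = recruit_rmax,
    recruit_k50 = recruit_k50,
    lateral_orientation_prob = lateral_orientation_prob,
    noise_sd = noise_sd,
    offset = offset,
    psf_sigma = psf_sigma,
    defocus_sigma_per_slice = defocus_sigma_per_slice,
    img_width = as.integer(img_width),
    img_height = as.integer(img_height),
    n_slices = as.integer(n_slices),
    body_half_height = body_half_height %||% (img_height / 6)
  )
  if (p$dose < 0) .chin_stop("'dose' must be non-negative")
  if (p$lateral_orientation_prob < 0 || p$lateral_orientation_prob > 1)
    .chin_stop("'lateral_orientation_prob' must lie in [0, 1]")
  if (p$n_neuromasts < 1) .chin_stop("'n_neuromasts' must be >= 1")
  if (p$baseline_count < 0) .chin_stop("'baseline_count' must be >= 0")
  if (p$noise_sd < 0) .chin_stop("'noise_sd' must be >= 0")
  if (p$recruit_rmax < 0 || p$recruit_k50 <= 0)
    .chin_stop("dose-response parameters must be positive")
  if (!is.null(p$recruit_mean) && p$recruit_mean < 0)
    .chin_stop("'recruit_mean' must be >= 0")
  class(p) <- "scene_params"
  p
}

#' Expected recruited leukocytes per neuromast at a given dose
#'
#' Saturating dose-response `rmax * dose / (dose + k50)`; 0 at dose 0 and
#' non-decreasing in dose. `params$recruit_mean`, when set, overrides the
#' curve.
#'
#' @param params a [scene_params()] object.
#' @param dose treatment concentration surrogate (>= 0).
#' @return expected recruited leukocytes per neuromast.
#' @export
recruit_mean_at <- function(params, dose = params$dose) {
  if (any(dose < 0)) .chin_stop("'dose' must be non-negative")
  if (!is.null(params$recruit_mean)) return(rep(params$recruit_mean,
                                                length(dose)))
  params$recruit_rmax * dose / (dose + params$recruit_k50)
}

#' Generate one synthetic larva with ground truth
#'
#' Draws a larva model: a myoseptum axis (horizontal when the larva is
#' mounted laterally; rotated and foreshortened when mounted unfavourably),
#' regularly spaced neuromasts on that axis, and leukocytes. Leukocytes
#' always include a Poisson(`baseline_count`) pool in a ventral/posterior
#' stripe below the myoseptum (where myeloid cells reside in untreated
#' larvae); under treatment (`dose > 0` or an explicit `recruit_mean`) each
#' neuromast additionally attracts Poisson(recruitment mean) cells placed
#' within `2 * neuromast_radius` of its centre. Whether the larva is
#' scoreable is drawn Bernoulli(`lateral_orientation_prob`).
#'
#' @param params a [scene_params()] object.
#' @param condition condition label carried into the ground truth.
#' @param dose treatment dose; defaults to `params$dose`.
#' @param recruit_mean optional direct recruitment mean, overriding the
#'   dose-response curve.
#' @return an object of class `larva_model`: body axis (`p0`, `p1`),
#'   `body_half_height`, `neuromast_centers` (n x 2 matrix of x, y),
#'   `neuromast_peaks`, `neuromast_radius`, `leukocytes` (data.frame with
#'   x, y, peak, radius, recruited), `orientation_ok`, `condition`, `dose`.
#' @export
generate_larva <- function(params = scene_params(), condition = "control",
                           dose = params$dose, recruit_mean = NULL) {
  stopifnot(inherits(params, "scene_params"))
  if (dose < 0) .chin_stop("'dose' must be non-negative")
  W <- params$img_width; H <- params$img_height
  lambda <- if (!is.null(recruit_mean)) {
    if (recruit_mean < 0) .chin_stop("'recruit_mean' must be >= 0")
    recruit_mean
  } else {
    recruit_mean_at(params, dose)
  }

  orientation_ok <- runif(1) < params$lateral_orientation_prob

  # Myoseptum axis: horizontal through mid-height for lateral mounts,
  # rotated/foreshortened for unfavourable mounts.
  cy <- H / 2 + runif(1, -0.05, 0.05) * H
  x0 <- 0.12 * W; x1 <- 0.90 * W
  cx <- (x0 + x1) / 2; halflen <- (x1 - x0) / 2
  if (orientation_ok) {
    theta <- 0
  } else {
    theta <- sample(c(-1, 1), 1) * runif(1, 15, 40) * pi / 180
    halflen <- halflen * cos(theta)  # foreshortening of the tilted body
  }
  u <- c(cos(theta), sin(theta))           # unit vector along the axis
  v <- c(-sin(theta), cos(theta))          # unit normal, +v is ventral
  p0 <- c(cx, cy) - halflen * u
  p1 <- c(cx, cy) + halflen * u
  axis_len <- 2 * halflen

  # Neuromasts: regular spacing with small jitter. The anatomical spacing
  # (on a laterally mounted larva) must stay >= 4 * radius; a tilted body
  # appears foreshortened in projection, which may crowd them further —
  # that is the pathology the orientation QC exists to exclude.
  n <- params$n_neuromasts
  spacing_lateral <- (x1 - x0) / n
  if (spacing_lateral * (1 - 2 * 0.04) < 4 * params$neuromast_radius)
    .chin_stop("image too small: neuromast spacing fell below 4 * radius; ",
               "enlarge the image or reduce 'n_neuromasts'")
  spacing <- axis_len / n
  tpos <- (seq_len(n) - 0.5) * spacing + runif(n, -0.04, 0.04) * spacing
  perp <- runif(n, -1, 1)                  # within 1 px of the axis
  centers <- cbind(p0[1] + tpos * u[1] + perp * v[1],
                   p0[2] + tpos * u[2] + perp * v[2])
  peaks <- rlnorm(n, log(params$neuromast_peak), params$neuromast_peak_sdlog)

  # Leukocytes: ventral/posterior baseline pool ...
  n_base <- rpois(1, params$baseline_count)
  lx <- numeric(0); ly <- numeric(0); recruited <- logical(0)
  if (n_base > 0) {
    t_b <- runif(n_base, 0.35, 1) * axis_len
    # resident cells sit clearly below the myoseptum: at least 2.5 rosette
    # radii away, so controls show only occasional cells near neuromasts
    d_b <- pmax(runif(n_base, 0.3, 0.95) * params$body_half_height,
                2.5 * params$neuromast_radius)
    lx <- p0[1] + t_b * u[1] + d_b * v[1]
    ly <- p0[2] + t_b * u[2] + d_b * v[2]
    recruited <- rep(FALSE, n_base)
  }
  # ... plus, under treatment, Poisson(lambda) cells within 2r per neuromast.
  if (lambda > 0) {
    for (i in seq_len(n)) {
      k <- rpois(1, lambda)
      if (k == 0) next
      ang <- runif(k, 0, 2 * pi)
      rad <- 2 * params$neuromast_radius * sqrt(runif(k))
      lx <- c(lx, centers[i, 1] + rad * cos(ang))
      ly <- c(ly, centers[i, 2] + rad * sin(ang))
      recruited <- c(recruited, rep(TRUE, k))
    }
  }
  n_leu <- length(lx)
  leu <- data.frame(
    x = pmin(pmax(lx, 2), W - 1),
    y = pmin(pmax(ly, 2), H - 1),
    peak = if (n_leu) rlnorm(n_leu, log(params$leukocyte_peak),
                             params$leukocyte_peak_sdlog) else numeric(0),
    radius = rep(params$leukocyte_sigma, n_leu),
    recruited = recruited
  )

  structure(list(
    p0 = p0, p1 = p1,
    body_half_height = params$body_half_height,
    neuromast_centers = centers,
    neuromast_peaks = peaks,
    neuromast_radius = params$neuromast_radius,
    leukocytes = leu,
    orientation_ok = orientation_ok,
    condition = condition,
    dose = dose,
    img_width = W, img_height = H
  ), class = "larva_model")
}

#' @export
print.larva_model <- function(x, ...) {
  cat(sprintf(
    "<larva_model> condition=%s dose=%g | %d neuromasts, %d leukocytes (%d recruited), orientation_ok=%s\n",
    x$condition, x$dose, nrow(x$neuromast_centers), nrow(x$leukocytes),
    sum(x$leukocytes$recruited), x$orientation_ok))
  invisible(x)
}

# Render one fluorescence channel slice: Gaussian spots with slice-dependent
# blur. 'sigma0' is the ideal (pre-psf) spot width; amplitudes are given as
# in-focus peaks and rescaled so flux is conserved across slices.
.render_spot_slice <- function(H, W, x, y, sigma0, peak_infocus,
                               psf_sigma, blur_k, offset) {
  img <- matrix(offset, H, W)
  if (length(x)) {
    s_in <- sqrt(sigma0^2 + psf_sigma^2)     # rendered in-focus width
    s_k <- sqrt(sigma0^2 + blur_k^2)         # rendered width in this slice
    amp <- peak_infocus * (s_in^2) / (s_k^2)
    cpp_add_spots(img, as.numeric(x), as.numeric(y),
                  rep(s_k, length(x)), rep_len(amp, length(x)), trunc = 4)
  }
  img
}

# Body-frame pixel coordinates for the silhouette, computed once per stack:
# along-axis (t) and signed normal (v) distance of every pixel, or the 1D
# grids when the body is axis-aligned (separable case).
.brightfield_geom <- function(larva, H, W) {
  d <- larva$p1 - larva$p0
  L <- sqrt(sum(d^2))
  u <- d / L
  if (abs(u[2]) < 1e-12) {
    list(separable = TRUE, L = L,
         tx = seq_len(W) - larva$p0[1],
         dv = seq_len(H) - larva$p0[2],
         hh = larva$body_half_height)
  } else {
    v <- c(-u[2], u[1])
    xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    ys <- matrix(seq_len(H), H, W)
    txi <- as.integer(round((xs - larva$p0[1]) * u[1] +
                              (ys - larva$p0[2]) * u[2]))
    dvi <- as.integer(round((xs - larva$p0[1]) * v[1] +
                              (ys - larva$p0[2]) * v[2]))
    list(separable = FALSE, L = L,
         txi = txi, tlo = min(txi), thi = max(txi),
         dvi = dvi, vlo = min(dvi), vhi = max(dvi),
         hh = larva$body_half_height)
  }
}

# Blurred body silhouette for the bright-field channel: product of
# smoothed-step (erf) ramps in the body frame — the analytic blur of a
# rectangle. For tilted bodies the ramps are read from 1-px lookup tables
# over the precomputed body-frame coordinates.
.render_brightfield <- function(geom, blur_sigma, H, W,
                                bg = 30000, body = 22000) {
  s <- max(blur_sigma, 0.5)
  if (geom$separable) {
    fx <- stats::pnorm(geom$tx / s) - stats::pnorm((geom$tx - geom$L) / s)
    fy <- stats::pnorm((geom$dv + geom$hh) / s) -
      stats::pnorm((geom$dv - geom$hh) / s)
    memb <- outer(fy, fx)
  } else {
    gt <- geom$tlo:geom$thi
    tab_t <- stats::pnorm(gt / s) - stats::pnorm((gt - geom$L) / s)
    gv <- geom$vlo:geom$vhi
    tab_v <- stats::pnorm((gv + geom$hh) / s) -
      stats::pnorm((gv - geom$hh) / s)
    memb <- matrix(tab_t[geom$txi - geom$tlo + 1L] *
                     tab_v[geom$dvi - geom$vlo + 1L], H, W)
  }
  bg - (bg - body) * memb
}

#' Render a three-channel z-stack from a larva model
#'
#' Produces the image data the microscope would have captured: a
#' bright-field body silhouette, a green channel with one Gaussian rosette
#' (ring of 8 cell-spots) per neuromast, and a red channel with one Gaussian
#' spot per leukocyte. Slice `k` carries blur
#' `psf_sigma + |k - central| * defocus_sigma_per_slice`, applied
#' analytically to the Gaussian scene (flux-conserving), plus additive
#' Gaussian camera noise and the camera offset. The central slice is
#' recorded in the stack metadata.
#'
#' @param larva a [generate_larva()] model.
#' @param params a [scene_params()] object.
#' @param n_slices number of optical sections; odd, >= 5.
#' @return a [zstack()] with channels brightfield, green, red.
#' @export
render_zstack <- function(larva, params = scene_params(),
                          n_slices = params$n_slices) {
  stopifnot(inherits(larva, "larva_model"))
  n_slices <- as.integer(n_slices)
  if (n_slices < 5 || n_slices %% 2L == 0L)
    .chin_stop("'n_slices' must be an odd number >= 5")
  H <- larva$img_height; W <- larva$img_width
  central <- (n_slices + 1L) %/% 2L

  # rosette cell positions: ring of 8 around each neuromast centre
  n_nm <- nrow(larva$neuromast_centers)
  ang <- lapply(seq_len(n_nm), function(i) 2 * pi * (0:7) / 8 + 0.3 * i)
  gx <- unlist(lapply(seq_len(n_nm), function(i)
    larva$neuromast_centers[i, 1] + larva$neuromast_radius * cos(ang[[i]])))
  gy <- unlist(lapply(seq_len(n_nm), function(i)
    larva$neuromast_centers[i, 2] + larva$neuromast_radius * sin(ang[[i]])))
  gpk <- rep(larva$neuromast_peaks, each = 8)

  geom <- .brightfield_geom(larva, H, W)
  data <- lapply(1:3, function(ch) array(0, dim = c(H, W, n_slices)))
  for (k in seq_len(n_slices)) {
    b_k <- params$psf_sigma +
      abs(k - central) * params$defocus_sigma_per_slice
    bf <- .render_brightfield(geom, b_k, H, W)
    green <- .render_spot_slice(H, W, gx, gy, params$neuromast_cell_sigma,
                                gpk, params$psf_sigma, b_k, params$offset)
    red <- .render_spot_slice(H, W, larva$leukocytes$x, larva$leukocytes$y,
                              params$leukocyte_sigma, larva$leukocytes$peak,
                              params$psf_sigma, b_k, params$offset)
    cpp_noise_clamp(bf, params$noise_sd, .noise_seed(), 0, CAMERA_MAX)
    cpp_noise_clamp(green, params$noise_sd, .noise_seed(), 0, CAMERA_MAX)
    cpp_noise_clamp(red, params$noise_sd, .noise_seed(), 0, CAMERA_MAX)
    data[[1]][, , k] <- bf
    data[[2]][, , k] <- green
    data[[3]][, , k] <- red
  }
  zstack(data, central_plane = central)
}

#' Plate layout for the synthetic screen
#'
#' @param conditions data.frame with columns `condition` and `dose`
#'   (optionally `recruit_mean` to override the dose-response curve, e.g.
#'   for a drug-suppression scenario).
#' @param larvae_per_condition larvae imaged per condition per plate
#'   (default 24, one larva per well of a 384-well plate).
#' @param replicates number of replicate plates (default 3).
#' @param plate_format number of wells per plate (default 384).
#' @return an object of class `plate_layout`.
#' @export
plate_layout <- function(conditions, larvae_per_condition = 24,
                         replicates = 3, plate_format = 384) {
  if (is.character(conditions))
    conditions <- data.frame(condition = conditions,
                             dose = c(0, rep(10, length(conditions) - 1)))
  stopifnot(is.data.frame(conditions), "condition" %in% names(conditions))
  if (is.null(conditions$dose)) conditions$dose <- 0
  if (any(conditions$dose < 0)) .chin_stop("'dose' must be non-negative")
  if (anyDuplicated(conditions$condition))
    .chin_stop("condition labels must be unique")
  n_wells <- nrow(conditions) * larvae_per_condition
  if (n_wells > plate_format)
    .chin_stop("layout needs ", n_wells, " wells but the plate has only ",
               plate_format)
  structure(list(conditions = conditions,
                 larvae_per_condition = as.integer(larvae_per_condition),
                 replicates = as.integer(replicates),
                 plate_format = as.integer(plate_format)),
            class = "plate_layout")
}

# 384-well ids: rows A..P, columns 1..24, filled row-major.
.well_ids <- function(n, plate_format = 384) {
  ncol <- if (plate_format == 96) 12L else 24L
  rows <- LETTERS[((seq_len(n) - 1L) %/% ncol) + 1L]
  cols <- ((seq_len(n) - 1L) %% ncol) + 1L
  sprintf("%s%02d", rows, cols)
}

# Deterministic per-well seed derived from the plate seed; wells never
# perturb one another, so adding wells leaves earlier wells unchanged.
.well_seed <- function(seed, replicate, well_index) {
  (as.numeric(seed) * 1009 + replicate * 131071 + well_index * 7919) %%
    2147483647 + 1
}

#' Generate a full synthetic plate on disk
#'
#' Writes one multi-page TIFF z-stack per occupied well (page order
#' channel-major: all bright-field, all green, all red), a plate manifest
#' CSV (`well_id, file, condition, dose, replicate, seed`), a ground-truth
#' CSV with one row per larva (true counts, orientation flag) and a JSON
#' sidecar with per-cell coordinates. Fully reproducible from `seed`.
#'
#' @param layout a [plate_layout()].
#' @param params a [scene_params()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the whole plate set.
#' @return invisibly, a list with `manifest` and `ground_truth` data.frames
#'   (also written to `manifest.csv`, `ground_truth.csv`,
#'   `ground_truth_cells.json` under `out_dir`).
#' @export
generate_plate <- function(layout, params = scene_params(), out_dir,
                           seed = 1) {
  stopifnot(inherits(layout, "plate_layout"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    .chin_stop("cannot create output directory: ", out_dir)

  conds <- layout$conditions
  man <- list(); gt <- list(); cells <- list()
  for (rep_i in seq_len(layout$replicates)) {
    well_idx <- 0L
    n_wells_rep <- nrow(conds) * layout$larvae_per_condition
    ids <- .well_ids(max(n_wells_rep, 1L), layout$plate_format)
    for (ci in seq_len(nrow(conds))) {
      for (li in seq_len(layout$larvae_per_condition)) {
        well_idx <- well_idx + 1L
        wid <- ids[well_idx]
        wseed <- .well_seed(seed, rep_i, well_idx)
        set.seed(wseed)
        rm_i <- if (!is.null(conds$recruit_mean) &&
                    !is.na(conds$recruit_mean[ci]))
          conds$recruit_mean[ci] else NULL
        larva <- generate_larva(params, condition = conds$condition[ci],
                                dose = conds$dose[ci], recruit_mean = rm_i)
        stack <- render_zstack(larva, params)
        fn <- file.path(sprintf("rep%d", rep_i), paste0(wid, ".tif"))
        dir.create(file.path(out_dir, dirname(fn)), showWarnings = FALSE)
        write_zstack(stack, file.path(out_dir, fn))
        man[[length(man) + 1L]] <- data.frame(
          well_id = wid, file = fn, condition = conds$condition[ci],
          dose = conds$dose[ci], replicate = rep_i, seed = wseed)
        gt[[length(gt) + 1L]] <- data.frame(
          well_id = wid, replicate = rep_i,
          condition = conds$condition[ci], dose = conds$dose[ci],
          n_neuromasts = nrow(larva$neuromast_centers),
          n_leukocytes = nrow(larva$leukocytes),
          n_recruited = sum(larva$leukocytes$recruited),
          orientation_ok = larva$orientation_ok)
        cells[[paste0("rep", rep_i, "_", wid)]] <- list(
          neuromasts = unname(apply(larva$neuromast_centers, 1, c,
                                    simplify = FALSE)),
          leukocytes = larva$leukocytes[, c("x", "y", "peak")])
      }
    }
  }
  manifest <- if (length(man)) do.call(rbind, man) else
    data.frame(well_id = character(), file = character(),
               condition = character(), dose = numeric(),
               replicate = integer(), seed = numeric())
  ground_truth <- if (length(gt)) do.call(rbind, gt) else
    data.frame(well_id = character(), replicate = integer(),
               condition = character(), dose = numeric(),
               n_neuromasts = integer(), n_leukocytes = integer(),
               n_recruited = integer(), orientation_ok = logical())
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  jsonlite::write_json(cells, file.path(out_dir, "ground_truth_cells.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, ground_truth = ground_truth))
}
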