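#' In-memory z-stack container
#'
#' A three-channel z-stack in camera counts: `data` is a
#' `3 x Z x H x W` array, channel order bright-field, green (GFP
#' neuromasts), red (DsRED2 leukocytes). Pixel size and z-spacing are kept
#' as explicit `NA` ("unknown") when the source file carries no calibration
#' tags; geometry is then in pixel units.
#'
#' @param data either a list of three `H x W x Z` arrays (one per channel,
#'   the internal storage) or a numeric array of dim `c(3, Z, H, W)`.
#' @param channel_names three ordered channel labels.
#' @param pixel_size,z_spacing micrometres, or `NA` if unknown.
#' @param central_plane focal slice index, or `NA` if not yet determined.
#' @return an object of class `zstack`.
#' @export
zstack <- function(data,
                   channel_names = c("brightfield", "green", "red"),
                   pixel_size = NA_real_, z_spacing = NA_real_,
                   central_plane = NA_integer_) {
  if (length(channel_names) != 3L)
    .chin_stop("'channel_names' must have exactly 3 entries")
  if (is.array(data) && length(dim(data)) == 4L) {
    d <- dim(data)
    if (d[1] != 3L) .chin_stop("'data' must be a 3 x Z x H x W array")
    data <- lapply(1:3, function(ch)
      aperm(array(data[ch, , , ], d[2:4]), c(2, 3, 1)))
  }
  if (!is.list(data) || length(data) != 3L)
    .chin_stop("'data' must be a list of three H x W x Z channel arrays")
  data <- lapply(data, function(a) {
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    if (length(dim(a)) != 3L)
      .chin_stop("each channel must be an H x W x Z array")
    a
  })
  dims <- vapply(data, dim, integer(3))
  if (any(dims != dims[, 1]))
    .chin_stop("all channels must share the same H x W x Z dimensions")
  if (dims[3, 1] < 1L) .chin_stop("a zstack needs at least one slice")
  names(data) <- channel_names
  structure(list(data = data, channel_names = channel_names,
                 pixel_size = pixel_size, z_spacing = z_spacing,
                 central_plane = central_plane),
            class = "zstack")
}

# c(channels = 3, Z, H, W)
.zstack_dim <- function(stack) {
  d <- dim(stack$data[[1]])
  c(3L, d[3], d[1], d[2])
}

#' @export
print.zstack <- function(x, ...) {
  d <- .zstack_dim(x)
  cat(sprintf("<zstack> %d channels (%s) x %d slices x %d x %d px; central plane: %s\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3],
              d[4], ifelse(is.na(x$central_plane), "unknown",
                           x$central_plane)))
  invisible(x)
}

#' Extract one channel of a z-stack
#'
#' @param stack a [zstack()].
#' @param channel channel label or index.
#' @param slice optional slice index; if given a single `H x W` matrix is
#'   returned, otherwise the channel's `H x W x Z` array.
#' @return matrix or array of intensities in camera counts.
#' @export
zstack_channel <- function(stack, channel, slice = NULL) {
  stopifnot(inherits(stack, "zstack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) .chin_stop("unknown channel '", channel, "'; have: ",
                               paste(stack$channel_names, collapse = ", "))
  } else idx <- as.integer(channel)
  arr <- stack$data[[idx]]
  if (is.null(slice)) arr else arr[, , slice]
}

#' Write a z-stack as a multi-page 16-bit TIFF
#'
#' Page order is channel-major: all bright-field slices, then all green,
#' then all red. Intensities are rounded to integers and clipped to the
#' 16-bit range; the write -> read round trip is lossless for
#' integer-valued data.
#'
#' @param stack a [zstack()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  d <- .zstack_dim(stack)
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    m <- round(stack$data[[ch]][, , z])
    m[m < 0] <- 0; m[m > CAMERA_MAX] <- CAMERA_MAX
    pages[[i]] <- m / CAMERA_MAX
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "none")
  if (!ok[1] && length(pages)) .chin_stop("failed to write TIFF: ", path)
  invisible(path)
}

#' Read a multi-page TIFF into a z-stack
#'
#' The page count must be divisible by 3; pages are de-interleaved
#' channel-major by default (all pages of channel 1, then channel 2, then
#' channel 3), matching [write_zstack()]. Calibration metadata absent from
#' the file is reported as `NA` (unknown), never silently defaulted.
#'
#' @param path TIFF file path.
#' @param channel_names labels for the three channels, in file page order.
#' @param interleaved if `TRUE`, pages alternate channels per slice
#'   (c1z1, c2z1, c3z1, c1z2, ...) instead of the channel-major default.
#' @return a [zstack()].
#' @export
read_zstack <- function(path,
                        channel_names = c("brightfield", "green", "red"),
                        interleaved = FALSE) {
  if (!file.exists(path)) .chin_stop("cannot read TIFF: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      .chin_stop("failed to read TIFF '", path, "': ",
                                 conditionMessage(e)))
  n <- length(pages)
  if (n == 0L || n %% 3L != 0L)
    .chin_stop("file '", path, "' has ", n,
               " pages; expected a multiple of 3 (three channels)")
  Z <- n %/% 3L
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  data <- lapply(1:3, function(ch) array(0, dim = c(H, W, Z)))
  for (i in seq_len(n)) {
    if (nrow(pages[[i]]) != H || ncol(pages[[i]]) != W)
      .chin_stop("file '", path, "' has pages of differing size")
    if (interleaved) {
      ch <- ((i - 1L) %% 3L) + 1L; z <- ((i - 1L) %/% 3L) + 1L
    } else {
      ch <- ((i - 1L) %/% Z) + 1L; z <- ((i - 1L) %% Z) + 1L
    }
    data[[ch]][, , z] <- pages[[i]]
  }
  zstack(data, channel_names = channel_names)
}

#' Load and validate a plate manifest
#'
#' Required columns: `well_id`, `file`, `condition`, `dose`, `replicate`
#' (`seed` and `orientation_ok` are optional). Doses must be non-negative
#' numbers; `(replicate, well_id)` pairs must be unique (well ids repeat
#' across replicate plates); every referenced image file must exist
#' relative to the manifest's directory (or absolutely).
#'
#' @param path manifest CSV path.
#' @param check_files if `FALSE`, skip the file-existence check.
#' @return a data.frame of class `plate_manifest` with an `image_dir`
#'   attribute.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) .chin_stop("no such manifest: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("well_id", "file", "condition", "dose", "replicate")
  missing <- setdiff(required, names(m))
  if (length(missing))
    .chin_stop("manifest is missing required column(s): ",
               paste(missing, collapse = ", "))
  m$dose <- suppressWarnings(as.numeric(m$dose))
  if (anyNA(m$dose) && nrow(m)) .chin_stop("manifest 'dose' must be numeric")
  if (any(m$dose < 0, na.rm = TRUE))
    .chin_stop("manifest 'dose' must be non-negative")
  key <- paste(m$replicate, m$well_id, sep = "/")
  if (anyDuplicated(key))
    .chin_stop("duplicate well id(s) in manifest: ",
               paste(unique(key[duplicated(key)]), collapse = ", "))
  image_dir <- dirname(normalizePath(path))
  if (check_files && nrow(m)) {
    full <- ifelse(.is_abs_path(m$file), m$file, file.path(image_dir, m$file))
    bad <- !file.exists(full)
    if (any(bad))
      .chin_stop("manifest references missing image file(s): ",
                 paste(utils::head(m$file[bad], 5), collapse = ", "))
  }
  attr(m, "image_dir") <- image_dir
  class(m) <- c("plate_manifest", "data.frame")
  m
}

.is_abs_path <- function(p) grepl("^(/|[A-Za-z]:)", p)
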