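#' Serial-section image series
#'
#' A `section_series` holds the raw, possibly misaligned, per-section images
#' of an array-tomography ribbon: one ordered list of 2D intensity matrices
#' per channel role, plus the physical calibration. All channels of a series
#' are acquired on the same physical sections, so they must agree in section
#' count and in-plane shape.
#'
#' @param channels Named list; each element is a list of numeric matrices
#'   (one per section, identical dimensions). Names are channel roles, e.g.
#'   `"presynapse"`, `"gfp"`, `"postsynapse"`, `"tau"`.
#' @param pixel_size_um In-plane pixel size in micrometres (> 0).
#' @param section_thickness_um Physical section thickness in micrometres
#'   (> 0); array tomography ribbons are conventionally 0.07 (70 nm).
#' @return An object of class `section_series`.
#' @export
section_series <- function(channels, pixel_size_um = 0.1,
                           section_thickness_um = 0.07) {
  stopifnot(is.list(channels), length(channels) > 0,
            !is.null(names(channels)), all(nzchar(names(channels))))
  if (pixel_size_um <= 0 || section_thickness_um <= 0) {
    stop("calibration must be strictly positive", call. = FALSE)
  }
  ns <- vapply(channels, length, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("channels differ in section count: ",
         paste(sprintf("%s=%d", names(ns), ns), collapse = ", "),
         call. = FALSE)
  }
  shapes <- lapply(channels, function(ch) unique(lapply(ch, dim)))
  shp <- unique(unlist(shapes, recursive = FALSE))
  if (ns[[1]] > 0 && length(shp) != 1L) {
    stop("sections differ in in-plane shape across channels", call. = FALSE)
  }
  structure(
    list(channels = channels,
         pixel_size_um = pixel_size_um,
         section_thickness_um = section_thickness_um),
    class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  d <- if (n_sections(x) > 0) dim(x$channels[[1]][[1]]) else c(0L, 0L)
  cat(sprintf(
    "<section_series> %d channel(s) [%s], %d sections of %dx%d px, %g um/px, %g um/section\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    n_sections(x), d[1], d[2], x$pixel_size_um, x$section_thickness_um))
  invisible(x)
}

#' Number of sections in a series
#' @param series A `section_series`.
#' @return Integer section count.
#' @export
n_sections <- function(series) length(series$channels[[1]])

#' Aligned single-channel voxel volume
#'
#' A `volume_stack` is an aligned 3D voxel grid for one channel, stored as a
#' numeric array with dimensions `(row = y, col = x, section = z)`, with
#' anisotropic calibration (`dx = dy = pixel_size_um`, `dz =
#' section_thickness_um`) and an origin offset so that centroids measured in
#' a cropped stack remain reportable in parent-volume coordinates. Physical
#' coordinates are micrometres with voxel centres at `(i - 0.5) * d` along
#' each axis (x along columns, y along rows, z along sections).
#'
#' @param data 3D numeric array `(y, x, z)`.
#' @param pixel_size_um,section_thickness_um Calibration in micrometres.
#' @param channel Channel role string.
#' @param origin_um Length-2 `(x, y)` offset of this stack's first voxel edge
#'   in parent coordinates, micrometres.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, pixel_size_um = 0.1,
                         section_thickness_um = 0.07,
                         channel = "unknown", origin_um = c(0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3, all(dim(data) > 0))
  if (pixel_size_um <= 0 || section_thickness_um <= 0) {
    stop("calibration must be strictly positive", call. = FALSE)
  }
  structure(
    list(data = data,
         pixel_size_um = pixel_size_um,
         section_thickness_um = section_thickness_um,
         channel = channel,
         origin_um = as.numeric(origin_um)),
    class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_stack> channel '%s': %dx%d px x %d sections (%.3g um^3)\n",
    x$channel, d[1], d[2], d[3], stack_volume_um3(x)))
  invisible(x)
}

#' Physical volume of a stack in cubic micrometres
#' @param stack A `volume_stack` (or `binary_mask`).
#' @return Scalar volume in um^3.
#' @export
stack_volume_um3 <- function(stack) {
  d <- dim(stack$data)
  d[1] * d[2] * d[3] * stack$pixel_size_um^2 * stack$section_thickness_um
}

#' Convert a (registered) series to per-channel volume stacks
#'
#' Stacks each channel's section list into a 3D array. Use after
#' [align_series()]; stacking a jittered series simply preserves the jitter.
#'
#' @param series A `section_series`.
#' @return Named list of `volume_stack`, one per channel.
#' @export
series_to_stacks <- function(series) {
  lapply(stats::setNames(names(series$channels), names(series$channels)),
         function(role) {
    ch <- series$channels[[role]]
    d <- dim(ch[[1]])
    arr <- array(unlist(ch, use.names = FALSE), dim = c(d[1], d[2], length(ch)))
    volume_stack(arr, series$pixel_size_um, series$section_thickness_um,
                 channel = role)
  })
}

# 16-bit intensity scale used when persisting stacks to TIFF
.tiff_max <- 65535

#' Write a section series as multi-page TIFF files
#'
#' One 16-bit grayscale multi-page TIFF per channel; page order is section
#' order. Intensities must be integers in `[0, 65535]` so that the
#' write/read round trip is lossless.
#'
#' @param series A `section_series`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix; files are `<prefix><channel>.tif`.
#' @return Invisibly, a named character vector of file paths.
#' @export
write_series <- function(series, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(series$channels), function(role) {
    path <- file.path(dir, paste0(prefix, role, ".tif"))
    pages <- lapply(series$channels[[role]], function(img) {
      if (any(img < 0 | img > .tiff_max)) {
        stop("intensities must lie in [0, 65535] for 16-bit TIFF export",
             call. = FALSE)
      }
      img / .tiff_max
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    path
  }, character(1))
  invisible(paths)
}

#' Read a multi-channel serial-section TIFF set
#'
#' @param paths Named character vector, channel role -> multi-page TIFF path.
#'   All channels must have equal page counts.
#' @param pixel_size_um,section_thickness_um Physical calibration.
#' @return A `section_series` with integer intensities on the 16-bit scale.
#' @export
read_series <- function(paths, pixel_size_um = 0.1,
                        section_thickness_um = 0.07) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(img) {
      if (length(dim(img)) == 3) img <- img[, , 1]  # tolerate grayscale-as-RGB
      round(img * .tiff_max)
    })
  })
  counts <- vapply(channels, length, integer(1))
  if (length(unique(counts)) != 1L) {
    stop("mismatched page counts across channels: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  }
  section_series(channels, pixel_size_um, section_thickness_um)
}

#' Crop a rectangular region of interest from a volume stack
#'
#' The crop rectangle is given in physical micrometres in the stack's parent
#' frame and is half-open: voxels whose centres fall in
#' `[origin, origin + size)` are kept. All sections are retained. The
#' returned stack records its origin offset so object centroids remain
#' reportable in parent coordinates.
#'
#' @param stack A `volume_stack`.
#' @param origin_um `(x, y)` crop origin in micrometres, parent frame.
#' @param size_um `(x, y)` crop extent in micrometres.
#' @return A cropped `volume_stack`.
#' @export
crop_roi <- function(stack, origin_um, size_um) {
  d <- dim(stack$data)
  px <- stack$pixel_size_um
  foot <- c(d[2], d[1]) * px  # (x, y) extent
  rel <- as.numeric(origin_um) - stack$origin_um
  if (any(rel < -1e-9) || any(rel + size_um > foot + 1e-9)) {
    stop(sprintf(
      "crop [%g,%g)x[%g,%g) um lies outside stack footprint [%g,%g)x[%g,%g) um",
      origin_um[1], origin_um[1] + size_um[1],
      origin_um[2], origin_um[2] + size_um[2],
      stack$origin_um[1], stack$origin_um[1] + foot[1],
      stack$origin_um[2], stack$origin_um[2] + foot[2]), call. = FALSE)
  }
  c0 <- floor(rel[1] / px)               # first column index (0-based)
  r0 <- floor(rel[2] / px)
  nc <- max(1L, round(size_um[1] / px))  # requested size to whole voxels
  nr <- max(1L, round(size_um[2] / px))
  nc <- min(nc, d[2] - c0)
  nr <- min(nr, d[1] - r0)
  volume_stack(stack$data[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc), , drop = FALSE],
               stack$pixel_size_um, stack$section_thickness_um,
               channel = stack$channel,
               origin_um = stack$origin_um + c(c0, r0) * px)
}
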