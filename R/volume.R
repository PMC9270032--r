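#' 3D intensity volume with physical voxel spacing
#'
#' A `volume_image` is a 3D grid of non-negative intensities together with
#' the per-axis voxel spacing in micrometres. The grid is stored with
#' dimensions `(nz, ny, nx)` (slice-major, matching multi-page TIFF order);
#' spacing is given in world `(sx, sy, sz)` order. World coordinates of the
#' voxel with 0-based index `(iz, iy, ix)` are `(ix*sx, iy*sy, iz*sz)`.
#'
#' @param intensities numeric 3D array, dimensions `(nz, ny, nx)`, values
#'   non-negative.
#' @param spacing numeric length-3 vector `(sx, sy, sz)` in micrometres per
#'   voxel, strictly positive.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(intensities, spacing = c(0.317, 0.317, 1.0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3) {
    stop("`intensities` must be a 3D array with dim (nz, ny, nx)")
  }
  if (any(dim(intensities) < 1)) stop("all grid dimensions must be >= 1")
  if (!is.numeric(spacing) || length(spacing) != 3 || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive numbers (sx, sy, sz)")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  storage.mode(intensities) <- "double"
  structure(
    list(intensities = intensities, spacing = as.numeric(spacing)),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um (x,y,z)\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  physical extent %.1f x %.1f x %.1f um; intensity range [%.4g, %.4g]\n",
    d[3] * x$spacing[1], d[2] * x$spacing[2], d[1] * x$spacing[3],
    min(x$intensities), max(x$intensities)
  ))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".yml")

#' Read a volume from a multi-page TIFF
#'
#' One TIFF page per z-slice. Integer TIFFs (8/16-bit) are read bit-exactly;
#' 32-bit float TIFFs written by [write_volume()] are de-normalized using the
#' scale recorded in the sidecar. Voxel spacing must be supplied either via
#' the `spacing` argument or a YAML sidecar `<path>.yml` with a `spacing`
#' entry (written automatically by [write_volume()]).
#'
#' @param path TIFF file path.
#' @param spacing optional `(sx, sy, sz)` in micrometres; overrides the
#'   sidecar.
#' @return a [volume_image()].
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits %in% c(8L, 16L)) {
    # integer TIFF: undo the [0, 1] normalisation bit-exactly
    top <- 2^bits - 1
    pages <- lapply(pages, function(p) round(p * top))
  }
  # 32-bit pages are IEEE float and arrive unscaled
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent page sizes in ", path)
  }
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- yaml::read_yaml(sidecar_path(path))
  }
  if (is.null(spacing)) spacing <- meta$spacing
  if (is.null(spacing)) {
    stop("voxel spacing unknown: pass `spacing` or provide a YAML sidecar")
  }
  nz <- length(pages)
  ny <- dims[1, 1]
  nx <- dims[2, 1]
  arr <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  if (!is.null(meta$intensity_scale)) {
    arr <- arr * meta$intensity_scale + (meta$intensity_offset %||% 0)
  }
  volume_image(arr, as.numeric(spacing))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume to a multi-page TIFF (plus YAML sidecar)
#'
#' Integer-valued volumes are stored as 8- or 16-bit integer TIFF and round
#' trip bit-exactly; other volumes are stored as 32-bit float after scaling
#' into \[0, 1\], with the scaling recorded in the sidecar so
#' [read_volume()] restores the original values (up to float32 precision).
#' The sidecar also records the voxel spacing.
#'
#' @param vol a [volume_image()].
#' @param path output TIFF path.
#' @param bits 8, 16 or 32 bits per sample; the default picks 16 for
#'   integer-valued data and 32 otherwise.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, bits = NULL) {
  stopifnot(inherits(vol, "volume_image"))
  a <- vol$intensities
  is_int <- all(a == round(a)) && max(a) <= 65535
  if (is.null(bits)) bits <- if (is_int) 16L else 32L
  meta <- list(spacing = vol$spacing)
  if (bits %in% c(8L, 16L)) {
    top <- 2^bits - 1
    if (!is_int || max(a) > top) {
      stop("integer TIFF requires integer intensities in [0, ", top, "]")
    }
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / top)
  } else if (bits == 32L) {
    lo <- min(a)
    hi <- max(a)
    scale <- if (hi > lo) hi - lo else 1
    meta$intensity_offset <- lo
    meta$intensity_scale <- scale
    pages <- lapply(seq_len(dim(a)[1]), function(z) (a[z, , ] - lo) / scale)
  } else {
    stop("`bits` must be 8, 16 or 32")
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}
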