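#' Segmentation parameters for nucleus-scale blob detection
#'
#' @param blob_diameter_um physical diameter of the structures to detect
#'   (default 4.5 um, the nominal nucleus size).
#' @param min_volume_um3 objects smaller than this are discarded as
#'   unspecific signal (default 15 um^3).
#' @param denoise_iterations curvature-flow iterations applied by the
#'   pipeline before detection.
#' @param denoise_timestep explicit time step of the curvature flow.
#' @param detection_threshold detection threshold in multiples of the robust
#'   background spread (median absolute deviation) of the blob response;
#'   being relative, detection is equivariant to global intensity scaling.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(blob_diameter_um = 4.5,
                                min_volume_um3 = 15,
                                denoise_iterations = 5,
                                denoise_timestep = 0.125,
                                detection_threshold = 5) {
  stopifnot_scalar_number(blob_diameter_um, "blob_diameter_um", positive = TRUE)
  stopifnot_scalar_number(min_volume_um3, "min_volume_um3", min = 0)
  stopifnot_scalar_number(denoise_iterations, "denoise_iterations", min = 0)
  stopifnot_scalar_number(denoise_timestep, "denoise_timestep", positive = TRUE)
  stopifnot_scalar_number(detection_threshold, "detection_threshold", positive = TRUE)
  structure(
    list(
      blob_diameter_um = blob_diameter_um,
      min_volume_um3 = min_volume_um3,
      denoise_iterations = as.integer(denoise_iterations),
      denoise_timestep = denoise_timestep,
      detection_threshold = detection_threshold
    ),
    class = "segmentation_config"
  )
}

#' Edge-preserving denoising by level-set curvature flow
#'
#' Evolves the intensity under mean-curvature motion of its level sets
#' (`I_t = |grad I| div(grad I / |grad I|)`), which flattens noise while
#' preserving rounded structures. Runs in index space with an explicit
#' scheme; `iterations = 0` returns the input unchanged. Constant volumes
#' are fixed points of the flow.
#'
#' @param vol a [volume_image()].
#' @param iterations number of explicit steps (>= 0).
#' @param timestep step size; values up to ~0.125 are stable.
#' @return the denoised [volume_image()], same shape and spacing.
#' @export
denoise_curvature_flow <- function(vol, iterations = 5, timestep = 0.125) {
  stopifnot(inherits(vol, "volume_image"))
  stopifnot_scalar_number(iterations, "iterations", min = 0)
  if (!is.numeric(timestep) || length(timestep) != 1 || timestep <= 0) {
    stop("`timestep` must be strictly positive")
  }
  out <- curvature_flow_cpp(
    as.numeric(vol$intensities), dim(vol$intensities),
    as.integer(iterations), timestep
  )
  res <- vol
  res$intensities <- array(out, dim(vol$intensities))
  res
}

#' Detect nucleus-sized blobs in a volume
#'
#' Scale-matched blob detection in physical units: the volume is smoothed
#' with an anisotropy-corrected Gaussian of physical scale
#' `sigma = diameter / (2 sqrt(3))` (the scale at which a ball of that
#' diameter maximises the 3D Laplacian-of-Gaussian response), the
#' scale-normalised negated Laplacian is computed with the true voxel
#' spacing, and local maxima above `detection_threshold` robust SDs of the
#' response background are grown into labelled objects by watershed-style
#' flooding over the supra-threshold region (26-connectivity).
#'
#' @param vol a [volume_image()] (typically after
#'   [denoise_curvature_flow()]).
#' @param cfg a [segmentation_config()].
#' @return An object of class `segmentation_result`: `labels` (integer array
#'   like the input, 0 = background), `per_object` (data frame with
#'   `object_id`, `volume_um3`, `x_um`, `y_um`, `z_um`, `peak_intensity`)
#'   and `spacing`.
#' @export
detect_blobs <- function(vol, cfg = segmentation_config()) {
  stopifnot(inherits(vol, "volume_image"), inherits(cfg, "segmentation_config"))
  if (is.null(vol$spacing)) stop("volume has no voxel spacing")
  d <- dim(vol$intensities)
  sp <- vol$spacing # (sx, sy, sz)
  sigma_phys <- cfg$blob_diameter_um / (2 * sqrt(3))
  sigma_vox_zyx <- sigma_phys / c(sp[3], sp[2], sp[1])
  sm <- gaussian_blur_cpp(as.numeric(vol$intensities), d, sigma_vox_zyx)
  resp <- -sigma_phys^2 *
    laplacian_cpp(as.numeric(sm), d, c(sp[3], sp[2], sp[1]))
  med <- stats::median(resp)
  spread <- stats::mad(resp)
  if (spread == 0) {
    # noiseless background: any genuinely positive response is signal
    spread <- max(1e-12, 1e-6 * (max(resp) - med))
  }
  thr <- med + cfg$detection_threshold * spread
  if (max(resp) <= thr) {
    return(empty_segmentation(d, sp))
  }
  seeds <- local_maxima_cpp(resp, d, thr)
  if (nrow(seeds) == 0) {
    return(empty_segmentation(d, sp))
  }
  # non-maximum suppression at the detection scale: discretisation (notably
  # the coarse z sampling) can split one blob into twin maxima, so only the
  # strongest maximum within 0.8 blob diameters is kept (well below the
  # ~1.5 diameter separation at which distinct nuclei are resolvable)
  world <- cbind((seeds[, 3] - 1) * sp[1], (seeds[, 2] - 1) * sp[2],
                 (seeds[, 1] - 1) * sp[3])
  vals <- resp[seeds]
  ord <- order(vals, decreasing = TRUE)
  r_min <- 0.8 * cfg$blob_diameter_um
  keep <- integer()
  for (i in ord) {
    if (!length(keep) ||
        min(sqrt(colSums((t(world[keep, , drop = FALSE]) - world[i, ])^2))) >= r_min) {
      keep <- c(keep, i)
    }
  }
  seeds <- seeds[sort(keep), , drop = FALSE]
  labels <- grow_labels_cpp(resp, d, seeds, thr)
  segmentation_from_labels(labels, vol, resp)
}

empty_segmentation <- function(d, sp) {
  structure(
    list(
      labels = array(0L, d),
      per_object = data.frame(
        object_id = integer(), volume_um3 = numeric(),
        x_um = numeric(), y_um = numeric(), z_um = numeric(),
        peak_intensity = numeric()
      ),
      spacing = sp
    ),
    class = "segmentation_result"
  )
}

segmentation_from_labels <- function(labels, vol, weights) {
  d <- dim(vol$intensities)
  sp <- vol$spacing
  voxvol <- prod(sp)
  idx <- which(labels > 0)
  lab <- labels[idx]
  co <- arrayInd(idx, d) # (z, y, x), 1-based
  w <- pmax(weights[idx], 0)
  wsum <- tapply(w, lab, sum)
  # weighted centroids in world um; 0-based index * spacing
  cx <- tapply(w * (co[, 3] - 1) * sp[1], lab, sum) / wsum
  cy <- tapply(w * (co[, 2] - 1) * sp[2], lab, sum) / wsum
  cz <- tapply(w * (co[, 1] - 1) * sp[3], lab, sum) / wsum
  nv <- tapply(rep(1, length(lab)), lab, sum)
  pk <- tapply(vol$intensities[idx], lab, max)
  ids <- as.integer(names(nv))
  ord <- order(ids)
  per <- data.frame(
    object_id = seq_along(ids),
    volume_um3 = as.numeric(nv[ord]) * voxvol,
    x_um = as.numeric(cx[ord]),
    y_um = as.numeric(cy[ord]),
    z_um = as.numeric(cz[ord]),
    peak_intensity = as.numeric(pk[ord])
  )
  # re-densify label ids 1..K
  remap <- integer(max(ids))
  remap[ids[ord]] <- seq_along(ids)
  new_labels <- array(0L, d)
  new_labels[idx] <- remap[lab]
  structure(
    list(labels = new_labels, per_object = per, spacing = sp),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d objects in a %s voxel volume\n",
    nrow(x$per_object), paste(dim(x$labels), collapse = " x ")
  ))
  if (nrow(x$per_object)) {
    cat(sprintf(
      "  volumes [um^3]: median %.1f, range %.1f - %.1f\n",
      stats::median(x$per_object$volume_um3),
      min(x$per_object$volume_um3), max(x$per_object$volume_um3)
    ))
  }
  invisible(x)
}

#' Remove small segmented objects
#'
#' Discards objects with volume below `min_volume_um3` (exclusive) and
#' re-densifies object ids. Applying thresholds `a` then `b` equals applying
#' `max(a, b)` once; a threshold of 0 is the identity.
#'
#' @param seg a `segmentation_result`.
#' @param min_volume_um3 volume threshold in cubic micrometres (>= 0).
#' @return filtered `segmentation_result`.
#' @export
filter_by_volume <- function(seg, min_volume_um3 = 15) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (!is.numeric(min_volume_um3) || length(min_volume_um3) != 1 ||
      is.na(min_volume_um3) || min_volume_um3 < 0) {
    stop("`min_volume_um3` must be a single non-negative number")
  }
  keep <- seg$per_object$volume_um3 >= min_volume_um3
  per <- seg$per_object[keep, , drop = FALSE]
  old_ids <- per$object_id
  per$object_id <- seq_len(nrow(per))
  rownames(per) <- NULL
  remap <- integer(max(seg$per_object$object_id, 1L))
  remap[old_ids] <- per$object_id
  labels <- seg$labels
  pos <- which(labels > 0)
  drop_ids <- seg$per_object$object_id[!keep]
  if (length(drop_ids)) {
    labels[pos][labels[pos] %in% drop_ids] <- 0L
    pos <- which(labels > 0)
  }
  labels[pos] <- remap[labels[pos]]
  structure(
    list(labels = labels, per_object = per, spacing = seg$spacing),
    class = "segmentation_result"
  )
}

#' Extract object centroids as a point cloud
#'
#' One point per segmented object, in world micrometre coordinates
#' (x, y, z).
#'
#' @param seg a `segmentation_result`.
#' @inheritParams point_cloud
#' @return a [point_cloud()].
#' @export
extract_centroids <- function(seg, animal_id = "animal1", line = "unknown",
                              sex = "unknown") {
  stopifnot(inherits(seg, "segmentation_result"))
  point_cloud(
    cbind(seg$per_object$x_um, seg$per_object$y_um, seg$per_object$z_um),
    animal_id = animal_id, line = line, sex = sex
  )
}

#' Compare an automated count against a manual count
#'
#' @param auto automated result: a [point_cloud()], `segmentation_result`,
#'   or a plain count.
#' @param manual_count manually annotated nucleus count (>= 0).
#' @return list with `difference` (automated - manual) and `percent`
#'   (100 x difference / manual).
#' @examples
#' concordance_report(9444, 9430) # difference of 14 nuclei, +0.15 %
#' @export
concordance_report <- function(auto, manual_count) {
  n_auto <- if (inherits(auto, "point_cloud")) {
    nrow(auto$points)
  } else if (inherits(auto, "segmentation_result")) {
    nrow(auto$per_object)
  } else {
    stopifnot_scalar_number(auto, "auto", min = 0)
    as.integer(auto)
  }
  stopifnot_scalar_number(manual_count, "manual_count", min = 0)
  if (manual_count == 0 && n_auto > 0) {
    stop("percent difference undefined: manual count is zero")
  }
  diffn <- n_auto - manual_count
  list(
    difference = as.integer(diffn),
    percent = if (manual_count == 0) 0 else 100 * diffn / manual_count
  )
}
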