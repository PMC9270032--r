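#' All pairwise inter-nuclei distances of a point cloud
#'
#' Computes the `n(n-1)/2` unordered-pair Euclidean distances, ordered by
#' lexicographic pair index (1-2, 1-3, ..., 2-3, ...). These distributions
#' distinguish cell types: glial nuclei show a unimodal distribution while
#' neuronal nuclei are bimodal.
#'
#' @param cloud a [point_cloud()] with at least 2 points.
#' @return An object of class `distance_summary` with element `distances`
#'   (micrometres); `features` and `histogram` are filled by
#'   [summarize_distances()].
#' @export
pairwise_distances <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$points)
  if (n < 2) stop("need at least 2 points to compute pairwise distances")
  d <- stats::dist(cloud$points) # lexicographic pair order
  structure(
    list(
      animal_id = cloud$animal_id,
      distances = as.numeric(d),
      features = NULL,
      histogram = NULL
    ),
    class = "distance_summary"
  )
}

#' Moments, bimodality coefficient and histogram of a distance distribution
#'
#' Fills in population (biased) moments of the distance distribution: mean,
#' variance, skewness, kurtosis (non-excess), and Sarle's bimodality
#' coefficient `(skewness^2 + 1) / kurtosis`. Values above 5/9 suggest a
#' bimodal distribution (a uniform distribution sits exactly at 5/9, a
#' normal one at 1/3). No small-sample correction is applied: with ~10^7
#' distances per whole-CNS cloud the correction is immaterial.
#'
#' @param ds a `distance_summary` from [pairwise_distances()] (or any list
#'   with a numeric `distances` element).
#' @param bin_width histogram bin width in micrometres.
#' @return the input with `features` (named numeric vector: `mean`,
#'   `variance`, `skewness`, `kurtosis`, `bimodality`) and `histogram`
#'   (`bin_edges`, `counts`) filled in. If the distances are constant the
#'   bimodality coefficient is undefined and returned as `NA` with a
#'   warning.
#' @export
summarize_distances <- function(ds, bin_width = 1.0) {
  d <- ds$distances
  if (length(d) < 2) stop("need at least 2 distances to summarise")
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  m <- mean(d)
  v <- mean((d - m)^2)
  if (v > 0) {
    skew <- mean((d - m)^3) / v^1.5
    kurt <- mean((d - m)^4) / v^2
    bimod <- (skew^2 + 1) / kurt
  } else {
    warning("zero variance: bimodality coefficient undefined", call. = FALSE)
    skew <- 0
    kurt <- NaN
    bimod <- NA_real_
  }
  edges <- seq(
    floor(min(d) / bin_width) * bin_width,
    ceiling(max(d) / bin_width) * bin_width + bin_width,
    by = bin_width
  )
  h <- graphics::hist(d, breaks = edges, plot = FALSE, right = FALSE)
  ds$features <- c(
    mean = m, variance = v, skewness = skew, kurtosis = kurt,
    bimodality = bimod
  )
  ds$histogram <- list(bin_edges = h$breaks, counts = h$counts)
  class(ds) <- "distance_summary"
  ds
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(
    "<distance_summary>%s %d pairwise distances\n",
    if (!is.null(x$animal_id)) paste0(" animal '", x$animal_id, "',") else "",
    length(x$distances)
  ))
  if (!is.null(x$features)) {
    f <- x$features
    cat(sprintf(
      "  mean %.2f um, variance %.2f um^2, skewness %.3f, kurtosis %.3f\n",
      f["mean"], f["variance"], f["skewness"], f["kurtosis"]
    ))
    cat(sprintf(
      "  bimodality coefficient %.3f (%s 5/9 => %s)\n",
      f["bimodality"], if (isTRUE(f[["bimodality"]] > 5 / 9)) ">" else "<=",
      if (isTRUE(f[["bimodality"]] > 5 / 9)) "bimodal" else "unimodal"
    ))
  }
  invisible(x)
}

#' @export
plot.distance_summary <- function(x, ...) {
  if (is.null(x$histogram)) x <- summarize_distances(x)
  graphics::plot(
    utils::head(x$histogram$bin_edges, -1), x$histogram$counts,
    type = "s", xlab = "inter-nuclei distance [um]", ylab = "pair count",
    main = x$animal_id %||% "", ...
  )
  invisible(x)
}

#' Scalar distance-distribution features for a set of clouds
#'
#' The "simple features" baseline: real-valued summaries of the
#' pairwise-distance distribution of each cloud, suitable for a radial basis
#' function kernel. All features are invariant under rigid motions of the
#' cloud.
#'
#' @param clouds list of [point_cloud()]s (each with >= 2 points).
#' @param which subset of `c("mean", "variance", "skewness", "kurtosis",
#'   "bimodality")`; the default uses mean and variance.
#' @return numeric matrix, one row per cloud (row names = animal ids),
#'   columns in the order requested.
#' @export
feature_matrix <- function(clouds, which = c("mean", "variance")) {
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  which <- match.arg(
    which,
    c("mean", "variance", "skewness", "kurtosis", "bimodality"),
    several.ok = TRUE
  )
  rows <- lapply(clouds, function(pc) {
    summarize_distances(pairwise_distances(pc))$features[which]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(clouds, `[[`, character(1), "animal_id")
  colnames(out) <- which
  out
}
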