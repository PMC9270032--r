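#' Repeated random subsampling of a point cloud
#'
#' Draws `repeats` subsamples of exactly `m` points, uniformly without
#' replacement, from one animal's cloud. Subsampling both tests the
#' stability of the topological summaries and removes point-count
#' differences between animals as a possible signal. Deterministic given
#' `seed`.
#'
#' @param cloud a [point_cloud()] with at least `m` points.
#' @param m subsample size.
#' @param repeats number of subsamples.
#' @param seed integer seed.
#' @return An object of class `subsample_set`: list with `parent_animal_id`,
#'   `clouds` (list of [point_cloud()]s, metadata inherited), `m`,
#'   `repeats`, `seed`.
#' @export
subsample_cloud <- function(cloud, m, repeats, seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  stopifnot_scalar_number(m, "m", positive = TRUE)
  stopifnot_scalar_number(repeats, "repeats", positive = TRUE)
  n <- nrow(cloud$points)
  if (n < m) {
    stop(sprintf(
      "cannot subsample %d points from a cloud of %d (animal '%s')",
      m, n, cloud$animal_id
    ))
  }
  clouds <- with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      keep <- sample.int(n, m)
      point_cloud(cloud$points[keep, , drop = FALSE],
                  animal_id = cloud$animal_id, line = cloud$line,
                  sex = cloud$sex)
    })
  })
  structure(
    list(
      parent_animal_id = cloud$animal_id, clouds = clouds,
      m = as.integer(m), repeats = as.integer(repeats),
      seed = as.integer(seed)
    ),
    class = "subsample_set"
  )
}

#' @export
print.subsample_set <- function(x, ...) {
  cat(sprintf(
    "<subsample_set> animal '%s': %d subsamples of %d points (seed %d)\n",
    x$parent_animal_id, x$repeats, x$m, x$seed
  ))
  invisible(x)
}

new_persistence_diagram <- function(pairs, degree = 1L) {
  pairs <- matrix(as.numeric(pairs), ncol = 2)
  colnames(pairs) <- c("birth", "death")
  structure(list(degree = as.integer(degree), pairs = pairs),
            class = "persistence_diagram")
}

#' Degree-1 persistence diagram of the alpha complex
#'
#' Computes the persistent homology in degree 1 (unfilled loops) of the
#' alpha-complex filtration of a 3D point cloud. Values are in squared-radius
#' units (um^2): a feature born at `b` and dying at `d` corresponds to a loop
#' that exists while the balls grown on the points have squared radius in
#' `[b, d)`.
#'
#' Implementation: Delaunay triangulation (randomised incremental), standard
#' alpha filtration values (a simplex that is not Gabriel with respect to a
#' coface inherits the coface's value), and boundary-matrix reduction over
#' Z/2 restricted to the edge/triangle block. Numerics:
#' \itemize{
#'   \item clouds whose thickness is below `1e-5` of their diameter are
#'     triangulated in their own plane (the alpha complex of coplanar points
#'     is planar); collinear or coincident clouds are an error;
#'   \item if the 3D triangulation fails on a degenerate (e.g. cospherical)
#'     configuration, a deterministic symmetric-breaking jitter of
#'     `1e-6` x the bounding-box diagonal is applied and the triangulation
#'     retried;
#'   \item pairs with persistence below `min_persistence` (default `1e-12`,
#'     numerical noise) are dropped;
#'   \item degree-1 classes of a full alpha filtration all die; a surviving
#'     (essential) class indicates a broken triangulation and is an error.
#' }
#'
#' @param cloud a [point_cloud()] (or bare n x 3 matrix); fewer than 4
#'   points yield an empty diagram.
#' @param min_persistence drop pairs with `death - birth` below this.
#' @param units `"squared"` (default, squared-radius um^2, the convention of
#'   alpha-complex software) or `"radius"` (square roots, um) for
#'   sensitivity analyses.
#' @param seed seed for the insertion order and any fallback jitter.
#' @return a `persistence_diagram`: list with `degree = 1` and `pairs`, a
#'   matrix with columns `birth`, `death` (all finite, `birth <= death`).
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 21)[-1]
#' ring <- cbind(cos(theta), sin(theta), 0)
#' alpha_persistence_degree1(point_cloud(ring))
#' @export
alpha_persistence_degree1 <- function(cloud, min_persistence = 1e-12,
                                      units = c("squared", "radius"),
                                      seed = 1L) {
  units <- match.arg(units)
  X <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (ncol(X) != 3) stop("expected 3D coordinates")
  n <- nrow(X)
  if (n < 3) {
    return(new_persistence_diagram(matrix(numeric(), 0, 2)))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  diag_len <- sqrt(sum((apply(X, 2, max) - apply(X, 2, min))^2))
  if (diag_len == 0) stop("degenerate input: all points coincide")
  sv <- svd(Xc, nu = 0)
  if (sv$d[2] < 1e-9 * diag_len) stop("degenerate input: points are collinear")
  planar <- sv$d[3] < 1e-5 * diag_len

  res <- NULL
  if (planar) {
    P2 <- Xc %*% sv$v[, 1:2]
    tri <- planar_triangles(P2)
    res <- alpha_persistence_cpp(
      cbind(P2, 0), matrix(integer(), 0, 4), tri, min_persistence
    )
  } else {
    if (n < 4) {
      return(new_persistence_diagram(matrix(numeric(), 0, 2)))
    }
    Xw <- X
    for (attempt in 0:3) {
      res <- tryCatch(
        {
          ord <- with_seed(derive_seed(seed, attempt), sample.int(n))
          tets <- delaunay3d_cpp(Xw, ord)
          alpha_persistence_cpp(Xw, tets, matrix(integer(), 0, 3),
                                min_persistence)
        },
        error = function(e) e
      )
      if (!inherits(res, "error")) break
      # symmetric-breaking jitter, deterministic given the seed
      Xw <- X + with_seed(derive_seed(seed, 100 + attempt), {
        matrix(stats::runif(3 * n, -1, 1), n, 3) * 1e-6 * diag_len
      })
    }
    if (inherits(res, "error")) {
      stop("alpha complex failed on degenerate input: ",
           conditionMessage(res))
    }
  }
  pairs <- res$pairs
  if (units == "radius") pairs <- sqrt(pairs)
  new_persistence_diagram(pairs)
}

# Delaunay triangles of a planar point set, via deldir
planar_triangles <- function(P2) {
  if (nrow(P2) == 3) {
    return(matrix(1:3, 1, 3))
  }
  dd <- deldir::deldir(P2[, 1], P2[, 2], suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  if (is.null(tri) || !is.matrix(tri) || nrow(tri) == 0 || anyNA(tri)) {
    stop("planar triangulation failed")
  }
  storage.mode(tri) <- "integer"
  tri
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf(
    "<persistence_diagram> degree %d, %d finite (birth, death) pairs\n",
    x$degree, nrow(x$pairs)
  ))
  if (nrow(x$pairs)) {
    p <- x$pairs[, 2] - x$pairs[, 1]
    top <- utils::head(order(p, decreasing = TRUE), 3)
    for (i in top) {
      cat(sprintf(
        "  (%.4g, %.4g)  persistence %.4g\n",
        x$pairs[i, 1], x$pairs[i, 2], p[i]
      ))
    }
    if (nrow(x$pairs) > 3) cat(sprintf("  ... and %d more\n", nrow(x$pairs) - 3))
  }
  invisible(x)
}

#' @export
plot.persistence_diagram <- function(x, ...) {
  p <- x$pairs
  lim <- if (nrow(p)) c(0, max(p) * 1.05) else c(0, 1)
  graphics::plot(
    p[, 1], p[, 2], xlim = lim, ylim = lim, pch = 20,
    col = grDevices::adjustcolor("steelblue", 0.6),
    xlab = "birth [squared radius]", ylab = "death [squared radius]", ...
  )
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
as.data.frame.persistence_diagram <- function(x, ...) {
  data.frame(degree = rep(x$degree, nrow(x$pairs)),
             birth = x$pairs[, 1], death = x$pairs[, 2])
}

#' Persistence scale-space heat kernel between two diagrams
#'
#' The positive-definite similarity
#' \deqn{k_\sigma(F,G) = \frac{1}{8\pi\sigma} \sum_{p \in F, q \in G}
#'   e^{-\|p-q\|^2/(8\sigma)} - e^{-\|p-\bar q\|^2/(8\sigma)}}
#' where \eqn{\bar q} is \eqn{q} mirrored across the diagonal. Equivalently,
#' the inner product of the two solutions of the heat equation with Dirichlet
#' boundary on the diagonal whose initial conditions are point masses on the
#' diagram points. Points near the diagonal contribute little (their mirror
#' image cancels them), which makes the kernel stable under diagram
#' perturbations.
#'
#' @param F,G `persistence_diagram`s (or bare 2-column matrices). An empty
#'   diagram has similarity 0 with everything.
#' @param sigma kernel bandwidth, in squared-radius units (> 0).
#' @return a single non-negative number for `F = G`; real in general.
#' @export
heat_kernel <- function(F, G, sigma = 0.01) {
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  pf <- diagram_pairs(F)
  pg <- diagram_pairs(G)
  pssk_cpp(pf, pg, sigma)
}

diagram_pairs <- function(x) {
  p <- if (inherits(x, "persistence_diagram")) x$pairs else as.matrix(x)
  if (length(p) == 0) p <- matrix(numeric(), 0, 2)
  if (ncol(p) != 2) stop("a persistence diagram has two columns (birth, death)")
  if (nrow(p) && (any(!is.finite(p)) || any(p[, 1] > p[, 2]) || any(p[, 1] < 0))) {
    stop("invalid diagram: need 0 <= birth <= death < Inf")
  }
  p
}

new_kernel_gram <- function(K, item_ids, group_ids, kernel_kind, params) {
  K <- (K + t(K)) / 2
  dimnames(K) <- list(item_ids, item_ids)
  structure(
    list(matrix = K, item_ids = item_ids, group_ids = group_ids,
         kernel_kind = kernel_kind, params = params),
    class = "kernel_gram"
  )
}

#' Heat-kernel Gram matrix over persistence diagrams
#'
#' Evaluates [heat_kernel()] between all pairs of diagrams and symmetrises
#' the result. The per-item `group_ids` (animal of origin) are carried
#' through for group-aware train/test splitting.
#'
#' @param diagrams list of `persistence_diagram`s.
#' @param group_ids character vector, one animal id per diagram (defaults to
#'   the list names, or item index).
#' @param sigma heat-kernel bandwidth.
#' @return An object of class `kernel_gram`: `matrix`, `item_ids`,
#'   `group_ids`, `kernel_kind = "persistence_heat"`, `params`.
#' @export
gram_matrix <- function(diagrams, group_ids = NULL, sigma = 0.01) {
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  if (!length(diagrams)) stop("need at least one diagram")
  plist <- lapply(diagrams, diagram_pairs)
  K <- pssk_gram_cpp(plist, sigma)
  item_ids <- names(diagrams) %||% as.character(seq_along(diagrams))
  if (is.null(group_ids)) group_ids <- item_ids
  if (length(group_ids) != length(diagrams)) {
    stop("`group_ids` must have one entry per diagram")
  }
  new_kernel_gram(K, item_ids, as.character(group_ids), "persistence_heat",
                  list(sigma = sigma))
}

#' Radial-basis-function Gram matrix over scalar features
#'
#' The baseline kernel for the "simple features" classifier:
#' `K[i, j] = exp(-||f_i - f_j||^2 / (2 bandwidth^2))` (so the diagonal is
#' 1). Because "bandwidth" is ambiguous in parts of the SVM literature, the
#' convention `exp(-d^2 / bandwidth)` is also available for replication
#' sweeps.
#'
#' @param features numeric matrix, one row per item (e.g. from
#'   [feature_matrix()]).
#' @param bandwidth kernel bandwidth (> 0).
#' @param group_ids per-item animal ids (defaults to row names).
#' @param convention `"gaussian"` for `exp(-d^2/(2 bw^2))` (default) or
#'   `"exp_d2_over_bw"` for `exp(-d^2/bw)`.
#' @return a `kernel_gram` with `kernel_kind = "feature_rbf"`.
#' @export
rbf_feature_gram <- function(features, bandwidth = 1e5, group_ids = NULL,
                             convention = c("gaussian", "exp_d2_over_bw")) {
  convention <- match.arg(convention)
  stopifnot_scalar_number(bandwidth, "bandwidth", positive = TRUE)
  features <- as.matrix(features)
  d2 <- as.matrix(stats::dist(features))^2
  K <- if (convention == "gaussian") {
    exp(-d2 / (2 * bandwidth^2))
  } else {
    exp(-d2 / bandwidth)
  }
  item_ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  if (is.null(group_ids)) group_ids <- item_ids
  if (length(group_ids) != nrow(features)) {
    stop("`group_ids` must have one entry per feature row")
  }
  new_kernel_gram(K, make.unique(item_ids), as.character(group_ids),
                  "feature_rbf",
                  list(bandwidth = bandwidth, convention = convention))
}

#' @export
print.kernel_gram <- function(x, ...) {
  cat(sprintf(
    "<kernel_gram> %s kernel, %d items over %d groups\n",
    x$kernel_kind, length(x$item_ids), length(unique(x$group_ids))
  ))
  ev <- range(eigen(x$matrix, symmetric = TRUE, only.values = TRUE)$values)
  cat(sprintf("  eigenvalue range [%.3g, %.3g]\n", ev[1], ev[2]))
  invisible(x)
}

#' Diagrams for every subsample of a cohort
#'
#' Convenience wrapper chaining [subsample_cloud()] and
#' [alpha_persistence_degree1()] over a list of clouds. Item names are
#' `<animal>#<replicate>`; per-item seeds are derived from `seed`.
#'
#' @param clouds list of [point_cloud()]s.
#' @param m subsample size.
#' @param repeats subsamples per animal.
#' @param seed master seed.
#' @param min_persistence passed to [alpha_persistence_degree1()].
#' @return list with `diagrams` (named list), `group_ids`, `sex` (per item).
#' @export
cohort_diagrams <- function(clouds, m, repeats, seed = 1L,
                            min_persistence = 1e-12) {
  diagrams <- list()
  group_ids <- character()
  sex <- character()
  for (i in seq_along(clouds)) {
    pc <- clouds[[i]]
    ss <- subsample_cloud(pc, m, repeats, seed = derive_seed(seed, i))
    for (r in seq_len(repeats)) {
      nm <- sprintf("%s#%03d", pc$animal_id, r)
      diagrams[[nm]] <- alpha_persistence_degree1(
        ss$clouds[[r]], min_persistence = min_persistence,
        seed = derive_seed(seed, 1000L * i + r)
      )
      group_ids <- c(group_ids, pc$animal_id)
      sex <- c(sex, pc$sex)
    }
  }
  list(diagrams = diagrams, group_ids = group_ids, sex = sex)
}
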