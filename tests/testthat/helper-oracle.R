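# Independent brute-force oracle for alpha-complex degree-1 persistence.
# Deliberately shares no code or algorithmic shortcuts with the package:
# Delaunay by exhaustive empty-circumsphere testing, filtration values from
# the definition (squared radius of the smallest empty sphere through the
# simplex), persistence by dense reduction of the full boundary matrix.

oracle_circumsphere <- function(P) {
  # sphere through 4 points
  a <- P[1, ]
  A <- 2 * sweep(P[2:4, , drop = FALSE], 2, a)
  rhs <- rowSums(P[2:4, , drop = FALSE]^2) - sum(a^2)
  cc <- solve(A, rhs)
  list(cc = cc, r2 = sum((cc - a)^2))
}

oracle_delaunay_tets <- function(X) {
  n <- nrow(X)
  keep <- list()
  cb <- utils::combn(n, 4)
  for (i in seq_len(ncol(cb))) {
    id <- cb[, i]
    cs <- tryCatch(oracle_circumsphere(X[id, ]), error = function(e) NULL)
    if (is.null(cs)) next
    d2 <- colSums((t(X) - cs$cc)^2)
    if (all(d2[-id] > cs$r2)) keep[[length(keep) + 1]] <- sort(id)
  }
  if (!length(keep)) matrix(integer(), 0, 4) else do.call(rbind, keep)
}

# smallest empty sphere through the vertices of a simplex (2 or 3 vertices):
# centres form an affine family c(t) orthogonal to the simplex; each other
# point contributes one linear feasibility constraint; minimise |t|^2.
oracle_alpha_value <- function(X, id) {
  V <- X[id, , drop = FALSE]
  a <- V[1, ]
  n <- nrow(X)
  others <- setdiff(seq_len(n), id)
  if (length(id) == 3) {
    u <- V[2, ] - a
    v <- V[3, ] - a
    nrm <- c(
      u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1]
    )
    nrm <- nrm / sqrt(sum(nrm^2))
    M <- rbind(2 * (V[2, ] - a), 2 * (V[3, ] - a))
    rhs <- c(sum(V[2, ]^2) - sum(a^2), sum(V[3, ]^2) - sum(a^2))
    # particular centre: circumcentre in the triangle plane
    uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
    det <- uu * vv - uv^2
    s <- vv * (uu - uv) / (2 * det)
    t0 <- uu * (vv - uv) / (2 * det)
    cc0 <- a + s * u + t0 * v
    dirs <- matrix(nrm, 3, 1)
  } else if (length(id) == 2) {
    cc0 <- (V[1, ] + V[2, ]) / 2
    d <- V[2, ] - V[1, ]
    d <- d / sqrt(sum(d^2))
    # orthonormal basis of the plane orthogonal to the edge
    e <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    b1 <- e - sum(e * d) * d
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(
      d[2] * b1[3] - d[3] * b1[2],
      d[3] * b1[1] - d[1] * b1[3],
      d[1] * b1[2] - d[2] * b1[1]
    )
    dirs <- cbind(b1, b2)
  } else {
    stop("oracle handles edges and triangles")
  }
  r20 <- sum((cc0 - a)^2)
  k <- ncol(dirs)
  if (!length(others)) {
    return(r20)
  }
  # constraint per other point q: |q - c(t)|^2 >= |a - c(t)|^2, c(t) = cc0 + dirs t
  # expands to: (|q|^2 - |a|^2 - 2 (q-a).cc0) - 2 (q-a).dirs t >= 0
  Q <- X[others, , drop = FALSE]
  const <- rowSums(Q^2) - sum(a^2) - 2 * as.vector((Q - matrix(a, nrow(Q), 3, byrow = TRUE)) %*% cc0)
  Amat <- -2 * (Q - matrix(a, nrow(Q), 3, byrow = TRUE)) %*% dirs
  feas <- function(t) all(const + Amat %*% t >= -1e-9 * max(1, abs(const)))
  cand <- list(rep(0, k))
  if (k == 1) {
    # 1-D: boundaries of each constraint
    for (i in seq_along(const)) {
      if (abs(Amat[i, 1]) > 1e-300) cand[[length(cand) + 1]] <- -const[i] / Amat[i, 1]
    }
  } else {
    # 2-D: projections onto single constraint lines and pairwise intersections
    for (i in seq_along(const)) {
      ai <- Amat[i, ]
      na2 <- sum(ai^2)
      if (na2 > 1e-300) cand[[length(cand) + 1]] <- -const[i] * ai / na2
      if (i < length(const)) {
        for (j in (i + 1):length(const)) {
          M2 <- rbind(Amat[i, ], Amat[j, ])
          if (abs(det(M2)) > 1e-300) {
            cand[[length(cand) + 1]] <- solve(M2, -c(const[i], const[j]))
          }
        }
      }
    }
  }
  best <- Inf
  for (t in cand) {
    t <- as.numeric(t)
    if (length(t) != k || any(!is.finite(t))) next
    if (feas(t)) best <- min(best, sum(t^2))
  }
  if (!is.finite(best)) {
    return(NA_real_)  # not in the alpha complex at any scale (non-Delaunay)
  }
  r20 + best
}

# full filtered complex of a 3-D point set, by definition
oracle_alpha_complex <- function(X) {
  tets <- oracle_delaunay_tets(X)
  tri_keys <- unique(do.call(rbind, apply(tets, 1, function(r) t(utils::combn(r, 3)), simplify = FALSE)))
  edge_keys <- unique(do.call(rbind, apply(tets, 1, function(r) t(utils::combn(r, 2)), simplify = FALSE)))
  tet_f <- apply(tets, 1, function(id) oracle_circumsphere(X[id, ])$r2)
  tri_f <- apply(tri_keys, 1, function(id) oracle_alpha_value(X, id))
  edge_f <- apply(edge_keys, 1, function(id) oracle_alpha_value(X, id))
  list(
    tets = tets, tris = tri_keys, edges = edge_keys,
    tet_f = tet_f, tri_f = tri_f, edge_f = edge_f
  )
}

# dense Z/2 reduction of the full boundary matrix; returns degree-1 pairs
oracle_persistence_h1 <- function(X, min_persistence = 1e-12) {
  cx <- oracle_alpha_complex(X)
  n <- nrow(X)
  simp <- c(
    lapply(seq_len(n), function(i) list(dim = 0, v = i, f = 0)),
    lapply(seq_len(nrow(cx$edges)), function(i) list(dim = 1, v = cx$edges[i, ], f = cx$edge_f[i])),
    lapply(seq_len(nrow(cx$tris)), function(i) list(dim = 2, v = cx$tris[i, ], f = cx$tri_f[i])),
    lapply(seq_len(nrow(cx$tets)), function(i) list(dim = 3, v = cx$tets[i, ], f = cx$tet_f[i]))
  )
  fs <- vapply(simp, `[[`, numeric(1), "f")
  ds <- vapply(simp, `[[`, numeric(1), "dim")
  ord <- order(fs, ds)
  simp <- simp[ord]
  m <- length(simp)
  key <- vapply(simp, function(s) paste(s$dim, paste(sort(s$v), collapse = "-")), "")
  idx <- stats::setNames(seq_len(m), key)
  B <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$dim == 0) next
    for (drop in seq_along(s$v)) {
      face <- sort(s$v[-drop])
      B[idx[[paste(s$dim - 1, paste(face, collapse = "-"))]], j] <- TRUE
    }
  }
  lows <- integer(m)
  for (j in seq_len(m)) {
    repeat {
      col <- which(B[, j])
      if (!length(col)) {
        lows[j] <- 0L
        break
      }
      low <- max(col)
      prev <- which(lows[seq_len(j - 1)] == low)
      if (!length(prev)) {
        lows[j] <- low
        break
      }
      B[, j] <- xor(B[, j], B[, prev[1]])
    }
  }
  pairs <- NULL
  for (j in seq_len(m)) {
    if (lows[j] > 0 && simp[[lows[j]]]$dim == 1) {
      birth <- simp[[lows[j]]]$f
      death <- simp[[j]]$f
      if (death - birth > min_persistence) pairs <- rbind(pairs, c(birth, death))
    }
  }
  if (is.null(pairs)) matrix(numeric(), 0, 2) else pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

# numerical-integration cross-check of the persistence heat kernel for tiny
# diagrams: inner product of the two heat-equation solutions with Dirichlet
# boundary on the diagonal (implemented by mirrored negative sources)
oracle_heat_kernel_numint <- function(F, G, sigma, lim = 8, n = 801) {
  gs <- seq(-lim, lim, length.out = n)
  h <- gs[2] - gs[1]
  solution <- function(D, t) {
    U <- matrix(0, n, n)
    for (i in seq_len(nrow(D))) {
      b <- D[i, 1]; d <- D[i, 2]
      for (s in c(1, -1)) {
        x0 <- if (s == 1) b else d
        y0 <- if (s == 1) d else b
        U <- U + s / (4 * pi * t) *
          outer(exp(-(gs - x0)^2 / (4 * t)), exp(-(gs - y0)^2 / (4 * t)))
      }
    }
    U
  }
  Uf <- solution(F, sigma)
  Ug <- solution(G, sigma)
  upper <- outer(gs, gs, function(x, y) y > x)  # the domain is above the diagonal
  sum(Uf * Ug * upper) * h^2
}
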