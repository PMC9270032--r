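test_that("subsampling is deterministic, exact and leak-free", {
  set.seed(1)
  pc <- point_cloud(matrix(runif(300, 0, 50), 100, 3), "a1", sex = "female")
  ss <- subsample_cloud(pc, 40, 5, seed = 7)
  expect_length(ss$clouds, 5)
  expect_true(all(vapply(ss$clouds, n_points, integer(1)) == 40L))
  # drawn without replacement from the parent
  for (cl in ss$clouds) {
    expect_equal(anyDuplicated(cl$points), 0)
    expect_true(all(apply(cl$points, 1, function(r) {
      any(colSums(abs(t(pc$points) - r)) < 1e-12)
    })))
    expect_equal(cl$animal_id, "a1")
    expect_equal(cl$sex, "female")
  }
  ss2 <- subsample_cloud(pc, 40, 5, seed = 7)
  expect_identical(ss$clouds[[3]]$points, ss2$clouds[[3]]$points)

  # m = cloud size reproduces the parent as a multiset
  full <- subsample_cloud(pc, 100, 1, seed = 1)$clouds[[1]]
  expect_equal(full$points[order(full$points[, 1]), ],
               pc$points[order(pc$points[, 1]), ])

  expect_error(subsample_cloud(pc, 101, 1), "cannot subsample")
})

test_that("an equilateral triangle yields the analytic degree-1 pair", {
  side <- 1
  tri <- rbind(
    c(0, 0, 0),
    c(side, 0, 0),
    c(side / 2, side * sqrt(3) / 2, 0)
  )
  d <- alpha_persistence_degree1(point_cloud(tri))
  expect_equal(nrow(d$pairs), 1)
  expect_equal(unname(d$pairs[1, "birth"]), 0.25, tolerance = 1e-6)   # (side/2)^2
  expect_equal(unname(d$pairs[1, "death"]), 1 / 3, tolerance = 1e-6)  # circumradius^2

  # jittered into 3D, same answer (handled by the planar branch)
  set.seed(2)
  tri3 <- tri + matrix(rnorm(9, 0, 1e-7), 3, 3)
  d3 <- alpha_persistence_degree1(point_cloud(tri3))
  expect_equal(unname(d3$pairs[1, "birth"]), 0.25, tolerance = 1e-6)
  expect_equal(unname(d3$pairs[1, "death"]), 1 / 3, tolerance = 1e-6)

  # radius units are the square roots
  dr <- alpha_persistence_degree1(point_cloud(tri), units = "radius")
  expect_equal(unname(dr$pairs[1, "birth"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(dr$pairs[1, "death"]), 1 / sqrt(3), tolerance = 1e-6)
})

test_that("a sampled circle gives the half-chord birth and radius death", {
  theta <- seq(0, 2 * pi, length.out = 21)[-1]
  ring <- cbind(cos(theta), sin(theta), 0)
  d <- alpha_persistence_degree1(point_cloud(ring))
  dom <- which.max(d$pairs[, "death"] - d$pairs[, "birth"])
  expect_equal(unname(d$pairs[dom, "birth"]), sin(pi / 20)^2, tolerance = 1e-6)
  expect_equal(unname(d$pairs[dom, "death"]), 1.0, tolerance = 1e-6)
})

test_that("degenerate inputs behave per contract", {
  expect_equal(nrow(alpha_persistence_degree1(
    point_cloud(matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE))
  )$pairs), 0)
  expect_error(
    alpha_persistence_degree1(point_cloud(cbind(1:10, 2 * (1:10), 3 * (1:10)))),
    "collinear"
  )
  expect_error(
    alpha_persistence_degree1(point_cloud(matrix(1, 5, 3))),
    "degenerate|collinear|coincide"
  )
})

test_that("diagrams match the brute-force oracle on small random clouds", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(6:8, 1)
    X <- matrix(runif(3 * n, 0, 2), n, 3)
    d <- alpha_persistence_degree1(point_cloud(X))
    imp <- d$pairs[order(d$pairs[, 1], d$pairs[, 2]), , drop = FALSE]
    orc <- oracle_persistence_h1(X)
    expect_equal(nrow(imp), nrow(orc))
    if (nrow(imp)) {
      expect_equal(unname(imp), unname(orc), tolerance = 1e-9)
    }
  }
})

test_that("persistence is invariant to reordering and rigid motion, and
           scales as squared lengths", {
  set.seed(12)
  X <- matrix(runif(120, 0, 10), 40, 3)
  base <- alpha_persistence_degree1(point_cloud(X))$pairs
  perm <- alpha_persistence_degree1(point_cloud(X[sample(40), ]))$pairs
  expect_equal(sort(base[, 1]), sort(perm[, 1]), tolerance = 1e-9)
  expect_equal(sort(base[, 2]), sort(perm[, 2]), tolerance = 1e-9)

  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  moved <- alpha_persistence_degree1(
    point_cloud(sweep(X %*% t(R), 2, c(3, -7, 2), "+"))
  )$pairs
  expect_equal(sort(base[, 1]), sort(moved[, 1]), tolerance = 1e-8)
  expect_equal(sort(base[, 2]), sort(moved[, 2]), tolerance = 1e-8)

  s <- 2.5
  scaled <- alpha_persistence_degree1(point_cloud(s * X))$pairs
  expect_equal(sort(scaled[, 1]), s^2 * sort(base[, 1]), tolerance = 1e-8)
  expect_equal(sort(scaled[, 2]), s^2 * sort(base[, 2]), tolerance = 1e-8)
})

test_that("a planted circle among background dies near its squared radius", {
  # balls centred on a circle of radius R cover its disk exactly at
  # squared radius R^2, so the loop's death is R^2 provided no background
  # point spans the disk earlier (background kept outside 2.5 R)
  R <- 12
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    ang <- seq(0, 2 * pi, length.out = 31)[-1]
    ring <- cbind(R * cos(ang), R * sin(ang), 0) +
      matrix(rnorm(90, 0, 0.3), 30, 3)
    bg <- cbind(runif(80, -70, 70), runif(80, -70, 70), runif(80, -40, 40))
    keep <- sqrt(rowSums(bg^2)) > 2.5 * R
    d <- alpha_persistence_degree1(point_cloud(rbind(ring, bg[keep, ])))
    p <- d$pairs[, 2] - d$pairs[, 1]
    if (any(abs(d$pairs[, 2] - R^2) < 0.15 * R^2 & p > 0.25 * R^2)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("the heat kernel matches its closed form and the heat-equation
           inner product", {
  F1 <- matrix(c(0, 1), 1, 2)
  expect_equal(heat_kernel(F1, F1, sigma = 0.01),
               1 / (8 * pi * 0.01) * (1 - exp(-2 / 0.08)),
               tolerance = 1e-7) # ~3.97887
  # independent numerical integration of the two heat solutions
  set.seed(3)
  G <- matrix(c(0.2, 0.8, 0.5, 1.4), 2, 2, byrow = TRUE)
  expect_equal(heat_kernel(F1, G, 0.05),
               oracle_heat_kernel_numint(F1, G, 0.05, lim = 4, n = 1201),
               tolerance = 1e-4)
  expect_equal(heat_kernel(G, G, 0.02),
               oracle_heat_kernel_numint(G, G, 0.02, lim = 4, n = 1201),
               tolerance = 1e-4)

  # empty diagrams and far-separated diagrams
  empty <- matrix(numeric(), 0, 2)
  expect_equal(heat_kernel(empty, G, 0.01), 0)
  expect_equal(heat_kernel(F1, matrix(c(100, 101), 1, 2), 0.01), 0)

  expect_error(heat_kernel(F1, G, sigma = 0), "positive")
  expect_error(heat_kernel(matrix(c(1, 0.5), 1, 2), G, 0.01), "invalid diagram")
})

random_diagram <- function(k) {
  b <- runif(k, 0, 3)
  cbind(b, b + rexp(k, 2))
}

test_that("the heat kernel satisfies Cauchy-Schwarz on random diagrams", {
  set.seed(4)
  for (i in 1:15) {
    F1 <- random_diagram(sample(1:8, 1))
    G1 <- random_diagram(sample(1:8, 1))
    k12 <- heat_kernel(F1, G1, 0.05)
    expect_lte(k12^2,
               heat_kernel(F1, F1, 0.05) * heat_kernel(G1, G1, 0.05) + 1e-12)
  }
})

test_that("heat-kernel Gram matrices are symmetric and PSD", {
  set.seed(5)
  diags <- lapply(1:10, function(i) {
    new <- random_diagram(sample(3:12, 1))
    structure(list(degree = 1L, pairs = new), class = "persistence_diagram")
  })
  gram <- gram_matrix(diags, group_ids = rep(letters[1:5], each = 2),
                      sigma = 0.01)
  K <- gram$matrix
  expect_lt(max(abs(K - t(K))), 1e-9 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  # duplicated diagrams: equal rows, still PSD
  gram2 <- gram_matrix(c(diags[1], diags[1], diags[2]), sigma = 0.01)
  expect_equal(gram2$matrix[1, ], gram2$matrix[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  ev2 <- eigen(gram2$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev2), -1e-8 * max(ev2))

  g1 <- gram_matrix(diags[1], sigma = 0.01)
  expect_equal(dim(g1$matrix), c(1L, 1L))
  expect_equal(g1$matrix[1, 1], heat_kernel(diags[[1]], diags[[1]], 0.01))
})

test_that("the feature RBF kernel follows its stated convention", {
  f <- rbind(a = c(0, 0), b = c(1e5, 0), c = c(0, 0))
  g <- rbf_feature_gram(f, bandwidth = 1e5)
  expect_equal(unname(diag(g$matrix)), rep(1, 3))
  expect_equal(g$matrix[1, 3], 1) # identical rows
  expect_equal(g$matrix[1, 2], exp(-1 / 2), tolerance = 1e-12)

  wide <- rbf_feature_gram(f, bandwidth = 1e12)
  expect_true(all(wide$matrix > 1 - 1e-10)) # bandwidth -> Inf: all ones

  alt <- rbf_feature_gram(f, bandwidth = 1e10, convention = "exp_d2_over_bw")
  expect_equal(alt$matrix[1, 2], exp(-1), tolerance = 1e-12)

  expect_error(rbf_feature_gram(f, bandwidth = 0), "positive")
})
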