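# independent 26-neighbourhood local-maximum counter used to check phantoms
count_maxima_r <- function(arr, floor_value) {
  d <- dim(arr)
  n <- 0
  for (z in 2:(d[1] - 1)) {
    for (y in 2:(d[2] - 1)) {
      for (x in 2:(d[3] - 1)) {
        v <- arr[z, y, x]
        if (v < floor_value) next
        nb <- arr[(z - 1):(z + 1), (y - 1):(y + 1), (x - 1):(x + 1)]
        if (v >= max(nb)) n <- n + 1
      }
    }
  }
  n
}

test_that("noiseless phantoms contain exactly the planted local maxima", {
  spec <- phantom_spec(
    n_nuclei = 25, noise_sd = 0, seed = 42,
    volume_shape_vox = c(30, 120, 120)
  )
  ph <- generate_phantom(spec)
  expect_equal(n_points(ph$truth), 25L)
  expect_true(all(ph$truth$points >= 0))
  expect_equal(
    count_maxima_r(ph$volume$intensities, spec$background + 0.5 * spec$peak_intensity),
    25L
  )
  expect_gte(min(dist(ph$truth$points)), spec$min_separation_um)
})

test_that("rendered blob centres match the truth cloud to < 0.25 voxel", {
  spec <- phantom_spec(n_nuclei = 10, noise_sd = 0, seed = 7,
                       volume_shape_vox = c(30, 100, 100))
  ph <- generate_phantom(spec)
  arr <- ph$volume$intensities - spec$background
  sp <- spec$spacing
  worst <- 0
  for (i in seq_len(10)) {
    tr <- ph$truth$points[i, ]
    # intensity-weighted centroid in a window around the truth
    iz <- which(abs((seq_len(dim(arr)[1]) - 1) * sp[3] - tr[3]) <= 3)
    iy <- which(abs((seq_len(dim(arr)[2]) - 1) * sp[2] - tr[2]) <= 3)
    ix <- which(abs((seq_len(dim(arr)[3]) - 1) * sp[1] - tr[1]) <= 3)
    # sharpened weights (intensity^4) suppress window-truncation bias
    w <- arr[iz, iy, ix, drop = FALSE]^4
    cz <- sum(apply(w, 1, sum) * (iz - 1) * sp[3]) / sum(w)
    cy <- sum(apply(w, 2, sum) * (iy - 1) * sp[2]) / sum(w)
    cx <- sum(apply(w, 3, sum) * (ix - 1) * sp[1]) / sum(w)
    # error in voxel units, per axis
    err_vox <- abs(c(cx - tr[1], cy - tr[2], cz - tr[3])) / sp
    worst <- max(worst, err_vox)
  }
  expect_lt(worst, 0.25)
})

test_that("phantom generation is deterministic and edge cases behave", {
  spec <- phantom_spec(n_nuclei = 5, seed = 3, volume_shape_vox = c(20, 60, 60))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$truth$points, b$truth$points)
  c <- generate_phantom(phantom_spec(n_nuclei = 5, seed = 4,
                                     volume_shape_vox = c(20, 60, 60)))
  expect_false(identical(a$truth$points, c$truth$points))

  blank <- generate_phantom(phantom_spec(n_nuclei = 0, noise_sd = 0,
                                         volume_shape_vox = c(5, 10, 10)))
  expect_equal(n_points(blank$truth), 0L)
  expect_equal(unique(as.vector(blank$volume$intensities)), 0.1)

  # infeasible packing must fail loudly, not hang or silently under-place
  expect_error(
    generate_phantom(phantom_spec(n_nuclei = 500, volume_shape_vox = c(12, 40, 40))),
    "attempts"
  )
})

test_that("cohorts have exact point counts and deterministic seeds", {
  spec <- cohort_spec(n_per_class = 2, points_per_cloud = 300,
                      n_loops_class0 = 1, n_loops_class1 = 5, seed = 5)
  coh <- generate_cohort(spec)
  expect_length(coh, 4)
  expect_true(all(vapply(coh, n_points, integer(1)) == 300L))
  expect_equal(unname(vapply(coh, `[[`, character(1), "sex")),
               c("female", "female", "male", "male"))
  coh2 <- generate_cohort(spec)
  expect_identical(coh$M01$points, coh2$M01$points)
  coh3 <- generate_cohort(cohort_spec(n_per_class = 2, points_per_cloud = 300,
                                      n_loops_class0 = 1, n_loops_class1 = 5,
                                      seed = 6))
  expect_false(identical(coh$M01$points, coh3$M01$points))

  expect_error(cohort_spec(points_per_cloud = 100, n_loops_class1 = 10,
                           loop_points = 20), "infeasible")
})

test_that("a null cohort uses identical generative parameters for both classes", {
  spec <- cohort_spec(n_per_class = 3, points_per_cloud = 200,
                      n_loops_class0 = 4, n_loops_class1 = 4, seed = 11)
  coh <- generate_cohort(spec)
  counts <- vapply(coh, n_points, integer(1))
  expect_true(all(counts == 200L))
  # all points stay within the envelope inflated by the loop geometry
  # (loop centres are inside 0.8x the envelope; loop points can protrude by
  # at most the loop radius plus jitter)
  margin <- spec$loop_radius_um + 5 * spec$loop_jitter_um
  r2 <- vapply(coh, function(pc) {
    max(rowSums(sweep(pc$points, 2, spec$envelope_semiaxes_um + margin, "/")^2))
  }, numeric(1))
  expect_true(all(r2 <= 1 + 1e-9))
})

test_that("extra planted loops enrich high-persistence degree-1 features", {
  # 20 extra loops of radius 15 in class 1: its diagrams should carry more
  # points with persistence above (loop_radius / 2)^2 than class 0, on
  # average (checked over three independent cohorts)
  thr <- (15 / 2)^2
  for (seed in c(21, 22, 23)) {
    coh <- generate_cohort(cohort_spec(
      n_per_class = 2, points_per_cloud = 400,
      envelope_semiaxes_um = c(50, 40, 30),
      n_loops_class0 = 0, n_loops_class1 = 20,
      loop_radius_um = 15, loop_points = 12, loop_jitter_um = 0.5,
      seed = seed
    ))
    high <- vapply(coh, function(pc) {
      d <- alpha_persistence_degree1(pc)
      sum(d$pairs[, 2] - d$pairs[, 1] > thr)
    }, numeric(1))
    cls <- vapply(coh, `[[`, character(1), "sex")
    expect_gt(mean(high[cls == "male"]), mean(high[cls == "female"]))
  }
})
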