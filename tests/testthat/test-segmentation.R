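test_that("curvature flow is the identity at 0 iterations and fixes flats", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 3, seed = 1, noise_sd = 0.03,
                                      volume_shape_vox = c(20, 60, 60)))
  out0 <- denoise_curvature_flow(ph$volume, iterations = 0)
  expect_identical(out0$intensities, ph$volume$intensities)

  flat <- volume_image(array(0.4, c(8, 8, 8)), c(1, 1, 1))
  out <- denoise_curvature_flow(flat, iterations = 10)
  expect_equal(out$intensities, flat$intensities, tolerance = 1e-12)

  expect_error(denoise_curvature_flow(flat, 5, timestep = 0), "positive")
})

test_that("curvature flow reduces background noise variance", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 4, seed = 2, noise_sd = 0.05,
                                      volume_shape_vox = c(24, 80, 80)))
  dn <- denoise_curvature_flow(ph$volume, iterations = 5)
  # background = voxels far from any nucleus
  sp <- ph$volume$spacing
  d <- dim(ph$volume$intensities)
  grid <- expand.grid(z = (seq_len(d[1]) - 1) * sp[3],
                      y = (seq_len(d[2]) - 1) * sp[2],
                      x = (seq_len(d[3]) - 1) * sp[1])
  mind <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(ph$truth$points))) {
    tr <- ph$truth$points[i, ]
    mind <- pmin(mind, sqrt((grid$x - tr[1])^2 + (grid$y - tr[2])^2 +
                              (grid$z - tr[3])^2))
  }
  bg <- mind > 6
  expect_lt(var(as.vector(dn$intensities)[bg]),
            var(as.vector(ph$volume$intensities)[bg]))
})

test_that("blob detection recovers planted nuclei with subvoxel centroids", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 30, seed = 5, noise_sd = 0.03,
                                      volume_shape_vox = c(36, 160, 160)))
  dn <- denoise_curvature_flow(ph$volume)
  seg <- filter_by_volume(detect_blobs(dn), 15)
  expect_equal(nrow(seg$per_object), 30)
  pc <- extract_centroids(seg, animal_id = "ph5")
  D <- as.matrix(dist(rbind(ph$truth$points, pc$points)))[1:30, -(1:30)]
  rmse <- sqrt(mean(apply(D, 1, min)^2))
  expect_lt(rmse, 0.5)
})

test_that("blank volumes yield zero objects", {
  blank <- generate_phantom(phantom_spec(n_nuclei = 0, noise_sd = 0,
                                         volume_shape_vox = c(10, 30, 30)))
  seg <- detect_blobs(blank$volume)
  expect_equal(nrow(seg$per_object), 0)
  pc <- extract_centroids(seg)
  expect_equal(n_points(pc), 0L)
})

test_that("two nuclei at >= 6 um separation are never merged", {
  # hand-placed pair exactly 6 um apart along x
  spec <- phantom_spec(n_nuclei = 0, noise_sd = 0, volume_shape_vox = c(24, 90, 90))
  ph <- generate_phantom(spec)
  arr <- ph$volume$intensities
  sp <- spec$spacing
  sigma <- 4.5 / (2 * sqrt(2 * log(2)))
  add_blob <- function(arr, ctr) {
    xs <- (seq_len(dim(arr)[3]) - 1) * sp[1]
    ys <- (seq_len(dim(arr)[2]) - 1) * sp[2]
    zs <- (seq_len(dim(arr)[1]) - 1) * sp[3]
    g <- 0.8 * outer(exp(-(zs - ctr[3])^2 / (2 * sigma^2)),
                     outer(exp(-(ys - ctr[2])^2 / (2 * sigma^2)),
                           exp(-(xs - ctr[1])^2 / (2 * sigma^2))))
    arr + g
  }
  arr <- add_blob(arr, c(10, 14, 12))
  arr <- add_blob(arr, c(16, 14, 12))
  seg <- detect_blobs(volume_image(arr, sp))
  expect_equal(nrow(seg$per_object), 2)
  expect_equal(sort(seg$per_object$x_um), c(10, 16), tolerance = 0.05)
})

test_that("the volume filter implements the published sphere threshold", {
  # analytic sphere volumes: d = 3 um -> 14.14 um^3 (removed at 15),
  # d = 4.5 um -> 47.71 um^3 (kept)
  seg <- structure(
    list(
      labels = array(c(1L, 2L, 0L, 0L), c(1, 2, 2)),
      per_object = data.frame(
        object_id = 1:2,
        volume_um3 = c(4 / 3 * pi * 1.5^3, 4 / 3 * pi * 2.25^3),
        x_um = c(1, 2), y_um = c(1, 2), z_um = c(0, 0),
        peak_intensity = c(1, 1)
      ),
      spacing = c(1, 1, 1)
    ),
    class = "segmentation_result"
  )
  kept <- filter_by_volume(seg, 15)
  expect_equal(nrow(kept$per_object), 1)
  expect_equal(kept$per_object$volume_um3, 4 / 3 * pi * 2.25^3)
  expect_equal(kept$per_object$object_id, 1L) # ids re-densified
  expect_equal(sort(unique(as.vector(kept$labels))), c(0L, 1L))

  expect_identical(filter_by_volume(seg, 0)$per_object, seg$per_object)
  expect_error(filter_by_volume(seg, -1), "non-negative")
})

test_that("volume filters compose as max(a, b)", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 12, seed = 9, noise_sd = 0.02,
                                      volume_shape_vox = c(30, 110, 110)))
  seg <- detect_blobs(denoise_curvature_flow(ph$volume))
  a <- 20
  b <- 60
  ab <- filter_by_volume(filter_by_volume(seg, a), b)
  direct <- filter_by_volume(seg, max(a, b))
  expect_equal(ab$per_object, direct$per_object)
})

test_that("detection is equivariant to global intensity scaling", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 8, seed = 11, noise_sd = 0.02,
                                      volume_shape_vox = c(26, 90, 90)))
  seg1 <- detect_blobs(ph$volume)
  scaled <- volume_image(ph$volume$intensities * 37.5, ph$volume$spacing)
  seg2 <- detect_blobs(scaled)
  expect_equal(nrow(seg1$per_object), nrow(seg2$per_object))
  expect_equal(seg1$per_object$x_um, seg2$per_object$x_um, tolerance = 1e-9)
  expect_equal(seg1$per_object$volume_um3, seg2$per_object$volume_um3)
})

test_that("centroid export maps voxel indices to world micrometres", {
  # a single-voxel object at 0-based (z, y, x) = (10, 20, 30) with spacing
  # (0.317, 0.317, 1.0) sits at (9.51, 6.34, 10.0) um
  labels <- array(0L, c(16, 32, 40))
  labels[11, 21, 31] <- 1L
  seg <- structure(
    list(
      labels = labels,
      per_object = data.frame(
        object_id = 1L, volume_um3 = 0.317 * 0.317 * 1,
        x_um = 30 * 0.317, y_um = 20 * 0.317, z_um = 10 * 1.0,
        peak_intensity = 1
      ),
      spacing = c(0.317, 0.317, 1.0)
    ),
    class = "segmentation_result"
  )
  pc <- extract_centroids(seg, animal_id = "vx")
  expect_equal(unname(pc$points[1, ]), c(9.51, 6.34, 10.0))
})

test_that("concordance reports match the published comparison", {
  r <- concordance_report(9444, 9430)
  expect_equal(r$difference, 14L)
  expect_equal(r$percent, 100 * 14 / 9430)
  expect_equal(concordance_report(100, 100), list(difference = 0L, percent = 0))
  r2 <- concordance_report(101, 100)
  expect_equal(r2$difference, 1L)
  expect_equal(r2$percent, 1)
  expect_error(concordance_report(5, 0), "zero")
})
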