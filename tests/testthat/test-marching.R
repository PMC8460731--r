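test_that("isosurface of a voxelized ball is closed with accurate area", {
  n <- 26
  g <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  ball <- array(as.numeric(rowSums((g - 12.5)^2) < 100), rep(n, 3))
  lab <- label_volume(ball)
  m <- surface_from_labels(lab, 0.5, smooth_sigma = 1)
  expect_true(historeg:::mesh_is_closed(m))
  expect_lt(abs(mesh_area(m) / (4 * pi * 100) - 1), 0.05)
  ## vertices near the true boundary (within half a voxel)
  r <- sqrt(rowSums(sweep(m$vertices, 2, rep(12.5, 3))^2))
  expect_lt(max(abs(r - 10)), 0.5)
  ## outward orientation: normals point away from the centre
  nor <- face_normals(m); cen <- face_centers(m)
  expect_true(all(rowSums(nor * sweep(cen, 2, rep(12.5, 3))) > 0))
  expect_error(surface_from_labels(label_volume(array(0, c(4, 4, 4)))),
               class = "historeg_empty_error")
})

test_that("surface extraction respects world geometry", {
  n <- 20
  g <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  ball <- array(as.numeric(rowSums(sweep(sweep(g, 2, c(10, 10, 10)), 2,
                                         c(1, 1, 2), "*")^2) < 49), rep(n, 3))
  lab <- label_volume(ball, spacing = c(1, 1, 2), origin = c(5, -3, 0))
  m <- surface_from_labels(lab, 0.5, smooth_sigma = 1)
  ctr <- c(5, -3, 0) + c(10, 10, 20)
  r <- sqrt(rowSums(sweep(m$vertices, 2, ctr)^2))
  expect_lt(abs(mean(r) - 7), 0.5)   # 7 mm ball in anisotropic voxels
})

test_that("label_surface upsampling preserves thin slabs", {
  slab <- array(0, c(20, 20, 7))
  slab[4:17, 4:17, 3:5] <- 1        # 3 mm thick at 1 mm spacing
  lab <- label_volume(slab)
  direct <- surface_from_labels(lab, 0.5, smooth_sigma = 1)
  fine <- label_surface(lab, target_spacing = 0.5)
  ## smoothing at native resolution erodes the slab; upsampling does not
  expect_gt(mesh_area(fine), mesh_area(direct))
  expect_gt(mesh_area(fine), 0.85 * (2 * 14^2 + 4 * 14 * 3))
})

test_that("vertex-clustering decimation preserves coarse geometry", {
  m <- ellipsoid_mesh(c(10, 8, 6), n_theta = 24, n_phi = 24)
  d <- decimate_mesh(m, 1.5)
  expect_lt(nrow(d$faces), nrow(m$faces))
  expect_lt(abs(mesh_area(d) / mesh_area(m) - 1), 0.15)
  ## every decimated vertex lies near the original surface
  dmin <- apply(historeg:::cross_dist_sq(d$vertices, m$vertices), 1, min)
  expect_lt(max(sqrt(dmin)), 1.5)
})
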