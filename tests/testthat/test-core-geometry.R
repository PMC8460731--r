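test_that("world/voxel conversion is exact and invertible", {
  vol <- image_volume(array(0, c(4, 5, 6)), spacing = c(0.5, 1, 2),
                      origin = c(10, -3, 2), orientation = rot3(c(0, 0, 1), 0.3))
  expect_equal(world_to_voxel(vol, vol$origin), matrix(0, 1, 3))
  step <- vol$origin + as.vector(vol$orientation %*% (vol$spacing * c(1, 1, 1)))
  expect_equal(world_to_voxel(vol, step), matrix(1, 1, 3), tolerance = 1e-12)
  set.seed(1)
  x <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_lt(max(abs(voxel_to_world(vol, world_to_voxel(vol, x)) - x)), 1e-9)
})

test_that("invalid image geometry is rejected", {
  expect_error(image_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               class = "historeg_geometry_error")
  expect_error(image_volume(array(0, c(2, 2, 2)), orientation = diag(3) * 2),
               class = "historeg_geometry_error")
  expect_error(label_volume(array(0.5, c(2, 2, 2))),
               class = "historeg_geometry_error")
})

test_that("transform chains compose sequentially and invert", {
  expect_equal(apply_chain(transform_chain(), matrix(1:6, 2, 3)),
               matrix(as.numeric(1:6), 2, 3))
  ch <- transform_chain(translation_transform(c(1, 0, 0)),
                        translation_transform(c(0, 2, 0)))
  expect_equal(apply_chain(ch, c(0, 0, 0)), matrix(c(1, 2, 0), 1, 3))
  A <- affine_transform(rot3(c(1, 2, 3), 0.4), c(2, -1, 5))
  pair <- transform_chain(A, chain_element(A, "inverse"))
  set.seed(2)
  pts <- matrix(rnorm(60), 20, 3)
  expect_lt(max(abs(apply_chain(pair, pts) - pts)), 1e-9)
})

test_that("chain application is associative over element grouping", {
  set.seed(3)
  T1 <- affine_transform(rot3(rnorm(3), 0.2), rnorm(3))
  T2 <- translation_transform(c(0.5, -1, 2))
  T3 <- affine_transform(diag(3) * 1.1, c(0, 1, 0))
  pts <- matrix(rnorm(90), 30, 3)
  a <- apply_chain(T3, apply_chain(transform_chain(T1, T2), pts))
  b <- apply_chain(transform_chain(T2, T3), apply_chain(T1, pts))
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("diffeomorphisms satisfy Jacobian and inverse-consistency checks", {
  set.seed(4)
  v <- array(rnorm(6 * 6 * 6 * 3, sd = 0.5), c(6, 6, 6, 3))
  for (c in 1:3) v[, , , c] <- historeg:::gaussian_smooth_array(v[, , , c], 1.5)
  phi <- diffeomorphism(
    lapply(1:4, function(k) grid_velocity_step(v, c(3, 3, 3), c(-8, -8, -8),
                                               dt = 1 / 4)),
    domain_bounds = rbind(c(-6, -6, -6), c(6, 6, 6)))
  chk <- check_diffeomorphism(phi)
  expect_true(chk$ok)
  expect_gt(chk$min_jacobian, 0)
  ## a violently folding field is rejected at construction
  vbad <- v * 40
  expect_error(
    diffeomorphism(list(grid_velocity_step(vbad, c(3, 3, 3), c(-8, -8, -8))),
                   domain_bounds = rbind(c(-6, -6, -6), c(6, 6, 6))),
    class = "historeg_diffeo_error")
})

test_that("2D transforms act in-plane on 3D points", {
  A2 <- affine_transform(matrix(c(0, 1, -1, 0), 2, 2), c(1, 0))  # +90 deg
  p <- matrix(c(2, 0, 7), 1, 3)
  out <- apply_chain(A2, p)
  expect_equal(out[1, 3], 7)           # depth untouched
  expect_equal(out[1, 1:2], c(1, 2))   # rotated + shifted in-plane
})

test_that("mesh transforms preserve counts and connectivity", {
  m <- ellipsoid_mesh(c(3, 2, 1), n_theta = 8, n_phi = 8)
  A <- affine_transform(rot3(c(1, 1, 0), 0.5), c(4, 5, 6))
  m2 <- transform_mesh(m, A)
  expect_identical(dim(m2$vertices), dim(m$vertices))
  expect_identical(m2$faces, m$faces)
})

test_that("landmark sets enforce unique labels and transform correctly", {
  expect_error(landmark_set(matrix(0, 2, 3), labels = c("a", "a")),
               class = "historeg_parameter_error")
  lm <- landmark_set(matrix(rnorm(9), 3, 3), space = "block")
  moved <- transform_landmarks(lm, translation_transform(c(1, 2, 3)), "ex")
  expect_equal(moved$points, sweep(lm$points, 2, c(1, 2, 3), "+"))
  expect_equal(moved$space, "ex")
})
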