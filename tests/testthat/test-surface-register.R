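test_that("affine surface registration recovers rigid motions of an ellipsoid", {
  set.seed(10)
  m <- ellipsoid_mesh(c(10, 8, 6), n_theta = 14, n_phi = 14)
  for (trial in 1:3) {
    ang <- runif(1, -15, 15) * pi / 180
    A <- affine_transform(rot3(rnorm(3), ang), runif(3, -5, 5))
    tgt <- transform_mesh(m, A)
    res <- affine_register_surfaces(m, tgt, currents_params(sigma = 2))
    moved <- transform_mesh(m, res$transform)
    expect_lt(mean(row_norms_test(moved$vertices - tgt$vertices)), 0.05)
    ## per-scale energy traces are non-increasing
    for (tr in res$energy) if (length(tr) > 1) expect_true(all(diff(tr) <= 0))
  }
  ## identity case
  same <- affine_register_surfaces(m, m, currents_params(sigma = 2))
  sm <- transform_mesh(m, same$transform)
  expect_lt(mean(row_norms_test(sm$vertices - m$vertices)), 0.02)
})

test_that("rigid model cannot shear or collapse flat faces", {
  set.seed(11)
  ## a flat irregular disk: open surface with unconstrained affine modes
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  rad <- 5 + 1.5 * sin(3 * th)
  v <- rbind(c(0, 0, 0), cbind(rad * cos(th), rad * sin(th), 0))
  f <- cbind(1, 2:21, c(3:21, 2))
  disk <- triangle_mesh(v, f, check_degenerate = FALSE)
  tgt <- transform_mesh(disk, translation_transform(c(0.8, -0.4, 0.3)))
  res <- affine_register_surfaces(disk, tgt, currents_params(sigma = 2),
                                  model = "rigid")
  expect_lt(abs(det(res$transform$linear) - 1), 1e-6)   # orthogonal
  expect_lt(max(abs(res$transform$translation - c(0.8, -0.4, 0.3))), 0.1)
})

test_that("diffeomorphic surface registration recovers a smooth bump", {
  set.seed(12)
  m <- ellipsoid_mesh(c(10, 8, 6), n_theta = 12, n_phi = 12)
  ctr <- c(6, 0, 4)
  w <- exp(-rowSums(sweep(m$vertices, 2, ctr)^2) / 18)
  tgt <- triangle_mesh(m$vertices + 0.8 * cbind(w, 0.5 * w, -0.3 * w),
                       m$faces, check_degenerate = FALSE)
  res <- diffeo_register_surfaces(m, tgt,
                                  currents_params(sigma = 2,
                                                  velocity_kernel_scale = 3,
                                                  step_size = 0.3,
                                                  max_iters = 120))
  expect_identical(res$status, "ok")
  expect_lt(mean(row_norms_test(res$moved$vertices - tgt$vertices)), 0.2)
  expect_true(all(diff(res$energy) <= 1e-12))
  ## the returned flow reproduces the optimized vertices
  again <- transform_mesh(m, res$transform)
  expect_lt(max(row_norms_test(again$vertices - res$moved$vertices)), 1e-9)
  ## identity case: near-identity map
  same <- diffeo_register_surfaces(m, m, currents_params(sigma = 2, max_iters = 30))
  expect_lt(max(row_norms_test(same$moved$vertices - m$vertices)), 0.01)
})

test_that("z-translation-only flows recover z-shifts without in-plane z variation", {
  m <- ellipsoid_mesh(c(8, 7, 5), n_theta = 12, n_phi = 12)
  tgt <- transform_mesh(m, translation_transform(c(0, 0, 0.4)))
  res <- diffeo_register_surfaces(m, tgt,
                                  currents_params(sigma = 2, step_size = 0.2,
                                                  max_iters = 80),
                                  constraint = "z_translation_only")
  dz <- res$moved$vertices[, 3] - m$vertices[, 3]
  expect_lt(abs(mean(dz) - 0.4), 0.05)
  expect_lt(stats::sd(dz), 1e-10)
})

test_that("produced surface flows honour diffeomorphism invariants", {
  set.seed(13)
  m <- ellipsoid_mesh(c(6, 5, 4), n_theta = 10, n_phi = 10)
  w <- exp(-rowSums(sweep(m$vertices, 2, c(3, 0, 2))^2) / 12)
  tgt <- triangle_mesh(m$vertices + cbind(0.6 * w, 0, 0.3 * w), m$faces,
                       check_degenerate = FALSE)
  res <- diffeo_register_surfaces(m, tgt, currents_params(sigma = 2, max_iters = 60))
  chk <- check_diffeomorphism(res$transform, n = 5)
  expect_true(chk$ok)
  expect_gt(chk$min_jacobian, 0)
})

test_that("grid discretization of a kernel flow preserves the mapping", {
  set.seed(14)
  m <- ellipsoid_mesh(c(6, 5, 4), n_theta = 10, n_phi = 10)
  w <- exp(-rowSums(sweep(m$vertices, 2, c(3, 0, 2))^2) / 12)
  tgt <- triangle_mesh(m$vertices + cbind(0.6 * w, 0, 0), m$faces,
                       check_degenerate = FALSE)
  res <- diffeo_register_surfaces(m, tgt, currents_params(sigma = 2, max_iters = 40))
  fast <- discretize_diffeomorphism(res$transform, spacing = 0.7)
  pts <- m$vertices[seq(1, nrow(m$vertices), by = 3), ]
  a <- apply_diffeomorphism(res$transform, pts)
  b <- apply_diffeomorphism(fast, pts)
  expect_lt(max(row_norms_test(a - b)), 0.05)
})
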