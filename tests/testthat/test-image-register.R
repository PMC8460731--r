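test_that("sum-of-squares energy matches closed forms and a voxel-sum oracle", {
  im0 <- image2d(matrix(1:12, 3, 4), c(1, 1), c(0, 0))
  expect_equal(sse_energy(im0, im0), 0)
  c1 <- image2d(matrix(2, 3, 4), c(0.5, 2), c(0, 0))
  c2 <- image2d(matrix(5, 3, 4), c(0.5, 2), c(0, 0))
  expect_equal(sse_energy(c1, c2), 9 * 12 * 0.5 * 2)  # c^2 * domain measure
  set.seed(1)
  a <- image_volume(array(rnorm(512), c(8, 8, 8)), c(1, 1, 1))
  b <- image_volume(array(rnorm(512), c(8, 8, 8)), c(1, 1, 1))
  expect_equal(sse_energy(a, b), sum((a$values - b$values)^2))
  far <- image_volume(array(0, c(2, 2, 2)), origin = c(100, 100, 100))
  expect_error(sse_energy(a, far), class = "historeg_domain_error")
})

test_that("Cauchy-Navier smoothing is linear, self-adjoint, and low-pass", {
  set.seed(2)
  n <- c(16, 12)
  u <- array(rnorm(prod(n) * 2), c(n, 2))
  v <- array(rnorm(prod(n) * 2), c(n, 2))
  Ku <- cauchy_navier_smooth(u, c(1, 1), 1, 1)
  Kv <- cauchy_navier_smooth(v, c(1, 1), 1, 1)
  K2 <- cauchy_navier_smooth(2 * u + v, c(1, 1), 1, 1)
  expect_equal(K2, 2 * Ku + Kv, tolerance = 1e-10)          # linear
  expect_equal(sum(v * Ku), sum(u * Kv), tolerance = 1e-8)  # self-adjoint
  highfreq <- function(a) {
    d <- a - historeg:::gaussian_smooth_array(a, 1)
    sum(d^2)
  }
  expect_lt(highfreq(Ku[, , 1]) / sum(Ku^2), highfreq(u[, , 1]) / sum(u^2))
})

test_that("affine image registration recovers known shifts and rotations", {
  mkdisk <- function(transform = NULL, soft = FALSE) {
    n <- 48
    g <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1)))
    p <- if (is.null(transform)) g else apply_chain(invert_chain(transform), g)
    ## clearly anisotropic shape; `soft` gives an anti-aliased edge so the
    ## shape carries sub-pixel orientation information (a hard binary edge
    ## aliases differently on the rotated and unrotated lattices)
    r <- sqrt((p[, 1] - 24)^2 + (p[, 2] - 24)^2 / 3)
    v <- if (soft) pmin(pmax(11 - r, 0), 1.5) / 1.5 else as.numeric(r < 11)
    image2d(matrix(v, n, n), c(1, 1), c(0, 0))
  }
  prm <- image_reg_params(pyramid_levels = c(2, 1), max_iters = 80)
  fixed <- mkdisk()
  expect_error(affine_register_images(
    image2d(matrix(1, 8, 8), c(1, 1), c(0, 0)), fixed, prm),
    class = "historeg_flat_image_error")
  ## identity
  same <- affine_register_images(fixed, fixed, prm)
  expect_lt(sqrt(sum(same$transform$translation^2)), 0.1)
  ## known shift of 3 voxels
  sh <- translation_transform(c(3, -2))
  reg <- affine_register_images(mkdisk(sh), fixed, prm)
  expect_lt(max(abs(reg$transform$translation - c(3, -2))), 0.1)
  ## known 5-degree rotation about the centre.  The target must have a
  ## trivial affine stabilizer: an ellipse rotated 5 degrees equals a
  ## sheared ellipse, so rotation is unidentifiable from it under a full
  ## affine model.  A smooth random texture identifies the rotation.
  set.seed(7)
  base <- historeg:::gaussian_smooth_array(matrix(rnorm(48 * 48), 48, 48), 2)
  win <- exp(-((0:47 - 24)^2) / 200)
  base <- base * outer(win, win)   # taper so content stays in-frame
  tex <- function(transform = NULL) {
    img0 <- image2d(base, c(1, 1), c(0, 0))
    if (is.null(transform)) return(img0)
    g <- as.matrix(expand.grid(x = 0:47, y = 0:47))
    p <- apply_chain(invert_chain(transform), g)
    image2d(matrix(sample_image2d(img0, p), 48, 48), c(1, 1), c(0, 0))
  }
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rotA <- affine_transform(R, c(24, 24) - as.vector(R %*% c(24, 24)))
  reg2 <- affine_register_images(tex(rotA), tex(),
                                 image_reg_params(pyramid_levels = c(2, 1),
                                                  max_iters = 120,
                                                  presmooth_sigma = 0.5))
  ang <- atan2(reg2$transform$linear[2, 1], reg2$transform$linear[1, 1]) * 180 / pi
  expect_lt(abs(ang - 5), 0.2)
})

test_that("diffeomorphic image registration recovers a known smooth warp", {
  n <- 64
  g <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1)))
  disk <- matrix(as.numeric((g[, 1] - 32)^2 + (g[, 2] - 30)^2 < 18^2), n, n)
  I0 <- image2d(disk, c(1, 1), c(0, 0))
  ## identity case: near-identity map
  same <- diffeo_register_images(I0, I0, image_reg_params(pyramid_levels = 1,
                                                          max_iters = 20))
  probe <- cbind(runif(30, 5, 58), runif(30, 5, 58))
  moved <- apply_diffeomorphism(same$transform, probe)
  expect_lt(max(sqrt(rowSums((moved - probe)^2))), 0.05)
  ## boundary-normal radial warp, max ~1.4 px
  warp <- function(p) {
    dx <- p[, 1] - 32; dy <- p[, 2] - 30; r <- sqrt(dx^2 + dy^2) + 1e-9
    s <- 1 + 1.4 * exp(-((r - 18)^2) / 60) * cos(atan2(dy, dx))^2 / r
    cbind(32 + dx * s, 30 + dy * s)
  }
  inv_warp <- function(y) { x <- y; for (i in 1:30) x <- x - (warp(x) - y); x }
  I1 <- image2d(matrix(sample_image2d(I0, inv_warp(g)), n, n), c(1, 1), c(0, 0))
  res <- diffeo_register_images(I1, I0,
                                image_reg_params(pyramid_levels = c(2, 1),
                                                 max_iters = 80))
  expect_identical(res$status, "ok")
  wb <- round(res$warped$values)
  dice <- 2 * sum(wb * disk) / (sum(wb) + sum(disk))
  expect_gt(dice, 0.98)
  ## energy non-increasing at every accepted step of each level
  for (tr in res$energy) if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-12))
})

test_that("resampling honours transforms, grids and label value sets", {
  set.seed(3)
  img <- image2d(matrix(rnorm(15 * 11), 15, 11), c(1, 1), c(0, 0))
  same <- resample_image(img, NULL, img)
  expect_equal(same$values, img$values)
  ## one-voxel translation = integer shift of the array
  sh <- resample_image(img, translation_transform(c(1, 0)), img)
  expect_equal(sh$values[1:14, ], img$values[2:15, ])
  ## nearest-neighbour keeps binary labels binary
  lab <- image2d(matrix(rbinom(15 * 11, 1, 0.4), 15, 11), c(1, 1), c(0, 0))
  warped <- resample_image(lab, translation_transform(c(0.4, -0.3)), lab,
                           interpolation = "nearest")
  expect_true(all(warped$values %in% c(0, 1)))
})
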