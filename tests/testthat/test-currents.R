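test_that("Cauchy kernel has unit peak, symmetry, and the stated form", {
  expect_equal(cauchy_kernel(c(1, 2, 3), c(1, 2, 3), 2), 1)
  x <- c(0, 0, 0); y <- c(3, 0, 0)
  expect_equal(cauchy_kernel(x, y, 3), 0.5)   # separation == sigma
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3); b <- matrix(rnorm(30), 10, 3)
  expect_equal(cauchy_kernel(a, b, 1.7), cauchy_kernel(b, a, 1.7))
  r2 <- rowSums((a - b)^2)
  expect_equal(cauchy_kernel(a, b, 1.7), 1 / (1 + r2 / 1.7^2))
  expect_error(cauchy_kernel(x, y, 0), class = "historeg_parameter_error")
})

test_that("currents norm matches hand evaluation and is rigid-invariant", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       matrix(1:3, 1))
  ## single face: <eta, eta> k(c, c) with area-weighted normal (0, 0, 1/2)
  for (sigma in c(0.5, 1, 7)) expect_equal(currents_norm_sq(tri, sigma), 0.25)
  set.seed(2)
  m <- random_mesh(12)
  A <- affine_transform(rot3(rnorm(3), 0.8), c(5, -2, 3))
  expect_equal(currents_norm_sq(transform_mesh(m, A), 1.5),
               currents_norm_sq(m, 1.5), tolerance = 1e-12)
})

test_that("dissimilarity is zero on itself, symmetric, and separates", {
  set.seed(3)
  m1 <- random_mesh(10); m2 <- random_mesh(8, offset = c(0.5, 0, 0))
  expect_lt(abs(currents_dissimilarity(m1, m1, 1)), 1e-10)
  expect_equal(currents_dissimilarity(m1, m2, 1),
               currents_dissimilarity(m2, m1, 1))
  ## far-separated surfaces: cross term vanishes
  tri1 <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, 1))
  tri2 <- transform_mesh(tri1, translation_transform(c(10, 0, 0)))
  d <- currents_dissimilarity(tri1, tri2, 1)
  expect_equal(d, currents_norm_sq(tri1, 1) + currents_norm_sq(tri2, 1),
               tolerance = 1e-2)
  expect_error(currents_dissimilarity(triangle_mesh(matrix(0, 1, 3),
                                                    matrix(0L, 0, 3)), m1, 1),
               class = "historeg_empty_error")
})

test_that("fast evaluation matches the naive double-sum oracle", {
  set.seed(4)
  for (trial in 1:5) {
    m1 <- random_mesh(sample(5:40, 1))
    m2 <- random_mesh(sample(5:40, 1), offset = rnorm(3, sd = 0.5))
    sigma <- runif(1, 0.5, 3)
    expect_equal(currents_norm_sq(m1, sigma), oracle_norm_sq(m1, sigma),
                 tolerance = 1e-12)
    expect_equal(currents_dissimilarity(m1, m2, sigma),
                 oracle_dissimilarity(m1, m2, sigma), tolerance = 1e-12)
  }
})

test_that("dissimilarity is invariant to vertex and face ordering", {
  set.seed(5)
  m1 <- random_mesh(15); m2 <- random_mesh(12, offset = c(1, 0, 0))
  perm <- sample(nrow(m1$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m1p <- triangle_mesh(m1$vertices[perm, ],
                       matrix(inv[m1$faces], ncol = 3)[sample(nrow(m1$faces)), ],
                       check_degenerate = FALSE)
  expect_equal(currents_dissimilarity(m1p, m2, 1.2),
               currents_dissimilarity(m1, m2, 1.2), tolerance = 1e-10)
})

test_that("analytic vertex gradient matches central finite differences", {
  set.seed(6)
  for (trial in 1:3) {
    m1 <- random_mesh(6); m2 <- random_mesh(5, offset = c(0.3, 0.1, -0.2))
    sigma <- runif(1, 0.8, 2)
    g <- historeg:::currents_dissimilarity_grad(m1, m2, sigma)
    h <- 1e-6
    fd <- g * 0
    for (i in seq_len(nrow(m1$vertices))) for (c in 1:3) {
      vp <- m1$vertices; vp[i, c] <- vp[i, c] + h
      vm <- m1$vertices; vm[i, c] <- vm[i, c] - h
      fd[i, c] <- (currents_dissimilarity(
        triangle_mesh(vp, m1$faces, check_degenerate = FALSE), m2, sigma) -
          currents_dissimilarity(
            triangle_mesh(vm, m1$faces, check_degenerate = FALSE), m2, sigma)) /
        (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  }
})

test_that("block surfaces split into head, foot and exterior by normals", {
  ## axis-aligned unit cube, 12 triangles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  lab <- label_volume(array(1, c(2, 2, 2)))
  cube <- surface_from_labels(lab, 0.5, smooth_sigma = 0)
  parts <- split_block_surface(cube, c(0, 0, 1), 45)
  nz <- face_normals(cube)[, 3] / face_areas(cube)
  expect_equal(nrow(parts$head$faces), sum(nz > 0.999))
  expect_equal(nrow(parts$head$faces) + nrow(parts$foot$faces) +
                 nrow(parts$exterior$faces), nrow(cube$faces))
  ## an elongated ellipsoid: caps split to head/foot, barrel to exterior
  m <- ellipsoid_mesh(c(3, 3, 9), n_theta = 20, n_phi = 16)
  p2 <- split_block_surface(m, c(0, 0, 1), 45)
  expect_gt(nrow(p2$head$faces), 0)
  expect_gt(nrow(p2$foot$faces), 0)
  expect_gt(nrow(p2$exterior$faces), nrow(p2$head$faces))
  expect_gt(min(face_centers(p2$head)[, 3]), 0)    # caps on the correct sides
  expect_lt(max(face_centers(p2$foot)[, 3]), 0)
  expect_setequal(c(p2$head_faces, p2$foot_faces, p2$exterior_faces),
                  seq_len(nrow(m$faces)))
})
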