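## Shared fixtures and independent oracles for the test suite.

## Rodrigues rotation about an arbitrary axis.
rot3 <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

## Random small mesh: n_tri triangles with vertices drawn near the origin.
random_mesh <- function(n_tri, scale = 1, offset = c(0, 0, 0)) {
  nv <- n_tri + 2
  v <- matrix(stats::rnorm(nv * 3, sd = scale), nv, 3)
  v <- sweep(v, 2, offset, "+")
  f <- cbind(seq_len(n_tri), seq_len(n_tri) + 1L, seq_len(n_tri) + 2L)
  triangle_mesh(v, f, check_degenerate = FALSE)
}

## Naive double-sum evaluation of the currents norm / dissimilarity:
## explicit loop over the faces of the first surface, no shared code with
## the package's matrix implementation.
oracle_currents_terms <- function(c1, n1, c2, n2, sigma) {
  acc <- 0
  for (p in seq_len(nrow(c1))) {
    dif <- sweep(c2, 2, c1[p, ])
    k <- 1 / (1 + rowSums(dif^2) / sigma^2)
    acc <- acc + sum((n2 %*% n1[p, ]) * k)
  }
  acc
}

oracle_norm_sq <- function(mesh, sigma) {
  cen <- face_centers(mesh); nor <- face_normals(mesh)
  oracle_currents_terms(cen, nor, cen, nor, sigma)
}

oracle_dissimilarity <- function(m1, m2, sigma) {
  c1 <- face_centers(m1); n1 <- face_normals(m1)
  c2 <- face_centers(m2); n2 <- face_normals(m2)
  oracle_currents_terms(c1, n1, c1, n1, sigma) -
    2 * oracle_currents_terms(c1, n1, c2, n2, sigma) +
    oracle_currents_terms(c2, n2, c2, n2, sigma)
}

## Binary disk section image of radius r (pixels) on an n x n grid.
disk_image <- function(n = 64, cx = n / 2, cy = n / 2 - 2, r = 18) {
  g <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1)))
  image2d(matrix(as.numeric((g[, 1] - cx)^2 + (g[, 2] - cy)^2 < r^2), n, n),
          c(1, 1), c(0, 0))
}

## Small phantom for fast pipeline-level tests: ~9 mm of tissue in z
## (3 blocks), reduced in-plane extent, coarser sectioning.
small_phantom_spec <- function(seed = 1, ...) {
  phantom_spec(volume_size = c(22, 22, 14), tissue_radii = c(8, 7, 4.4),
               necrosis_center_offset = c(1, -0.5, 0),
               necrosis_radii = c(3.5, 3, 2.5),
               n_tubes = 1, n_blobs = 1,
               section_spacing_um = 500, blockface_spacing_um = 250,
               landmarks_per_stage = 4, seed = seed, ...)
}

## Build block surface sets + ex vivo target from a slicing result, the
## same way the pipeline does but starting from simulator masks.
phantom_block_sets <- function(sl, ex, decimate_cell = 1.5) {
  nb <- sl$n_blocks
  bss <- lapply(seq_len(nb), function(b) {
    blk <- sl$blocks[[b]]
    msk <- historeg:::mask_from_class(blk$class_volume, 1:4)
    cp <- c(if (b == 1) NA else blk$z_range[1],
            if (b == nb) NA else blk$z_range[2])
    block_surface_set(label_surface(msk), b, cut_planes = cp,
                      cut_tolerance = 0.5, decimate_cell = decimate_cell)
  })
  list(bss = bss,
       ex_surface = label_surface(ex$tissue_label, decimate_cell = 1.8))
}

row_norms_test <- function(m) sqrt(rowSums(m * m))

section_landmarks_test <- function(sec, n) historeg:::section_landmarks(sec, n, seed = 42)
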