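#' Cauchy kernel
#'
#' Scalar kernel `k(x, y) = 1 / (1 + ||x - y||^2 / sigma^2)`, the radial
#' kernel underlying both the currents metric on surfaces and the
#' reproducing-kernel velocity fields used for surface flows.  Values lie
#' in `(0, 1]`, with `k(x, x) = 1` and `k = 1/2` at separation `sigma`.
#'
#' @param x,y K x d point matrices (or single points), mm.
#' @param sigma kernel scale, mm; must be positive.
#' @return numeric vector of kernel values (row-wise pairing).
#' @export
cauchy_kernel <- function(x, y, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop_historeg("sigma must be a positive scalar", "historeg_parameter_error")
  x <- as_point_matrix(x); y <- as_point_matrix(y)
  d <- rowSums((x - y)^2)
  1 / (1 + d / sigma^2)
}

## Full kernel matrix between rows of a and rows of b.
cauchy_kernel_matrix <- function(a, b, sigma) {
  1 / (1 + cross_dist_sq(a, b) / sigma^2)
}

check_nonempty_mesh <- function(mesh, what = "mesh") {
  if (!inherits(mesh, "triangle_mesh") || nrow(mesh$faces) == 0)
    stop_historeg(sprintf("%s has no faces", what), "historeg_empty_error")
}

#' Currents norm and dissimilarity between surfaces
#'
#' A triangular mesh `S` is represented as a current: the sum of
#' vector-valued Dirac masses `eta(p) delta_c(p)` over its faces, with
#' `c(p)` the face centre and `eta(p)` the area-weighted face normal.  The
#' squared kernel norm is the double sum
#' `sum_p sum_p' <eta(p), eta(p')> k(c(p), c(p'))` with the Cauchy kernel
#' `k`; the dissimilarity between two surfaces is the squared K-norm of the
#' difference of their currents, expanded into the two self terms minus
#' twice the cross term.  The measure needs no point correspondence, is
#' invariant under rigid motion of both surfaces, and is zero only when the
#' two currents coincide.
#'
#' @param mesh,mesh1,mesh2 [triangle_mesh] objects (non-empty).
#' @param sigma Cauchy kernel scale, mm.
#' @return nonnegative scalar.
#' @export
currents_norm_sq <- function(mesh, sigma) {
  check_nonempty_mesh(mesh)
  cen <- face_centers(mesh); nor <- face_normals(mesh)
  sum(cauchy_kernel_matrix(cen, cen, sigma) * tcrossprod(nor))
}

#' @rdname currents_norm_sq
#' @export
currents_dissimilarity <- function(mesh1, mesh2, sigma) {
  check_nonempty_mesh(mesh1, "mesh1"); check_nonempty_mesh(mesh2, "mesh2")
  c1 <- face_centers(mesh1); n1 <- face_normals(mesh1)
  c2 <- face_centers(mesh2); n2 <- face_normals(mesh2)
  currents_terms(c1, n1, c2, n2, sigma)
}

## Three-term expansion given centres/normals directly.
currents_terms <- function(c1, n1, c2, n2, sigma) {
  s11 <- sum(cauchy_kernel_matrix(c1, c1, sigma) * tcrossprod(n1))
  s22 <- sum(cauchy_kernel_matrix(c2, c2, sigma) * tcrossprod(n2))
  s12 <- sum(cauchy_kernel_matrix(c1, c2, sigma) * tcrossprod(n1, n2))
  s11 - 2 * s12 + s22
}

## Gradient of currents_dissimilarity(mesh1, mesh2) w.r.t. mesh1 vertices.
## Chain rule through face centres (dc/dx = I/3 per corner) and
## area-weighted normals (d<G,eta>/dx_a = G x (x_c - x_b)/2, cyclically).
currents_dissimilarity_grad <- function(mesh1, mesh2, sigma,
                                        target_cache = NULL) {
  check_nonempty_mesh(mesh1, "mesh1"); check_nonempty_mesh(mesh2, "mesh2")
  c1 <- face_centers(mesh1); n1 <- face_normals(mesh1)
  if (is.null(target_cache)) {
    c2 <- face_centers(mesh2); n2 <- face_normals(mesh2)
  } else { c2 <- target_cache$centers; n2 <- target_cache$normals }
  s2 <- sigma^2
  k11 <- cauchy_kernel_matrix(c1, c1, sigma)
  k12 <- cauchy_kernel_matrix(c1, c2, sigma)
  ## dD/deta_f = 2 (sum_f' k11 eta_f' - sum_g k12 mu_g)
  g_eta <- 2 * (k11 %*% n1 - k12 %*% n2)
  ## dD/dc_f: grad_x k(x,y) = -(2/s2) (x-y) k^2
  ip11 <- tcrossprod(n1)           # <eta_f, eta_f'>
  ip12 <- tcrossprod(n1, n2)
  w11 <- ip11 * k11^2              # f x f'
  w12 <- ip12 * k12^2              # f x g
  ## sum over partners of w * (c_f - c_partner)
  g_c <- matrix(0, nrow(c1), 3)
  for (c in 1:3) {
    g_c[, c] <- 2 * (-2 / s2) * (rowSums(w11) * c1[, c] - w11 %*% c1[, c]) -
      2 * (-2 / s2) * (rowSums(w12) * c1[, c] - w12 %*% c2[, c])
  }
  ## distribute to vertices
  f <- mesh1$faces; v <- mesh1$vertices
  grad <- matrix(0, nrow(v), 3)
  ## centre part: each corner gets g_c/3
  for (j in 1:3) {
    contrib <- g_c / 3
    grad <- grad + rowsum_into(contrib, f[, j], nrow(v))
  }
  ## normal part: d<G, eta>/dx_a = 0.5 * G x (x_c - x_b)
  xa <- v[f[, 1], , drop = FALSE]; xb <- v[f[, 2], , drop = FALSE]
  xc <- v[f[, 3], , drop = FALSE]
  grad <- grad + rowsum_into(0.5 * cross3(g_eta, xc - xb), f[, 1], nrow(v))
  grad <- grad + rowsum_into(0.5 * cross3(g_eta, xa - xc), f[, 2], nrow(v))
  grad <- grad + rowsum_into(0.5 * cross3(g_eta, xb - xa), f[, 3], nrow(v))
  grad
}

## Scatter-add rows of m into an n-row accumulator at indices idx.
rowsum_into <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  rs <- rowsum(m, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Partition a closed block surface into head, foot and exterior faces
#'
#' Faces whose unit outward normal lies within `angle_threshold` degrees of
#' `+axis` form the head (cut) surface, within the threshold of `-axis` the
#' foot surface, and the remainder the exterior (original tissue boundary).
#' The three parts partition the faces of the input exactly.
#'
#' @param mesh closed, consistently oriented [triangle_mesh].
#' @param axis length-3 sectioning axis (need not be unit length).
#' @param angle_threshold half-angle of the head/foot cones, degrees.
#' @return list with `head`, `foot`, `exterior` (`triangle_mesh`es sharing
#'   the parent vertex array) and the corresponding face index vectors.
#' @export
split_block_surface <- function(mesh, axis = c(0, 0, 1), angle_threshold = 45) {
  check_nonempty_mesh(mesh)
  if (!mesh_is_closed(mesh))
    stop_historeg("split_block_surface requires a closed oriented mesh",
                  "historeg_orientation_error")
  axis <- axis / sqrt(sum(axis^2))
  nor <- face_normals(mesh)
  a <- face_areas(mesh)
  unit <- nor / pmax(a, 1e-300)
  cosang <- as.vector(unit %*% axis)
  cthr <- cos(angle_threshold * pi / 180)
  head_idx <- which(cosang >= cthr)
  foot_idx <- which(cosang <= -cthr)
  ext_idx <- setdiff(seq_len(nrow(mesh$faces)), c(head_idx, foot_idx))
  part <- function(idx) triangle_mesh(mesh$vertices,
                                      mesh$faces[idx, , drop = FALSE],
                                      check_degenerate = FALSE)
  list(head = part(head_idx), foot = part(foot_idx), exterior = part(ext_idx),
       head_faces = head_idx, foot_faces = foot_idx, exterior_faces = ext_idx)
}
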