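#' Triangular surface mesh
#'
#' Vertices in world mm with 1-based triangular face indices.  Derived
#' per-face quantities used throughout surface matching: the face centre
#' `c(p)` (mean of the three corners) and the *area-weighted* face normal
#' `eta(p)` (half cross-product of the edge vectors, magnitude = triangle
#' area).  Area weighting makes the currents norm consistent under mesh
#' refinement, which a unit normal would not be.
#'
#' @param vertices N x 3 matrix, mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param check_degenerate warn about faces with area below `area_epsilon`.
#' @param area_epsilon degenerate-face area threshold, mm^2.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, check_degenerate = TRUE,
                          area_epsilon = 1e-12) {
  vertices <- as_point_matrix(vertices, 3)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3)
    stop_historeg("faces must be an M x 3 index matrix", "historeg_geometry_error")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop_historeg("face indices out of range", "historeg_geometry_error")
  m <- structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
  if (check_degenerate && nrow(faces) > 0) {
    a <- face_areas(m)
    if (any(a < area_epsilon))
      warning(sprintf("%d degenerate face(s) with area < %g mm^2",
                      sum(a < area_epsilon), area_epsilon))
  }
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh, %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @rdname triangle_mesh
#' @param mesh a `triangle_mesh`.
#' @export
face_centers <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @rdname triangle_mesh
#' @export
face_normals <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  0.5 * cross3(e1, e2)
}

#' @rdname triangle_mesh
#' @export
face_areas <- function(mesh) row_norms(face_normals(mesh))

#' @rdname triangle_mesh
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Transform a mesh
#'
#' Applies a transform (chain) to the vertices; faces and connectivity are
#' untouched.
#'
#' @param mesh a [triangle_mesh].
#' @param chain [transform_chain], [affine_transform] or [diffeomorphism].
#' @return transformed `triangle_mesh`.
#' @export
transform_mesh <- function(mesh, chain) {
  triangle_mesh(apply_chain(chain, mesh$vertices), mesh$faces,
                check_degenerate = FALSE)
}

## Merge several meshes into one (vertex indices offset).
merge_meshes <- function(meshes) {
  meshes <- meshes[vapply(meshes, function(m) nrow(m$faces) > 0, logical(1))]
  if (length(meshes) == 0)
    stop_historeg("no non-empty meshes to merge", "historeg_empty_error")
  vs <- lapply(meshes, `[[`, "vertices")
  off <- cumsum(c(0L, vapply(vs, nrow, integer(1))))
  fs <- Map(function(m, o) m$faces + o, meshes, off[seq_along(meshes)])
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs), check_degenerate = FALSE)
}

## Check that every edge is shared by exactly two faces (closed surface).
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' Decimate a mesh by vertex clustering
#'
#' Snaps vertices to a regular grid of cell size `cell` mm, collapses each
#' cluster to its mean position, and drops faces that become degenerate.
#' A coarse but robust decimation used to keep currents computations on
#' dense marching-extracted surfaces tractable; geometry is preserved to
#' within roughly one cell.
#'
#' @param mesh a [triangle_mesh].
#' @param cell clustering cell size, mm.
#' @return decimated `triangle_mesh`.
#' @export
decimate_mesh <- function(mesh, cell) {
  v <- mesh$vertices
  key <- paste(floor(v[, 1] / cell), floor(v[, 2] / cell), floor(v[, 3] / cell))
  grp <- match(key, unique(key))
  nv <- rowsum(v, grp) / tabulate(grp)
  f <- matrix(grp[mesh$faces], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  ## drop duplicate faces irrespective of rotation (vectorized row-sort)
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  mid <- f[, 1] + f[, 2] + f[, 3] - lo - hi
  f <- f[!duplicated(cbind(lo, mid, hi)), , drop = FALSE]
  triangle_mesh(nv, f, check_degenerate = FALSE)
}

#' Ellipsoid test mesh
#'
#' Latitude/longitude triangulation of an ellipsoid, consistently oriented
#' with outward normals.  Used for synthetic-recovery tests and phantoms.
#'
#' @param radii length-3 semi-axes, mm.
#' @param center length-3 centre, mm.
#' @param n_theta,n_phi latitude bands / longitude steps.
#' @return a [triangle_mesh] with `2 * n_phi * (n_theta - 1)` faces.
#' @export
ellipsoid_mesh <- function(radii = c(1, 1, 1), center = c(0, 0, 0),
                           n_theta = 16, n_phi = 18) {
  theta <- seq(0, pi, length.out = n_theta + 1)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  ring_id <- function(i, j) 2L + (i - 2L) * n_phi + (j - 1L) %% n_phi
  verts <- rbind(center + c(0, 0, radii[3]))
  for (i in 2:n_theta) {
    st <- sin(theta[i]); ct <- cos(theta[i])
    verts <- rbind(verts, cbind(center[1] + radii[1] * st * cos(phi),
                                center[2] + radii[2] * st * sin(phi),
                                center[3] + radii[3] * ct))
  }
  south <- nrow(verts) + 1L
  verts <- rbind(verts, center + c(0, 0, -radii[3]))
  faces <- NULL
  for (j in 1:n_phi)  # top cap
    faces <- rbind(faces, c(1L, ring_id(2, j), ring_id(2, j + 1)))
  if (n_theta > 2) for (i in 2:(n_theta - 1)) for (j in 1:n_phi) {
    a <- ring_id(i, j); b <- ring_id(i, j + 1)
    cc <- ring_id(i + 1, j); dd <- ring_id(i + 1, j + 1)
    faces <- rbind(faces, c(a, cc, b), c(b, cc, dd))
  }
  for (j in 1:n_phi)  # bottom cap
    faces <- rbind(faces, c(south, ring_id(n_theta, j + 1), ring_id(n_theta, j)))
  m <- triangle_mesh(verts, faces, check_degenerate = FALSE)
  ## enforce outward orientation
  nor <- face_normals(m); cen <- face_centers(m)
  flip <- rowSums(nor * sweep(cen, 2, center)) < 0
  f <- m$faces
  f[flip, c(2, 3)] <- f[flip, c(3, 2)]
  triangle_mesh(m$vertices, f, check_degenerate = FALSE)
}

#' @rdname triangle_mesh
#' @export
flip_mesh <- function(mesh) {
  triangle_mesh(mesh$vertices, mesh$faces[, c(1, 3, 2), drop = FALSE],
                check_degenerate = FALSE)
}
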