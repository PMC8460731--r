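#' Extract an isosurface mesh from a label volume
#'
#' Marching-tetrahedra isosurfacing: every grid cube is split into six
#' tetrahedra around its main diagonal and each tetrahedron contributes
#' zero, one or two triangles with vertices linearly interpolated along
#' sign-crossing edges.  The volume is zero-padded so surfaces close at the
#' boundary, shared edge vertices are welded, and triangles are oriented
#' with outward normals (from inside, above `iso`, toward outside).  Binary
#' labels are Gaussian-presmoothed (`smooth_sigma` voxels) before
#' extraction, which removes voxel staircase bias from the recovered
#' geometry; set it to 0 for already-smooth fields.
#'
#' @param labels a [label_volume] or [image_volume].
#' @param iso iso-level; default 0.5 for binary labels.
#' @param smooth_sigma Gaussian presmoothing in voxels.
#' @return a closed, outward-oriented [triangle_mesh] in world mm.
#' @export
surface_from_labels <- function(labels, iso = 0.5, smooth_sigma = 1) {
  vals <- labels$values
  if (sum(vals > iso) == 0 && max(vals) <= iso)
    stop_historeg("label volume is empty at this iso-level", "historeg_empty_error")
  f <- gaussian_smooth_array(vals + 0, smooth_sigma)
  ## pad with a value safely below the iso-level so the surface closes even
  ## when the whole grid is inside
  dm <- dim(f)
  pad <- array(iso - max(abs(f - iso)) - 1e-6, dm + 2)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- f
  f <- pad
  nx <- dm[1] + 2; ny <- dm[2] + 2; nz <- dm[3] + 2
  cx <- nx - 1L; cy <- ny - 1L; cz <- nz - 1L     # cubes per axis
  ncube <- cx * cy * cz
  ## 8 cube corners, bit order (x, y, z)
  corner_vals <- matrix(0, ncube, 8)
  corner_gidx <- matrix(0L, ncube, 8)
  base <- as.matrix(expand.grid(i = seq_len(cx), j = seq_len(cy), k = seq_len(cz)))
  for (c in 0:7) {
    dx <- bitwAnd(c, 1L); dy <- bitwShiftR(bitwAnd(c, 2L), 1L)
    dz <- bitwShiftR(bitwAnd(c, 4L), 2L)
    i <- base[, 1] + dx; j <- base[, 2] + dy; k <- base[, 3] + dz
    corner_vals[, c + 1] <- f[cbind(i, j, k)]
    corner_gidx[, c + 1] <- i + (j - 1L) * nx + (k - 1L) * nx * ny
  }
  ## six tetrahedra sharing the 0-7 diagonal
  tets <- rbind(c(0, 1, 3, 7), c(0, 3, 2, 7), c(0, 2, 6, 7),
                c(0, 6, 4, 7), c(0, 4, 5, 7), c(0, 5, 1, 7)) + 1
  tri_e1 <- tri_e2 <- tri_e3 <- NULL   # edge endpoint gidx pairs per triangle
  orient_ref <- NULL                   # inside->outside reference vectors
  node_pos <- function(g) {            # padded 1-based linear index -> 0-based ijk
    g0 <- g - 1L
    cbind(g0 %% nx, (g0 %/% nx) %% ny, g0 %/% (nx * ny))
  }
  edge_cross <- function(ga, gb, fa, fb) {
    ## interpolated crossing in padded index coordinates
    t <- (iso - fa) / (fb - fa)
    pa <- node_pos(ga); pb <- node_pos(gb)
    pa + t * (pb - pa)
  }
  out_tris <- list(); out_ref <- list()
  for (tt in 1:6) {
    tv <- corner_vals[, tets[tt, ], drop = FALSE]
    tg <- corner_gidx[, tets[tt, ], drop = FALSE]
    inside <- tv > iso
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    for (cs in 1:14) {
      rows <- which(code == cs)
      if (!length(rows)) next
      ins <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) != 0)
      outs <- setdiff(1:4, ins)
      V <- tv[rows, , drop = FALSE]; G <- tg[rows, , drop = FALSE]
      ## reference direction: outside centroid - inside centroid
      pctr <- function(cols) {
        acc <- 0
        for (cl in cols) acc <- acc + node_pos(G[, cl])
        acc / length(cols)
      }
      ref <- pctr(outs) - pctr(ins)
      if (length(ins) == 1 || length(ins) == 3) {
        a <- if (length(ins) == 1) ins else outs
        others <- setdiff(1:4, a)
        p1 <- edge_cross(G[, a], G[, others[1]], V[, a], V[, others[1]])
        p2 <- edge_cross(G[, a], G[, others[2]], V[, a], V[, others[2]])
        p3 <- edge_cross(G[, a], G[, others[3]], V[, a], V[, others[3]])
        out_tris[[length(out_tris) + 1]] <- list(p1, p2, p3)
        out_ref[[length(out_ref) + 1]] <- ref
      } else {
        i1 <- ins[1]; i2 <- ins[2]; o1 <- outs[1]; o2 <- outs[2]
        e1 <- edge_cross(G[, i1], G[, o1], V[, i1], V[, o1])
        e2 <- edge_cross(G[, i1], G[, o2], V[, i1], V[, o2])
        e3 <- edge_cross(G[, i2], G[, o2], V[, i2], V[, o2])
        e4 <- edge_cross(G[, i2], G[, o1], V[, i2], V[, o1])
        out_tris[[length(out_tris) + 1]] <- list(e1, e2, e3)
        out_ref[[length(out_ref) + 1]] <- ref
        out_tris[[length(out_tris) + 1]] <- list(e1, e3, e4)
        out_ref[[length(out_ref) + 1]] <- ref
      }
    }
  }
  if (!length(out_tris))
    stop_historeg("no surface found at this iso-level", "historeg_empty_error")
  P1 <- do.call(rbind, lapply(out_tris, `[[`, 1))
  P2 <- do.call(rbind, lapply(out_tris, `[[`, 2))
  P3 <- do.call(rbind, lapply(out_tris, `[[`, 3))
  REF <- do.call(rbind, out_ref)
  ## weld identical vertices (positions are exact functions of edge + t)
  allp <- rbind(P1, P2, P3)
  key <- paste(round(allp[, 1], 7), round(allp[, 2], 7), round(allp[, 3], 7))
  uid <- match(key, unique(key))
  nt <- nrow(P1)
  faces <- cbind(uid[1:nt], uid[nt + 1:nt], uid[2 * nt + 1:nt])
  verts_idx <- allp[!duplicated(key), , drop = FALSE]
  ## drop degenerate faces (two corners welded together)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]; REF <- REF[keep, , drop = FALSE]
  ## orient outward: normal . (outside - inside) > 0
  e1 <- verts_idx[faces[, 2], ] - verts_idx[faces[, 1], ]
  e2 <- verts_idx[faces[, 3], ] - verts_idx[faces[, 1], ]
  nrm <- cross3(e1, e2)
  flip <- rowSums(nrm * REF) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  ## padded index -> world: padded node (0,0,0) sits one voxel before origin
  idx <- sweep(verts_idx, 2, c(1, 1, 1))          # back to unpadded 0-based index
  verts <- voxel_to_world(labels, idx)
  triangle_mesh(verts, faces, check_degenerate = FALSE)
}

#' Extract a registration-ready surface from a label volume
#'
#' Resamples the label onto an isotropic grid of `target_spacing` mm
#' (nearest neighbour) before isosurfacing, so thin structures — a ~3 mm
#' tissue block is only a few voxels thick at scan resolution — are not
#' eroded by the pre-smoothing, then optionally decimates the result for
#' currents registration.
#'
#' @param labels a [label_volume].
#' @param target_spacing isotropic extraction grid spacing, mm.
#' @param iso iso-level.
#' @param smooth_sigma Gaussian presmoothing in (resampled) voxels.
#' @param decimate_cell if non-`NULL`, vertex-clustering cell size, mm.
#' @return a [triangle_mesh].
#' @export
label_surface <- function(labels, target_spacing = 0.5, iso = 0.5,
                          smooth_sigma = 1, decimate_cell = NULL) {
  sp <- rep(target_spacing, 3)
  if (max(abs(labels$spacing - sp)) > 1e-12) {
    dmw <- (dim(labels$values) - 1) * labels$spacing
    nd <- pmax(round(dmw / sp) + 1, 2)
    grid <- image_volume(array(0, nd), sp, labels$origin, labels$orientation)
    vals <- sample_volume(labels, volume_grid_points(grid),
                          interpolation = "nearest")
    labels <- label_volume(array(vals, nd), sp, labels$origin,
                           labels$orientation)
  }
  m <- surface_from_labels(labels, iso, smooth_sigma)
  if (!is.null(decimate_cell)) m <- decimate_mesh(m, decimate_cell)
  m
}
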