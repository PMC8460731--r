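#' 3D image volume with world geometry
#'
#' A scalar 3D grid together with the geometry that places it in a world
#' coordinate frame measured in millimetres: voxel spacing, the world
#' position of the *centre* of the first voxel (origin), and a 3x3
#' direction-cosine matrix.  Index `(0,0,0)` (zero-based, continuous) maps
#' exactly onto `origin`; all registration in this package operates on world
#' coordinates, never on raw voxel indices, so images of different
#' resolutions compose freely.
#'
#' @param values numeric 3D array, indexed `[ix, iy, iz]`.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @param orientation 3x3 direction-cosine matrix; must be orthonormal
#'   (`|det| = 1` within 1e-9).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = diag(3)) {
  values <- as.array(values)
  if (length(dim(values)) != 3)
    stop_historeg("image_volume requires a 3D array", "historeg_geometry_error")
  spacing <- as.double(spacing); origin <- as.double(origin)
  orientation <- as.matrix(orientation)
  if (any(spacing <= 0)) stop_historeg("spacing must be strictly positive", "historeg_geometry_error")
  if (!all(dim(orientation) == c(3, 3)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-9 ||
      abs(abs(det(orientation)) - 1) > 1e-9)
    stop_historeg("orientation must be an orthonormal 3x3 matrix", "historeg_geometry_error")
  structure(list(values = values, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s, spacing %s mm, origin %s mm>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' 2D section image
#'
#' A single histology or blockface section: a scalar 2D grid with in-plane
#' spacing/origin in mm and its depth along the sectioning axis.
#'
#' @param values numeric matrix, indexed `[ix, iy]`.
#' @param spacing length-2 in-plane mm per pixel.
#' @param origin length-2 world (in-plane) position of the first pixel centre, mm.
#' @param section_depth position of the section along the sectioning axis, mm.
#' @return An object of class `image2d`.
#' @export
image2d <- function(values, spacing = c(1, 1), origin = c(0, 0), section_depth = 0) {
  values <- as.matrix(values)
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (any(spacing <= 0)) stop_historeg("spacing must be strictly positive", "historeg_geometry_error")
  if (!is.finite(section_depth)) stop_historeg("section_depth must be finite", "historeg_geometry_error")
  structure(list(values = values, spacing = spacing, origin = origin,
                 section_depth = as.double(section_depth)),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %s, spacing %s mm, depth %.4g mm>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$section_depth))
  invisible(x)
}

#' Binary label volume
#'
#' An [image_volume] whose voxels are restricted to `{0, 1}`.
#'
#' @param values 3D array of 0/1 (logicals are coerced).
#' @inheritParams image_volume
#' @return An object of class `c("label_volume", "image_volume")`.
#' @export
label_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = diag(3)) {
  values <- as.array(values) + 0
  if (!all(values %in% c(0, 1)))
    stop_historeg("label_volume values must be 0 or 1", "historeg_geometry_error")
  v <- image_volume(values, spacing, origin, orientation)
  class(v) <- c("label_volume", class(v))
  v
}

#' Convert between world coordinates and continuous voxel indices
#'
#' Voxel indices are zero-based and continuous; index `(0,0,0)` is the centre
#' of the first voxel and maps to `origin`.  Points outside the grid return
#' out-of-range indices rather than raising an error.
#'
#' @param vol an [image_volume].
#' @param x K x 3 matrix of world points (mm); a bare length-3 vector is
#'   treated as one point.
#' @return K x 3 matrix of continuous zero-based voxel indices.
#' @export
world_to_voxel <- function(vol, x) {
  x <- as_point_matrix(x, 3)
  rel <- sweep(x, 2, vol$origin) %*% vol$orientation  # = t(R) %*% (x - o), rows
  sweep(rel, 2, vol$spacing, "/")
}

#' @rdname world_to_voxel
#' @param idx K x 3 matrix of continuous zero-based voxel indices.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- as_point_matrix(idx, 3)
  sweep(sweep(idx, 2, vol$spacing, "*") %*% t(vol$orientation), 2, vol$origin, "+")
}

## 2D pixel <-> in-plane world (axis-aligned sections).
pixel_to_world2 <- function(img, idx) {
  idx <- as_point_matrix(idx, 2)
  sweep(sweep(idx, 2, img$spacing, "*"), 2, img$origin, "+")
}
world_to_pixel2 <- function(img, x) {
  x <- as_point_matrix(x, 2)
  sweep(sweep(x, 2, img$origin), 2, img$spacing, "/")
}

## --- interpolation -------------------------------------------------------

## Linear interpolation of a 2D matrix at continuous zero-based indices.
interp_grid2 <- function(values, idx, fill = 0) {
  nx <- nrow(values); ny <- ncol(values)
  x <- idx[, 1]; y <- idx[, 2]
  out <- rep(fill, length(x))
  ok <- is.finite(x) & is.finite(y) & x > -1 & x < nx & y > -1 & y < ny
  if (!any(ok)) return(out)
  x <- pmin(pmax(x[ok], 0), nx - 1); y <- pmin(pmax(y[ok], 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  if (nx == 1) x0 <- x * 0
  if (ny == 1) y0 <- y * 0
  fx <- x - x0; fy <- y - y0
  i0 <- x0 + 1; j0 <- y0 + 1
  v00 <- values[cbind(i0, j0)]
  v10 <- values[cbind(pmin(i0 + 1, nx), j0)]
  v01 <- values[cbind(i0, pmin(j0 + 1, ny))]
  v11 <- values[cbind(pmin(i0 + 1, nx), pmin(j0 + 1, ny))]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  out
}

## Nearest-neighbour variant (2D).
interp_grid2_nn <- function(values, idx, fill = 0) {
  nx <- nrow(values); ny <- ncol(values)
  i <- round(idx[, 1]) + 1; j <- round(idx[, 2]) + 1
  out <- rep(fill, nrow(idx))
  ok <- is.finite(i) & is.finite(j) & i >= 1 & i <= nx & j >= 1 & j <= ny
  out[ok] <- values[cbind(i[ok], j[ok])]
  out
}

## Trilinear interpolation of a 3D array at continuous zero-based indices.
interp_grid3 <- function(values, idx, fill = 0) {
  dm <- dim(values); nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  out <- rep(fill, length(x))
  ok <- is.finite(x) & is.finite(y) & is.finite(z) &
    x > -1 & x < nx & y > -1 & y < ny & z > -1 & z < nz
  if (!any(ok)) return(out)
  x <- pmin(pmax(x[ok], 0), nx - 1)
  y <- pmin(pmax(y[ok], 0), ny - 1)
  z <- pmin(pmax(z[ok], 0), nz - 1)
  x0 <- pmin(floor(x), max(nx - 2, 0)); fx <- x - x0
  y0 <- pmin(floor(y), max(ny - 2, 0)); fy <- y - y0
  z0 <- pmin(floor(z), max(nz - 2, 0)); fz <- z - z0
  i0 <- x0 + 1; j0 <- y0 + 1; k0 <- z0 + 1
  i1 <- pmin(i0 + 1, nx); j1 <- pmin(j0 + 1, ny); k1 <- pmin(k0 + 1, nz)
  acc <- values[cbind(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    values[cbind(i1, j0, k0)] * fx * (1 - fy) * (1 - fz) +
    values[cbind(i0, j1, k0)] * (1 - fx) * fy * (1 - fz) +
    values[cbind(i1, j1, k0)] * fx * fy * (1 - fz) +
    values[cbind(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
    values[cbind(i1, j0, k1)] * fx * (1 - fy) * fz +
    values[cbind(i0, j1, k1)] * (1 - fx) * fy * fz +
    values[cbind(i1, j1, k1)] * fx * fy * fz
  out[ok] <- acc
  out
}

interp_grid3_nn <- function(values, idx, fill = 0) {
  dm <- dim(values)
  i <- round(idx[, 1]) + 1; j <- round(idx[, 2]) + 1; k <- round(idx[, 3]) + 1
  out <- rep(fill, nrow(idx))
  ok <- is.finite(i) & is.finite(j) & is.finite(k) &
    i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & k >= 1 & k <= dm[3]
  out[ok] <- values[cbind(i[ok], j[ok], k[ok])]
  out
}

#' Sample an image at world points
#'
#' Linear (default) or nearest-neighbour interpolation of an [image_volume]
#' at arbitrary world-mm points; out-of-grid points receive `fill`.
#'
#' @param vol an [image_volume].
#' @param x K x 3 world points, mm.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill value assigned outside the grid.
#' @return numeric vector of K sampled values.
#' @export
sample_volume <- function(vol, x, interpolation = c("linear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  idx <- world_to_voxel(vol, x)
  if (interpolation == "linear") interp_grid3(vol$values, idx, fill)
  else interp_grid3_nn(vol$values, idx, fill)
}

#' @rdname sample_volume
#' @param img an [image2d].
#' @param xy K x 2 in-plane world points, mm.
#' @export
sample_image2d <- function(img, xy, interpolation = c("linear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  idx <- world_to_pixel2(img, xy)
  if (interpolation == "linear") interp_grid2(img$values, idx, fill)
  else interp_grid2_nn(img$values, idx, fill)
}

#' World coordinates of all voxel centres
#'
#' Returns the K x 3 matrix of world positions (mm) of every voxel centre,
#' x fastest-varying — the evaluation grid used when mapping labels or
#' sampling fields over a volume.
#'
#' @param vol an [image_volume].
#' @return K x 3 matrix, mm.
#' @export
volume_grid_points <- function(vol) {
  dm <- dim(vol$values)
  idx <- as.matrix(expand.grid(ix = seq_len(dm[1]) - 1,
                               iy = seq_len(dm[2]) - 1,
                               iz = seq_len(dm[3]) - 1))
  voxel_to_world(vol, idx)
}

image2d_grid_points <- function(img) {
  dm <- dim(img$values)
  idx <- as.matrix(expand.grid(ix = seq_len(dm[1]) - 1, iy = seq_len(dm[2]) - 1))
  pixel_to_world2(img, idx)
}

## Physical pixel/voxel measure.
voxel_volume <- function(vol) prod(vol$spacing)
pixel_area <- function(img) prod(img$spacing)
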