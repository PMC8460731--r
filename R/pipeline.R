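#' Register ex vivo feature surfaces to in vivo feature surfaces
#'
#' Corresponding anatomical feature surfaces (vessels, tumour boundaries,
#' treatment features) segmented from ex vivo and in vivo MR are merged —
#' list order defines correspondence — and registered with one affine
#' transform followed by one diffeomorphic currents flow.  The returned
#' chain maps ex vivo coordinates to in vivo coordinates and corrects the
#' deformation introduced by tissue excision and fixation.
#'
#' @param features_ex,features_in lists of [triangle_mesh] in matching
#'   order.
#' @param params [currents_params]; kernel scale of the order of the
#'   feature size (default 2 mm).
#' @return list with `chain` ([transform_chain], ex vivo -> in vivo),
#'   `affine`, `diffeo`, `dissimilarity_before`, `dissimilarity_after`.
#' @export
register_exvivo_to_invivo <- function(features_ex, features_in,
                                      params = currents_params(sigma = 2)) {
  if (length(features_ex) != length(features_in))
    stop_historeg("feature surface lists differ in length",
                  "historeg_correspondence_error")
  if (length(features_ex) == 0)
    stop_historeg("no feature surfaces given", "historeg_empty_error")
  moving <- merge_meshes(features_ex)
  target <- merge_meshes(features_in)
  e0 <- currents_dissimilarity(moving, target, params$sigma)
  areg <- affine_register_surfaces(moving, target, params)
  moved <- transform_mesh(moving, areg$transform)
  dreg <- diffeo_register_surfaces(moved, target, params)
  list(chain = transform_chain(areg$transform, dreg$transform),
       affine = areg$transform, diffeo = dreg$transform,
       dissimilarity_before = e0, dissimilarity_after = dreg$dissimilarity)
}

#' Compose the full histology-to-in-vivo chain
#'
#' Assembles the spatial mapping for one histology section: the 2D
#' histology-to-blockface chain acts in-plane at the section's depth, then
#' the block's reconstruction chain, the global exterior-to-ex-vivo chain,
#' and the ex-vivo-to-in-vivo chain.  A histology-plane point `(u, v)` is
#' applied as `(u, v, section_depth)`.
#'
#' @param r1_chain 2D [transform_chain] (histology -> blockface stack).
#' @param block_chain block -> reconstructed frame chain.
#' @param exterior_chain reconstructed -> ex vivo chain.
#' @param r3_chain ex vivo -> in vivo chain.
#' @param section_depth section depth along the slicing axis, mm.
#' @return a [transform_chain]; apply to K x 3 `(u, v, depth)` points.
#' @export
build_full_chain <- function(r1_chain, block_chain, exterior_chain, r3_chain,
                             section_depth) {
  for (nm in c("r1_chain", "block_chain", "exterior_chain", "r3_chain")) {
    if (is.null(get(nm)))
      stop_historeg(paste0("missing pipeline stage: ", nm),
                    "historeg_assembly_error")
  }
  chain <- transform_chain(r1_chain, block_chain, exterior_chain, r3_chain)
  attr(chain, "section_depth") <- section_depth
  chain
}

#' Grid-sample all kernel flows in a transform chain
#'
#' Replaces kernel-parameterised diffeomorphisms by grid-sampled
#' equivalents ([discretize_diffeomorphism()]), which are far cheaper to
#' evaluate on dense point sets; affine elements and grid flows pass
#' through unchanged.
#'
#' @param chain a [transform_chain] (or single transform).
#' @param spacing sampling grid spacing, mm.
#' @return a [transform_chain].
#' @export
discretize_chain <- function(chain, spacing = 1) {
  if (inherits(chain, c("affine_transform", "diffeomorphism")))
    chain <- transform_chain(chain)
  elements <- lapply(chain$elements, function(el) {
    tr <- el$transform
    if (inherits(tr, "diffeomorphism") &&
        any(vapply(tr$steps, function(s) s$type == "kernel", logical(1))))
      chain_element(discretize_diffeomorphism(tr, spacing), el$direction)
    else el
  })
  do.call(transform_chain, elements)
}

## 2D signed distance to a binary mask boundary (negative inside),
## computed by brute-force distance to boundary pixels in mm.
signed_distance_2d <- function(img) {
  m <- img$values > 0.5
  dm <- dim(m)
  ## empty sections are "far outside" by a large finite distance (an
  ## infinite one would produce NaN when interpolated with weight zero)
  if (!any(m)) return(function(xy) rep(1e6, nrow(xy)))
  shift2 <- function(a, dx, dy) {
    out <- array(FALSE, dim(a))
    xs <- seq_len(dm[1]); ys <- seq_len(dm[2])
    xs2 <- xs + dx; ys2 <- ys + dy
    ok1 <- xs2 >= 1 & xs2 <= dm[1]; ok2 <- ys2 >= 1 & ys2 <= dm[2]
    out[xs[ok1], ys[ok2]] <- a[xs2[ok1], ys2[ok2]]
    out
  }
  interior <- m & shift2(m, 1, 0) & shift2(m, -1, 0) &
    shift2(m, 0, 1) & shift2(m, 0, -1)
  bnd <- which(m & !interior, arr.ind = TRUE) - 1
  bpts <- pixel_to_world2(img, bnd)
  h2 <- mean(img$spacing) / 2   # label edge lies half a pixel beyond the
  function(xy) {                # boundary-pixel centres
    d <- sqrt(pmax(apply(cross_dist_sq(as_point_matrix(xy, 2), bpts), 1, min), 0))
    inside <- sample_image2d(img, xy, interpolation = "nearest") > 0.5
    ifelse(inside, -(d + h2), d - h2)
  }
}

#' Build a volumetric histology label in the in vivo frame
#'
#' Maps every histology section's label through its chain into the target
#' grid and fills the space between sections by interpolating the
#' sections' signed-distance fields along the sectioning direction,
#' thresholding at zero.  Sections may either carry a complete `chain`
#' (histology plane to target frame), or — far faster when many sections
#' share a block — a 2D in-plane `chain2d` plus a `group` index into
#' `group_chains`, the shared 3D chain of that block; the expensive dense
#' inverse of each shared chain is then computed once per block.
#'
#' @param sections list of `list(label = image2d, depth = mm, chain = ...)`
#'   or `list(label, depth, chain2d, group)`.
#' @param target_grid [image_volume] defining the output grid (the in vivo
#'   frame).
#' @param group_chains list of shared 3D chains, indexed by `group`.
#' @param chain_spacing grid spacing (mm) used to discretize kernel flows
#'   before the dense inverse mapping.
#' @param max_gap sections further apart than this along the sectioning
#'   axis are not interpolated across, mm.
#' @param roi optional logical vector over the target grid voxels: only
#'   these voxels are computed (the rest stay 0).
#' @return a [label_volume] on `target_grid`.
#' @export
build_histology_volume <- function(sections, target_grid, group_chains = NULL,
                                   chain_spacing = 1, max_gap = 0.4,
                                   roi = NULL) {
  if (length(sections) < 2)
    stop_historeg("need at least two sections", "historeg_empty_error")
  depths <- vapply(sections, `[[`, numeric(1), "depth")
  ord <- order(depths)
  sections <- sections[ord]; depths <- depths[ord]
  vox_full <- volume_grid_points(target_grid)
  nvox_full <- nrow(vox_full)
  if (is.null(roi)) roi <- rep(TRUE, nvox_full)
  vox <- vox_full[roi, , drop = FALSE]
  nvox <- nrow(vox)
  ns <- length(sections)
  sdf_val <- matrix(NA_real_, nvox, ns)   # per-section SDF at the pre-image
  w_z <- matrix(NA_real_, nvox, ns)       # pre-image depth coordinate
  grouped <- !is.null(group_chains) && !is.null(sections[[1]]$group)
  pre3_cache <- list()
  if (grouped) {
    for (gidx in sort(unique(vapply(sections, `[[`, numeric(1), "group")))) {
      inv3 <- invert_chain(discretize_chain(group_chains[[gidx]], chain_spacing))
      pre3_cache[[as.character(gidx)]] <- apply_chain(inv3, vox)
    }
  }
  for (s in seq_len(ns)) {
    sec <- sections[[s]]
    if (grouped) {
      pre3 <- pre3_cache[[as.character(sec$group)]]
      near <- abs(pre3[, 3] - sec$depth) <= max_gap
      if (!any(near)) next
      uv <- apply_chain(invert_chain(sec$chain2d), pre3[near, 1:2, drop = FALSE])
      wz <- pre3[near, 3]
    } else {
      inv <- invert_chain(discretize_chain(sec$chain, chain_spacing))
      pre <- apply_chain(inv, vox)
      near <- abs(pre[, 3] - sec$depth) <= max_gap
      if (!any(near)) next
      uv <- pre[near, 1:2, drop = FALSE]
      wz <- pre[near, 3]
    }
    sdf <- signed_distance_2d(sec$label)
    sdf_val[near, s] <- sdf(uv)
    w_z[near, s] <- wz
  }
  out <- numeric(nvox)
  for (s in seq_len(ns - 1)) {
    d0 <- depths[s]; d1 <- depths[s + 1]
    if (d1 - d0 > max_gap) next
    ok <- !is.na(sdf_val[, s]) & !is.na(sdf_val[, s + 1]) &
      !is.na(w_z[, s]) & w_z[, s] >= d0 & w_z[, s] < d1
    if (!any(ok)) next
    t <- (w_z[ok, s] - d0) / (d1 - d0)
    v <- (1 - t) * sdf_val[ok, s] + t * sdf_val[ok, s + 1]
    out[ok] <- pmax(out[ok], as.numeric(v < 0))
  }
  ## margin beyond the terminal sections of each run: the material between
  ## the last retained section and the cut plane belongs to that section
  gap_after <- c(diff(depths), Inf)
  gap_before <- c(Inf, diff(depths))
  for (s in seq_len(ns)) {
    sides <- c(if (gap_before[s] > max_gap) -1, if (gap_after[s] > max_gap) 1)
    for (dz in sides) {
      ok <- !is.na(sdf_val[, s]) & !is.na(w_z[, s]) &
        (w_z[, s] - depths[s]) * dz >= 0 &
        abs(w_z[, s] - depths[s]) <= max_gap
      out[ok] <- pmax(out[ok], as.numeric(sdf_val[ok, s] < 0))
    }
  }
  full <- numeric(nvox_full)
  full[roi] <- out
  label_volume(array(full, dim(target_grid$values)), target_grid$spacing,
               target_grid$origin, target_grid$orientation)
}

#' Resample an MR volume onto a histology section plane
#'
#' Samples the MR volume at the chain-mapped positions of the histology
#' pixel grid — the inverse-direction visualization that demonstrates the
#' estimated transformations are invertible.
#'
#' @param mr [image_volume].
#' @param full_chain chain from [build_full_chain()] (histology -> MR).
#' @param section [image2d] defining the histology pixel grid and depth.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return an [image2d] of MR intensities on the histology grid.
#' @export
resample_mr_onto_histology <- function(mr, full_chain, section,
                                       interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  xy <- image2d_grid_points(section)
  pts3 <- cbind(xy, section$section_depth)
  mapped <- apply_chain(full_chain, pts3)
  vals <- sample_volume(mr, mapped, interpolation = interpolation)
  image2d(matrix(vals, nrow(section$values), ncol(section$values)),
          section$spacing, section$origin, section$section_depth)
}
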