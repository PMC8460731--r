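#' Lighting-difference blockface image
#'
#' Paraffin is slightly transparent, so tissue behind the exposed face
#' shows through blockface photographs.  Subtracting the image lit
#' perpendicular to the camera (show-through only) from the image lit
#' parallel to the camera (surface + show-through) leaves only the tissue
#' exposed at the surface; negative pixels are clipped to zero.
#'
#' @param img_parallel,img_perpendicular [image2d] images on the same grid.
#' @return an [image2d] of the exposed-surface signal.
#' @export
lighting_difference <- function(img_parallel, img_perpendicular) {
  if (!all(dim(img_parallel$values) == dim(img_perpendicular$values)) ||
      max(abs(img_parallel$spacing - img_perpendicular$spacing)) > 1e-9 ||
      max(abs(img_parallel$origin - img_perpendicular$origin)) > 1e-9)
    stop_historeg("lighting images are not on the same grid", "historeg_geometry_error")
  image2d(pmax(img_parallel$values - img_perpendicular$values, 0),
          img_parallel$spacing, img_parallel$origin, img_parallel$section_depth)
}

#' Align a blockface image series into a 3D stack
#'
#' Sequential 2D affine registration of each blockface image to its
#' (already aligned) predecessor corrects small camera shifts; the first
#' image anchors the stack.  Aligned images are resampled onto the first
#' image's grid and stacked into a 3D volume whose slice spacing is the
#' blockface imaging increment.
#'
#' @param images list of [image2d] with strictly increasing
#'   `section_depth`.
#' @param params [image_reg_params] for the pairwise registrations.
#' @return list of class `blockface_stack` with `images` (aligned),
#'   `affines` (accumulated per image, image i -> stack frame), `volume`
#'   ([image_volume]), `depths`.
#' @export
align_blockface_stack <- function(images, params = image_reg_params(
                                    pyramid_levels = 1, max_iters = 25,
                                    convergence_tol = 1e-5),
                                  content_threshold = NULL) {
  if (length(images) < 1)
    stop_historeg("no blockface images to stack", "historeg_empty_error")
  depths <- vapply(images, `[[`, numeric(1), "section_depth")
  if (any(diff(depths) <= 0))
    stop_historeg("section depths must be strictly increasing", "historeg_geometry_error")
  ref <- images[[1]]
  fov <- min(dim(ref$values) * ref$spacing)
  has_content <- function(img) is.null(content_threshold) ||
    mean(img$values > content_threshold) > 0.005
  ## the stack frame anchors to the first image carrying tissue: blank
  ## leading frames cannot be registered, so alignment effectively starts
  ## at the first content image
  content <- vapply(images, has_content, logical(1))
  anchor <- if (any(content)) which(content)[1] else 1L
  affines <- vector("list", length(images))
  affines[[1]] <- affine_transform(diag(2))
  aligned <- vector("list", length(images))
  aligned[[1]] <- ref
  if (length(images) > 1) for (i in 2:length(images)) {
    ## the fixed image already lives in the stack frame, so the solved
    ## transform is the accumulated stack-frame -> image-i map; pairs
    ## without tissue content (blank paraffin faces) keep the previous
    ## alignment, and a solution that moves the frame implausibly far
    ## (noise-driven divergence) is rejected in favour of it
    prev <- affines[[i - 1]]
    if (has_content(images[[i]]) && has_content(aligned[[i - 1]])) {
      ## camera shifts are translations; a full affine would absorb the
      ## anatomical change between consecutive faces into scale and drift
      reg <- tryCatch(
        affine_register_images(images[[i]], aligned[[i - 1]], params,
                               model = "translation"),
        historeg_flat_image_error = function(e) NULL)
      ok <- !is.null(reg) &&
        sqrt(sum(reg$transform$translation^2)) < fov / 4
      affines[[i]] <- if (ok) reg$transform else prev
    } else affines[[i]] <- prev
    aligned[[i]] <- resample_image(images[[i]], affines[[i]], ref)
    aligned[[i]]$section_depth <- depths[i]
  }
  dz <- if (length(depths) > 1) stats::median(diff(depths)) else 1
  vol <- array(0, c(dim(ref$values), length(images)))
  for (i in seq_along(images)) vol[, , i] <- aligned[[i]]$values
  volume <- image_volume(vol, c(ref$spacing, dz), c(ref$origin, depths[1]))
  structure(list(images = aligned, affines = affines, volume = volume,
                 depths = depths, anchor = anchor),
            class = "blockface_stack")
}

#' Match a histology section to its nearest blockface image
#'
#' Returns the index of the blockface image with the smallest absolute
#' depth difference, ties broken toward the shallower (earlier) image.
#'
#' @param section_depth depth of the histology section, mm.
#' @param stack a `blockface_stack` (or anything with `$depths`).
#' @return integer index into the stack.
#' @export
match_section_to_blockface <- function(section_depth, stack) {
  depths <- stack$depths
  inc <- if (length(depths) > 1) stats::median(diff(depths)) else Inf
  if (section_depth < min(depths) - inc || section_depth > max(depths) + inc)
    stop_historeg("section depth outside the blockface stack range",
                  "historeg_range_error")
  d <- abs(depths - section_depth)
  which(d == min(d))[1]  # first occurrence = shallower on ties
}

#' Register a histology section to its blockface image
#'
#' Affine then multi-scale diffeomorphic intensity registration of the two
#' binary segmentations, minimizing the sum-of-squares energy.  The
#' returned chain maps histology coordinates to blockface coordinates.
#'
#' @param hist_seg,bf_seg [image2d] segmentations (overlapping content).
#' @param params [image_reg_params].
#' @return list with `chain` ([transform_chain], histology -> blockface),
#'   `affine`, `diffeo`, `energy`, `dice_before`, `dice_after`.
#' @export
register_histology_to_blockface <- function(hist_seg, bf_seg,
                                            params = image_reg_params()) {
  if (sum(hist_seg$values) == 0 || sum(bf_seg$values) == 0)
    stop_historeg("empty segmentation image", "historeg_empty_error")
  dice2d <- function(a, b) {
    aa <- a > 0.5; bb <- b > 0.5
    2 * sum(aa & bb) / (sum(aa) + sum(bb))
  }
  areg <- affine_register_images(hist_seg, bf_seg, params)
  warped_aff <- resample_image(hist_seg, areg$transform, bf_seg)
  dreg <- diffeo_register_images(warped_aff, bf_seg, params)
  ## rare large-step flows can fail the invertibility check on thin
  ## structures; retry more conservatively, and if no valid flow is found
  ## return the last valid map — the affine stage alone (identity flow)
  tries <- 0
  while (dreg$status == "failed" && tries < 3) {
    tries <- tries + 1
    params$step_size <- params$step_size / 2
    dreg <- suppressWarnings(diffeo_register_images(warped_aff, bf_seg, params))
  }
  if (dreg$status == "failed") {
    dom <- dreg$transform$domain_bounds
    dreg$transform <- diffeomorphism(list(), dom, dim = 2, validate = FALSE)
    dreg$status <- "affine_fallback"
    dreg$warped <- warped_aff
  }
  ## blockface -> histology resampling map is x -> A(phi^-1(x)); the
  ## histology -> blockface chain is its inverse, u -> phi(A^-1(u))
  chain <- transform_chain(chain_element(areg$transform, "inverse"),
                           chain_element(dreg$transform, "forward"))
  list(chain = chain, affine = areg$transform, diffeo = dreg$transform,
       energy = c(areg$energy, dreg$energy),
       dice_before = dice2d(hist_seg$values, bf_seg$values),
       dice_after = dice2d(dreg$warped$values, bf_seg$values))
}

#' Partitioned block surface with its reconstruction transforms
#'
#' Splits a closed block surface into head / foot / exterior parts along
#' the sectioning axis and prepares decimated copies of each part for
#' currents registration (`decimate_cell` mm vertex clustering; the full
#' surface is carried un-decimated).
#'
#' In addition to the surface-normal criterion, optional cut-plane
#' positions restrict the head/foot faces to lie near the physical cut:
#' the outer caps of the two end blocks face along the sectioning axis too
#' but belong to the original tissue boundary, i.e. the exterior.  Passing
#' `cut_planes = c(NA, z)` (no foot cut) or `c(z, NA)` (no head cut)
#' encodes that side knowledge, standing in for the manual part of the
#' semi-automatic face separation.
#'
#' @param surface closed oriented [triangle_mesh] in block coordinates.
#' @param index block number along the head-foot axis (1 = foot end).
#' @param axis sectioning axis (default +z).
#' @param angle_threshold head/foot cone half-angle, degrees.
#' @param cut_planes length-2 `c(z_foot, z_head)` positions of the cut
#'   planes along the axis, mm (`NA` = that side is not a cut); `NULL`
#'   disables the locality restriction.
#' @param cut_tolerance max distance of a cut face centre from its cut
#'   plane, mm.
#' @param decimate_cell registration decimation cell, mm.
#' @return list of class `block_surface_set`.
#' @export
block_surface_set <- function(surface, index, axis = c(0, 0, 1),
                              angle_threshold = 45, cut_planes = NULL,
                              cut_tolerance = 1, decimate_cell = 1.2) {
  parts <- split_block_surface(surface, axis, angle_threshold)
  ## the physical cut face is one large connected patch; staircase treads
  ## of the quantized side wall also face along the axis near the plane and
  ## would bias the face matching, so only the largest edge-connected
  ## component of the candidate faces is kept as the cut face
  main_component <- function(fmat, keep) {
    idx <- which(keep)
    if (length(idx) < 2) return(keep)
    f <- fmat[idx, , drop = FALSE]
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    grp <- split(rep(seq_along(idx), 3), key)
    parent <- seq_along(idx)
    find <- function(i) {
      while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
      i
    }
    for (g in grp) if (length(g) > 1)
      for (k in 2:length(g)) {
        a <- find(g[1]); b <- find(g[k])
        if (a != b) parent[b] <- a
      }
    roots <- vapply(seq_along(idx), find, integer(1))
    main <- as.integer(names(which.max(table(roots))))
    out <- rep(FALSE, length(keep))
    out[idx[roots == main]] <- TRUE
    out
  }
  if (!is.null(cut_planes)) {
    axis <- axis / sqrt(sum(axis^2))
    proj <- function(m) as.vector(face_centers(m) %*% axis)
    keep_near <- function(m, plane) {
      if (nrow(m$faces) == 0) return(rep(TRUE, 0))
      if (is.na(plane)) rep(FALSE, nrow(m$faces))
      else abs(proj(m) - plane) <= cut_tolerance
    }
    kf <- main_component(parts$foot$faces, keep_near(parts$foot, cut_planes[1]))
    kh <- main_component(parts$head$faces, keep_near(parts$head, cut_planes[2]))
    sub <- function(m, keep) triangle_mesh(m$vertices, m$faces[keep, , drop = FALSE],
                                           check_degenerate = FALSE)
    extra <- rbind(parts$foot$faces[!kf, , drop = FALSE],
                   parts$head$faces[!kh, , drop = FALSE])
    parts$exterior <- triangle_mesh(surface$vertices,
                                    rbind(parts$exterior$faces, extra),
                                    check_degenerate = FALSE)
    parts$foot <- sub(parts$foot, kf)
    parts$head <- sub(parts$head, kh)
  }
  dec <- function(m) if (nrow(m$faces) == 0) m else decimate_mesh(m, decimate_cell)
  structure(list(index = index, surface = surface,
                 head = parts$head, foot = parts$foot, exterior = parts$exterior,
                 head_reg = dec(parts$head), foot_reg = dec(parts$foot),
                 exterior_reg = dec(parts$exterior)),
            class = "block_surface_set")
}

#' Sequential reconstruction of tissue blocks to the ex vivo surface
#'
#' Starting from a centre block (largest exterior area unless given), each
#' neighbouring block is registered — affine then diffeomorphic currents
#' matching of the facing cut surfaces — to the already-reconstructed
#' neighbour, propagating head-ward then foot-ward; the deformed block
#' becomes the target for the next one.  Finally the deformed exterior
#' surfaces are joined and registered to the ex vivo tissue surface,
#' yielding one additional global chain (per-block transforms are not
#' re-solved).  In `slice2d` mode every solved transform is constrained so
#' motion along the slicing axis is a per-block translation — the classic
#' 2D slice-correspondence assumption, kept for comparison.
#'
#' @param blocks list of [block_surface_set], ordered along the head-foot
#'   axis (increasing z).
#' @param ex_vivo_surface target [triangle_mesh] (ex vivo tissue boundary).
#' @param params_face [currents_params] for face-to-face registration
#'   (kernel scale ~1 mm).
#' @param params_exterior [currents_params] for the exterior-to-ex-vivo
#'   stage (kernel scale ~2 mm, order of the block thickness).
#' @param mode `"full3d"` or `"slice2d"`.
#' @param center centre block index; `NULL` picks the largest exterior.
#' @param exterior_decimate vertex-clustering cell (mm) applied to the
#'   joined exterior before the global registration.
#' @return list with `block_chains` (per block, block -> reconstructed
#'   frame), `exterior_chain` (reconstructed -> ex vivo), `center`,
#'   `deformed_blocks` (surfaces after per-block chains), `energies`.
#' @export
reconstruct_blocks <- function(blocks, ex_vivo_surface,
                               params_face = currents_params(sigma = 1),
                               params_exterior = currents_params(sigma = 2),
                               mode = c("full3d", "slice2d"), center = NULL,
                               exterior_decimate = 2) {
  mode <- match.arg(mode)
  if (length(blocks) < 1)
    stop_historeg("no blocks to reconstruct", "historeg_empty_error")
  constraint <- if (mode == "slice2d") "z_translation_only" else "none"
  nb <- length(blocks)
  if (is.null(center)) {
    ## largest exterior surface anchors the chain best, but the end blocks'
    ## outer caps inflate their exterior area while doubling propagation
    ## depth, so the choice is restricted to interior blocks when possible
    areas <- vapply(blocks, function(b) mesh_area(b$exterior), numeric(1))
    cand <- if (nb >= 3) 2:(nb - 1) else seq_len(nb)
    center <- cand[which.max(areas[cand])]
  }
  chains <- vector("list", nb)
  deformed <- vector("list", nb)      # deformed registration-resolution sets
  energies <- list()
  chains[[center]] <- transform_chain()
  deformed[[center]] <- blocks[[center]]
  solve_block <- function(b, target_face, moving_face_name) {
    blk <- blocks[[b]]
    moving_face <- blk[[moving_face_name]]
    if (nrow(moving_face$faces) == 0)
      stop_historeg(sprintf("block %d has an empty facing surface", blk$index),
                    "historeg_degenerate_face_error")
    if (nrow(target_face$faces) == 0)
      stop_historeg("target facing surface is empty", "historeg_degenerate_face_error")
    ## the two cut faces are the same physical surface seen from opposite
    ## sides: their outward normals are anti-parallel, so the target is
    ## orientation-flipped to make the currents attract instead of repel
    target_face <- flip_mesh(target_face)
    areg <- affine_register_surfaces(moving_face, target_face, params_face,
                                     constraint = constraint, model = "rigid")
    moved_aff <- transform_mesh(moving_face, areg$transform)
    dreg <- diffeo_register_surfaces(moved_aff, target_face, params_face,
                                     constraint = constraint)
    list(chain = transform_chain(areg$transform, dreg$transform),
         energy = dreg$dissimilarity)
  }
  ## only the decimated registration meshes are deformed while propagating;
  ## full-resolution surfaces can be pushed through the stored chains on
  ## demand by the caller
  apply_block_chain <- function(b, chain) {
    blk <- blocks[[b]]
    out <- blk
    for (nm in c("head_reg", "foot_reg", "exterior_reg"))
      out[[nm]] <- transform_mesh(blk[[nm]], chain)
    out
  }
  if (center < nb) for (b in (center + 1):nb) {       # head-ward sweep
    sol <- solve_block(b, deformed[[b - 1]]$head_reg, "foot_reg")
    chains[[b]] <- sol$chain
    deformed[[b]] <- apply_block_chain(b, sol$chain)
    energies[[paste0("face_block_", blocks[[b]]$index)]] <- sol$energy
  }
  if (center > 1) for (b in (center - 1):1) {         # foot-ward sweep
    sol <- solve_block(b, deformed[[b + 1]]$foot_reg, "head_reg")
    chains[[b]] <- sol$chain
    deformed[[b]] <- apply_block_chain(b, sol$chain)
    energies[[paste0("face_block_", blocks[[b]]$index)]] <- sol$energy
  }
  joined_exterior <- decimate_mesh(
    merge_meshes(lapply(deformed, `[[`, "exterior_reg")), exterior_decimate)
  ext_target <- ex_vivo_surface
  e_before <- currents_dissimilarity(joined_exterior, ext_target,
                                     params_exterior$sigma)
  areg <- affine_register_surfaces(joined_exterior, ext_target,
                                   params_exterior, constraint = constraint)
  moved_aff <- transform_mesh(joined_exterior, areg$transform)
  dreg <- diffeo_register_surfaces(moved_aff, ext_target, params_exterior,
                                   constraint = constraint)
  exterior_chain <- transform_chain(areg$transform, dreg$transform)
  energies$exterior_before <- e_before
  energies$exterior_after <- dreg$dissimilarity
  list(block_chains = chains, exterior_chain = exterior_chain,
       center = center, deformed_blocks = deformed, energies = energies,
       mode = mode)
}

#' Full chain from block coordinates to the ex vivo frame
#'
#' Convenience accessor composing a block's reconstruction chain with the
#' global exterior chain.
#'
#' @param recon output of [reconstruct_blocks()].
#' @param b block position (same indexing as the `blocks` argument).
#' @return a [transform_chain] mapping block coordinates to ex vivo mm.
#' @export
block_to_exvivo_chain <- function(recon, b) {
  transform_chain(recon$block_chains[[b]], recon$exterior_chain)
}
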