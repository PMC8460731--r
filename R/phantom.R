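#' Specification of the synthetic destructive-histopathology phantom
#'
#' Defines the digital subject and the magnitude of every degradation the
#' tissue-processing pipeline applies to it.  Geometry defaults mirror the
#' workflow being emulated: ~15 mm of tissue along the sectioning (z) axis
#' cut into ~3 mm blocks, histology retained every 250 um and blockface
#' images every 50 um; per-stage deformation magnitudes (excision 2 mm,
#' block 0.8 mm, section 0.4 mm) are chosen so per-stage ground-truth
#' errors bracket the sub-millimetre scales the restoring registrations
#' must recover.
#'
#' @param volume_size length-3 field of view, mm.
#' @param spacing voxel spacing, mm.
#' @param tissue_radii semi-axes of the tissue ellipsoid, mm.
#' @param necrosis_center_offset,necrosis_radii geometry of the internal
#'   necrosis lesion, mm (must sit strictly inside the tissue).
#' @param n_tubes,tube_radius tubular "vessel" features crossing the tissue.
#' @param n_blobs,blob_radius blob "tumour" features inside the tissue.
#' @param excision_magnitude,excision_smoothness max displacement and
#'   correlation length (mm) of the smooth excision deformation.
#' @param excision_rigid_deg,excision_rigid_mm rigid perturbation bounds.
#' @param block_thickness gross-slicing increment, mm.
#' @param block_magnitude,block_smoothness per-block smooth deformation, mm.
#' @param block_out_of_plane scale (0..1) of the out-of-plane (z) component
#'   of per-block deformations; 0 makes block degradation purely in-plane.
#' @param section_spacing_um histology retention interval, micrometres.
#' @param blockface_spacing_um blockface imaging interval, micrometres.
#' @param section_distortion_magnitude,section_smoothness per-section smooth
#'   2D distortion, mm.
#' @param section_inplane_spacing pixel size of section images, mm.
#' @param camera_jitter_px max per-image blockface camera shift, pixels.
#' @param landmarks_per_stage evaluation landmarks per stage.
#' @param noise_sd,bias_amplitude intensity noise and smooth bias of the
#'   rendered images.
#' @param seed integer governing all phantom randomness (per-stage sub-seeds
#'   are derived deterministically).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_size = c(30, 30, 22), spacing = c(1, 1, 1),
                         tissue_radii = c(11, 10, 7.5),
                         necrosis_center_offset = c(1.5, -1, 0.5),
                         necrosis_radii = c(5, 4.5, 4),
                         n_tubes = 2, tube_radius = 1.5,
                         n_blobs = 2, blob_radius = 2.5,
                         excision_magnitude = 2, excision_smoothness = 6,
                         excision_rigid_deg = 3, excision_rigid_mm = 1,
                         block_thickness = 3,
                         block_magnitude = 0.8, block_smoothness = 4,
                         block_out_of_plane = 1,
                         section_spacing_um = 250, blockface_spacing_um = 50,
                         section_distortion_magnitude = 0.4,
                         section_smoothness = 3,
                         section_inplane_spacing = 0.5,
                         camera_jitter_px = 2,
                         landmarks_per_stage = 5,
                         noise_sd = 2, bias_amplitude = 0.05,
                         seed = 1) {
  sp <- as.list(environment())
  if (any(unlist(sp[c("excision_magnitude", "block_magnitude",
                      "section_distortion_magnitude")]) < 0))
    stop_historeg("deformation magnitudes must be >= 0", "historeg_parameter_error")
  if (any(spacing <= 0) || section_spacing_um <= 0 || blockface_spacing_um <= 0)
    stop_historeg("spacings must be positive", "historeg_parameter_error")
  if (block_thickness * 1000 <= section_spacing_um)
    stop_historeg("block thickness must exceed the section spacing",
                  "historeg_parameter_error")
  structure(sp, class = "phantom_spec")
}

## class codes of the digital subject
PHANTOM_CLASSES <- c(background = 0, tissue = 1, necrosis = 2, tube = 3, blob = 4)

## modality lookup tables: class intensity per imaging stage; contrasts
## deliberately differ between stages so no registration step can succeed
## by intensity identity alone
phantom_lut <- function(modality) {
  switch(modality,
         mr_invivo = c(5, 100, 150, 55, 130),
         mr_exvivo = c(8, 120, 165, 70, 145),
         blockface = c(10, 180, 120, 90, 150),
         stop_historeg("unknown modality", "historeg_parameter_error"))
}

#' Render a class volume as a noisy modality image
#'
#' Applies the modality intensity table, a smooth multiplicative bias field
#' and additive Gaussian noise.
#'
#' @param class_vol [image_volume] of integer class codes.
#' @param modality `"mr_invivo"`, `"mr_exvivo"` or `"blockface"`.
#' @param spec a [phantom_spec] (noise/bias parameters and seed).
#' @param seed_tag string distinguishing renders of different stages.
#' @return an [image_volume] of intensities.
#' @export
render_phantom_volume <- function(class_vol, modality, spec,
                                  seed_tag = modality) {
  set.seed(derive_seed(spec$seed, paste0("render_", seed_tag)))
  lut <- phantom_lut(modality)
  vals <- array(lut[class_vol$values + 1], dim(class_vol$values))
  dm <- dim(vals)
  ax <- lapply(1:3, function(a) seq(0, pi, length.out = dm[a]))
  bias <- 1 + spec$bias_amplitude *
    outer(outer(sin(ax[[1]]), cos(2 * ax[[2]])), sin(ax[[3]] + 0.7))
  vals <- vals * bias + stats::rnorm(length(vals), sd = spec$noise_sd)
  image_volume(vals, class_vol$spacing, class_vol$origin, class_vol$orientation)
}

mask_from_class <- function(class_vol, classes) {
  label_volume(array((class_vol$values %in% classes) + 0, dim(class_vol$values)),
               class_vol$spacing, class_vol$origin, class_vol$orientation)
}

#' Generate the in vivo digital subject
#'
#' Builds the class volume (tissue ellipsoid, internal necrosis lesion,
#' tubular and blob features), the rendered in vivo MR-like image, the
#' ground-truth necrosis label, feature surface meshes, and the evaluation
#' landmarks (placed well inside the tissue).  Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [phantom_spec].
#' @return list of class `phantom` with `class_volume`, `in_vivo`,
#'   `tissue_label`, `necrosis_label`, `feature_meshes`, `landmarks`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  set.seed(derive_seed(spec$seed, "subject"))
  dm <- ceiling(spec$volume_size / spec$spacing)
  ctr <- spec$volume_size / 2
  if (any(abs(spec$necrosis_center_offset) + spec$necrosis_radii >
          spec$tissue_radii))
    stop_historeg("necrosis lesion extends outside the tissue",
                  "historeg_geometry_error")
  idx <- as.matrix(expand.grid(x = seq_len(dm[1]) - 1, y = seq_len(dm[2]) - 1,
                               z = seq_len(dm[3]) - 1))
  pos <- sweep(idx, 2, spec$spacing, "*")
  inside_ellipsoid <- function(p, c0, r) {
    rowSums(sweep(sweep(p, 2, c0), 2, r, "/")^2) < 1
  }
  cls <- numeric(nrow(pos))
  cls[inside_ellipsoid(pos, ctr, spec$tissue_radii)] <- PHANTOM_CLASSES["tissue"]
  ncr_ctr <- ctr + spec$necrosis_center_offset
  cls[cls > 0 & inside_ellipsoid(pos, ncr_ctr, spec$necrosis_radii)] <-
    PHANTOM_CLASSES["necrosis"]
  ## tubular features: lines through the tissue with random direction
  tube_dirs <- list()
  if (spec$n_tubes > 0) for (k in seq_len(spec$n_tubes)) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    o <- ctr + stats::runif(3, -0.35, 0.35) * spec$tissue_radii
    rel <- sweep(pos, 2, o)
    proj <- as.vector(rel %*% d)
    rad2 <- rowSums(rel^2) - proj^2
    ## features only claim plain tissue so the necrosis label stays intact
    sel <- cls == PHANTOM_CLASSES["tissue"] & rad2 < spec$tube_radius^2
    cls[sel] <- PHANTOM_CLASSES["tube"]
    tube_dirs[[k]] <- list(origin = o, dir = d)
  }
  if (spec$n_blobs > 0) for (k in seq_len(spec$n_blobs)) {
    o <- ctr + stats::runif(3, -0.45, 0.45) * (spec$tissue_radii - spec$blob_radius)
    sel <- cls == PHANTOM_CLASSES["tissue"] &
      inside_ellipsoid(pos, o, rep(spec$blob_radius, 3))
    cls[sel] <- PHANTOM_CLASSES["blob"]
  }
  class_volume <- image_volume(array(cls, dm), spec$spacing, c(0, 0, 0))
  tissue_label <- mask_from_class(class_volume, 1:4)
  necrosis_label <- mask_from_class(class_volume, PHANTOM_CLASSES["necrosis"])
  feature_meshes <- phantom_feature_meshes(class_volume)
  ## landmarks: inside the tissue, away from its boundary
  margin <- 0.7
  cand <- which(inside_ellipsoid(pos, ctr, spec$tissue_radii * margin))
  pick <- sample(cand, spec$landmarks_per_stage)
  lms <- landmark_set(pos[pick, , drop = FALSE], space = "in_vivo")
  structure(list(class_volume = class_volume,
                 in_vivo = render_phantom_volume(class_volume, "mr_invivo", spec),
                 tissue_label = tissue_label, necrosis_label = necrosis_label,
                 feature_meshes = feature_meshes, landmarks = lms, spec = spec),
            class = "phantom")
}

## feature surfaces for feature-based 3D registration: vessels (tubes),
## tumour blobs, and the treatment lesion itself -- features visible in
## both ex vivo and in vivo MR of the same contrast may include treatment
## features, which is what anchors the excision correction near the lesion
phantom_feature_meshes <- function(class_volume, decimate_cell = 1.5) {
  out <- list()
  for (cl in c("tube", "blob", "necrosis")) {
    msk <- mask_from_class(class_volume, PHANTOM_CLASSES[cl])
    if (sum(msk$values) < 8) next
    m <- surface_from_labels(msk, 0.5, smooth_sigma = 0.5)
    out[[cl]] <- decimate_mesh(m, decimate_cell)
  }
  out
}

## Smooth random diffeomorphism on a volume domain: white noise per
## component on a coarse grid, Gaussian-smoothed, scaled to `magnitude`
## max displacement, integrated as a stationary flow in n_steps.
random_smooth_diffeo <- function(domain_lo, domain_hi, magnitude, smoothness,
                                 dim = 3, zscale = 1, n_steps = 6,
                                 grid_step = NULL) {
  if (magnitude <= 0) {
    return(diffeomorphism(list(), rbind(domain_lo, domain_hi), dim = dim,
                          validate = FALSE))
  }
  grid_step <- grid_step %||% max(smoothness / 3, 1)
  n <- pmax(ceiling((domain_hi - domain_lo) / grid_step) + 3, 4)
  v <- array(stats::rnorm(prod(n) * dim), c(n, dim))
  sig <- smoothness / grid_step
  for (c in seq_len(dim)) {
    comp <- if (dim == 2) v[, , c] else v[, , , c]
    comp <- gaussian_smooth_array(comp, sig)
    if (dim == 2) v[, , c] <- comp else v[, , , c] <- comp
  }
  if (dim == 3 && zscale != 1) v[, , , 3] <- v[, , , 3] * zscale
  mag <- sqrt(Reduce(`+`, lapply(seq_len(dim), function(c)
    (if (dim == 2) v[, , c] else v[, , , c])^2)))
  v <- v * (magnitude / max(mag))
  origin <- domain_lo - grid_step
  for (attempt in 1:5) {
    steps <- lapply(seq_len(n_steps), function(k)
      grid_velocity_step(v, rep(grid_step, dim), origin, dt = 1 / n_steps))
    phi <- diffeomorphism(steps, rbind(domain_lo, domain_hi), dim = dim,
                          validate = FALSE)
    chk <- check_diffeomorphism(phi, n = 6, tol = 0.15)
    if (chk$ok) return(phi)
    warning("random deformation amplitude reduced to keep it diffeomorphic")
    v <- v * 0.7
  }
  stop_historeg("could not build a diffeomorphic random deformation",
                "historeg_diffeo_error")
}

rotation3 <- function(axis, angle_deg) {
  ax <- axis / sqrt(sum(axis^2)); a <- angle_deg * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

## Resample a class volume (nearest neighbour) through chain^-1 onto `grid`.
resample_class <- function(class_vol, chain, grid) {
  pts <- volume_grid_points(grid)
  src <- if (is.null(chain)) pts else apply_chain(invert_chain(chain), pts)
  vals <- sample_volume(class_vol, src, interpolation = "nearest", fill = 0)
  image_volume(array(vals, dim(grid$values)), grid$spacing, grid$origin,
               grid$orientation)
}

#' Simulate tissue excision and fixation
#'
#' Applies the ground-truth excision degradation: a smooth random
#' diffeomorphism (bounded displacement, checked-positive Jacobian) composed
#' with a small rigid perturbation.  The returned chain maps in vivo
#' coordinates to ex vivo coordinates; the ex vivo class volume and rendered
#' ex vivo MR-like image are produced by pulling classes back through its
#' inverse.
#'
#' @param phantom output of [generate_phantom()].
#' @param spec the [phantom_spec].
#' @return list with `chain` (ground truth, in vivo -> ex vivo),
#'   `class_volume`, `ex_vivo` (rendered), `tissue_label`.
#' @export
simulate_excision <- function(phantom, spec = phantom$spec) {
  set.seed(derive_seed(spec$seed, "excision"))
  g <- phantom$class_volume
  lo <- g$origin; hi <- g$origin + (dim(g$values) - 1) * g$spacing
  phi <- random_smooth_diffeo(lo, hi, spec$excision_magnitude,
                              spec$excision_smoothness)
  ctr <- (lo + hi) / 2
  R <- rotation3(stats::rnorm(3), stats::runif(1, -1, 1) * spec$excision_rigid_deg)
  tr <- stats::runif(3, -1, 1) * spec$excision_rigid_mm
  rigid <- affine_transform(R, ctr - as.vector(R %*% ctr) + tr)
  chain <- transform_chain(phi, rigid)
  cls <- resample_class(g, chain, g)
  list(chain = chain, class_volume = cls,
       ex_vivo = render_phantom_volume(cls, "mr_exvivo", spec,
                                       seed_tag = "exvivo"),
       tissue_label = mask_from_class(cls, 1:4))
}

#' Simulate gross slicing into tissue blocks
#'
#' Cuts the ex vivo tissue along the z (head-foot) axis into
#' `block_thickness` mm blocks and gives each an independent small rigid
#' plus smooth deformation (ground truth stored per block).  Each block's
#' chain maps ex vivo coordinates to that block's local coordinates.
#'
#' @param ex output of [simulate_excision()].
#' @param spec the [phantom_spec].
#' @return list of blocks, each with `index`, `chain` (ex vivo -> block),
#'   `class_volume` (block grid), `z_range` (ex vivo mm), plus `n_blocks`.
#' @export
simulate_gross_slicing <- function(ex, spec) {
  set.seed(derive_seed(spec$seed, "slicing"))
  g <- ex$class_volume
  zw <- voxel_to_world(g, cbind(0, 0, seq_len(dim(g$values)[3]) - 1))[, 3]
  occ <- apply(g$values > 0, 3, any)
  if (!any(occ)) stop_historeg("no tissue to slice", "historeg_empty_error")
  z0 <- min(zw[occ]); z1 <- max(zw[occ]) + 1e-9
  if (spec$block_thickness > (z1 - z0))
    stop_historeg("block thickness exceeds the tissue extent",
                  "historeg_slicing_error")
  nb <- ceiling((z1 - z0) / spec$block_thickness)
  ## a sliver of a final block (thinner than a third of the increment)
  ## stays attached to its neighbour, as gross slicing would leave it
  if (nb >= 2 && (z1 - (z0 + (nb - 1) * spec$block_thickness)) <
        spec$block_thickness / 3)
    nb <- nb - 1
  blocks <- vector("list", nb)
  lo <- g$origin; hi <- g$origin + (dim(g$values) - 1) * g$spacing
  for (b in seq_len(nb)) {
    zlo <- z0 + (b - 1) * spec$block_thickness
    zhi <- if (b == nb) z1 else zlo + spec$block_thickness
    phi <- random_smooth_diffeo(c(lo[1:2], zlo), c(hi[1:2], zhi),
                                spec$block_magnitude, spec$block_smoothness,
                                zscale = spec$block_out_of_plane)
    ctr <- c((lo[1:2] + hi[1:2]) / 2, (zlo + zhi) / 2)
    ang <- stats::runif(1, -1, 1) * 1.5
    R <- rotation3(c(stats::rnorm(2) * 0.3 * spec$block_out_of_plane, 1), ang)
    tr <- c(stats::runif(2, -0.6, 0.6),
            stats::runif(1, -0.3, 0.3) * spec$block_out_of_plane) *
      (spec$block_magnitude / 0.8)
    rigid <- affine_transform(R, ctr - as.vector(R %*% ctr) + tr)
    chain <- transform_chain(phi, rigid)
    ## block grid: fine z sampling on a lattice shared by all blocks, so
    ## the cut planes quantize identically on both sides of each cut; the
    ## slab window is applied continuously in ex vivo z at resample time
    bz <- min(g$spacing[3], 0.5)
    mz <- 2 * max(g$spacing)
    zg0 <- g$origin[3] + floor((zlo - mz - g$origin[3]) / bz) * bz
    nz <- ceiling((zhi + mz - zg0) / bz) + 1
    grid <- image_volume(array(0, c(dim(g$values)[1:2], nz)),
                         c(g$spacing[1:2], bz), c(g$origin[1:2], zg0))
    pts <- volume_grid_points(grid)
    src <- apply_chain(invert_chain(chain), pts)
    vals <- sample_volume(g, src, interpolation = "nearest", fill = 0)
    vals[src[, 3] < zlo | src[, 3] >= zhi] <- 0
    cls_block <- image_volume(array(vals, dim(grid$values)), grid$spacing,
                              grid$origin)
    blocks[[b]] <- list(index = b, chain = chain, class_volume = cls_block,
                        z_range = c(zlo, zhi))
  }
  list(blocks = blocks, n_blocks = nb)
}

## Smooth random 2D diffeomorphism for per-section distortions.
random_smooth_diffeo2 <- function(lo, hi, magnitude, smoothness, n_steps = 4) {
  random_smooth_diffeo(lo, hi, magnitude, smoothness, dim = 2,
                       n_steps = n_steps)
}

#' Simulate microtome sectioning of one block
#'
#' Produces the blockface image series (every `blockface_spacing_um`, with
#' simulated paraffin show-through via two lighting conditions and per-image
#' camera jitter) and the retained histology sections (every
#' `section_spacing_um`, each with an independent smooth 2D distortion).
#' All ground-truth transforms are returned.
#'
#' @param block one element of [simulate_gross_slicing()]'s `blocks`.
#' @param spec the [phantom_spec].
#' @return list with `blockface` (per image: `parallel`, `perpendicular`,
#'   `jitter_px`, `depth`) and `histology` (per section: `tissue_seg`,
#'   `necrosis_seg`, `depth`, `distortion` ground-truth 2D diffeo mapping
#'   undistorted block-plane coordinates to histology coordinates).
#' @export
simulate_sectioning <- function(block, spec) {
  set.seed(derive_seed(spec$seed, paste0("sectioning_", block$index)))
  g <- block$class_volume
  bf_dz <- spec$blockface_spacing_um / 1000
  hist_dz <- spec$section_spacing_um / 1000
  zlo <- block$z_range[1]; zhi <- block$z_range[2]
  if ((zhi - zlo) < hist_dz)
    stop_historeg("block is thinner than one section spacing",
                  "historeg_sectioning_error")
  sp2 <- rep(spec$section_inplane_spacing, 2)
  n2 <- ceiling(dim(g$values)[1:2] * g$spacing[1:2] / sp2)
  px <- as.matrix(expand.grid(x = seq_len(n2[1]) - 1, y = seq_len(n2[2]) - 1))
  xy <- sweep(sweep(px, 2, sp2, "*"), 2, g$origin[1:2], "+")
  class_slice <- function(depth) {
    vals <- sample_volume(g, cbind(xy, depth), interpolation = "nearest")
    matrix(vals, n2[1], n2[2])
  }
  lut <- phantom_lut("blockface")
  ## blockface photographs morph smoothly with depth: intensities are
  ## sampled from the LUT-mapped block volume with linear interpolation,
  ## so consecutive 50 um faces differ gradually rather than jumping at
  ## voxel boundaries
  ivol <- image_volume(array(lut[g$values + 1], dim(g$values)), g$spacing,
                       g$origin)
  intensity_slice <- function(depth) {
    matrix(sample_volume(ivol, cbind(xy, depth), interpolation = "linear",
                         fill = lut[1]), n2[1], n2[2])
  }
  ## the paraffin block itself is faintly visible in the lighting
  ## difference: a static rectangle in scene coordinates that anchors the
  ## camera-jitter correction (tissue alone drifts with depth, so aligning
  ## on it would absorb anatomical cross-section motion)
  inset <- 1.5
  lo2w <- g$origin[1:2] + inset
  hi2w <- g$origin[1:2] + (dim(g$values)[1:2] - 1) * g$spacing[1:2] - inset
  paraffin <- matrix(as.numeric(xy[, 1] >= lo2w[1] & xy[, 1] <= hi2w[1] &
                                  xy[, 2] >= lo2w[2] & xy[, 2] <= hi2w[2]),
                     n2[1], n2[2])
  depths_bf <- seq(zlo, zhi - 1e-9, by = bf_dz)
  blockface <- vector("list", length(depths_bf))
  for (i in seq_along(depths_bf)) {
    d <- depths_bf[i]
    surf <- intensity_slice(d)
    surf <- pmax(surf, 35 * paraffin)
    deeper <- intensity_slice(d + 0.4)
    show_through <- 0.4 * deeper
    jit <- round(stats::runif(2, -1, 1) * spec$camera_jitter_px)
    ## camera shift: pixel (i,j) images the world point xy + jit * pixel
    shift_img <- function(m) {
      img <- image2d(m, sp2, g$origin[1:2], d)
      matrix(sample_image2d(img, sweep(xy, 2, jit * sp2, "+"),
                            interpolation = "nearest"), n2[1], n2[2])
    }
    noise <- function() matrix(stats::rnorm(prod(n2), sd = spec$noise_sd), n2[1], n2[2])
    blockface[[i]] <- list(
      parallel = image2d(shift_img(surf + show_through) + noise(), sp2,
                         g$origin[1:2], d),
      perpendicular = image2d(shift_img(show_through) + noise(), sp2,
                              g$origin[1:2], d),
      clean_seg = image2d((class_slice(d) > 0) + 0, sp2, g$origin[1:2], d),
      jitter_px = jit, depth = d)
  }
  depths_h <- seq(zlo, zhi - 1e-9, by = hist_dz)
  lo2 <- g$origin[1:2]; hi2 <- g$origin[1:2] + (dim(g$values)[1:2] - 1) * g$spacing[1:2]
  histology <- vector("list", length(depths_h))
  for (i in seq_along(depths_h)) {
    d <- depths_h[i]
    theta <- random_smooth_diffeo2(lo2, hi2, spec$section_distortion_magnitude,
                                   spec$section_smoothness)
    seg <- (class_slice(d) > 0) + 0
    ncr <- (class_slice(d) == PHANTOM_CLASSES["necrosis"]) + 0
    src <- apply_diffeomorphism(theta, xy, inverse = TRUE)
    pull <- function(m) {
      img <- image2d(m, sp2, g$origin[1:2], d)
      matrix(sample_image2d(img, src, interpolation = "nearest"), n2[1], n2[2])
    }
    histology[[i]] <- list(
      tissue_seg = image2d(pull(seg), sp2, g$origin[1:2], d),
      necrosis_seg = image2d(pull(ncr), sp2, g$origin[1:2], d),
      depth = d, distortion = theta)
  }
  list(blockface = blockface, histology = histology)
}

#' Full destructive simulation of a phantom
#'
#' Convenience wrapper running excision, gross slicing and sectioning for
#' every block, returning all stages with their ground-truth transforms.
#'
#' @param spec a [phantom_spec].
#' @param sectioning if `FALSE`, stop after gross slicing (cheaper when only
#'   block reconstruction is being exercised).
#' @return list with `phantom`, `excision`, `slicing`, and (optionally)
#'   `sections` (one entry per block).
#' @export
simulate_destructive_pipeline <- function(spec = phantom_spec(),
                                          sectioning = TRUE) {
  ph <- generate_phantom(spec)
  ex <- simulate_excision(ph, spec)
  sl <- simulate_gross_slicing(ex, spec)
  out <- list(phantom = ph, excision = ex, slicing = sl)
  if (sectioning)
    out$sections <- lapply(sl$blocks, simulate_sectioning, spec = spec)
  out
}

#' Ground-truth chain from a histology section to in vivo coordinates
#'
#' Composes the inverses of the stored per-section 2D distortion, the
#' block's slicing transform, and the excision transform.  This is the
#' oracle every restoring registration is evaluated against.
#'
#' @param sim output of [simulate_destructive_pipeline()].
#' @param block_index,section_index which histology section.
#' @return a [transform_chain] mapping (x, y, depth) histology coordinates
#'   to in vivo mm.
#' @export
phantom_ground_truth_chain <- function(sim, block_index, section_index) {
  blk <- sim$slicing$blocks[[block_index]]
  sec <- sim$sections[[block_index]]$histology[[section_index]]
  transform_chain(chain_element(sec$distortion, "inverse"),
                  invert_chain(blk$chain),
                  invert_chain(sim$excision$chain))
}
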