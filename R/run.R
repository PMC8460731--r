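#' Parameter bundle for the full restoring pipeline
#'
#' Collects the per-stage registration parameters with defaults sized for
#' millimetre-resolution phantoms: ~1 mm currents scale for block face
#' matching, ~2 mm (order of the block thickness) for the exterior and
#' feature stages, a short pyramid for the small 2D section images.
#'
#' @param r1 [image_reg_params] for histology-to-blockface registration.
#' @param stack [image_reg_params] for sequential blockface alignment.
#' @param face,exterior,r3 [currents_params] for the three surface stages.
#' @param surface_spacing isotropic grid (mm) for label isosurfacing.
#' @param decimate_cell,exterior_decimate,feature_decimate vertex-clustering
#'   cells, mm.
#' @param cut_tolerance distance tolerance of cut faces to the cut plane, mm.
#' @param bf_threshold intensity threshold segmenting tissue in
#'   lighting-difference blockface images.
#' @param mode `"full3d"` or `"slice2d"` (2D slice-correspondence ablation).
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(r1 = image_reg_params(pyramid_levels = c(2, 1),
                                                  max_iters = 45),
                            stack = image_reg_params(pyramid_levels = 1,
                                                     max_iters = 30,
                                                     convergence_tol = 1e-5),
                            face = currents_params(sigma = 1,
                                                   sigma_schedule = c(2, 1),
                                                   max_iters = 50),
                            exterior = currents_params(sigma = 2, sigma_schedule = 2,
                                                       velocity_kernel_scale = 1,
                                                       max_iters = 30),
                            r3 = currents_params(sigma = 2, max_iters = 80),
                            surface_spacing = 0.4, decimate_cell = 1.2,
                            exterior_decimate = 2, feature_decimate = 1.2,
                            cut_tolerance = 0.5,
                            bf_threshold = 60,
                            mode = c("full3d", "slice2d")) {
  mode <- match.arg(mode)
  structure(list(r1 = r1, stack = stack, face = face, exterior = exterior,
                 r3 = r3, surface_spacing = surface_spacing,
                 decimate_cell = decimate_cell,
                 exterior_decimate = exterior_decimate,
                 feature_decimate = feature_decimate,
                 cut_tolerance = cut_tolerance, bf_threshold = bf_threshold,
                 mode = mode),
            class = "pipeline_params")
}

threshold_image2d <- function(img, thr) {
  image2d((img$values > thr) + 0, img$spacing, img$origin, img$section_depth)
}

## Segment the aligned blockface stack volume into a tissue label.
stack_tissue_label <- function(stack, thr) {
  label_volume(array((stack$volume$values > thr) + 0, dim(stack$volume$values)),
               stack$volume$spacing, stack$volume$origin)
}

#' Run the restoring registration pipeline on simulated data
#'
#' Executes the three restoring stages on the output of
#' [simulate_destructive_pipeline()]: per-block blockface stack alignment
#' and histology-to-blockface registration (R1), sequential block
#' reconstruction to the ex vivo surface (R2), and feature-surface
#' registration of ex vivo to in vivo (R3).  Tissue and feature
#' segmentations are taken from the simulator (segmentation itself is
#' outside this package's scope); every registration sees only images and
#' surfaces, never ground-truth transforms.
#'
#' @param sim output of [simulate_destructive_pipeline()] (with sections).
#' @param params [pipeline_params].
#' @param progress print per-stage timing.
#' @return list of class `historeg_fit` with `stacks`, `r1` (per block: per
#'   section chains), `recon` (R2), `r3`, `section_chains` (full composed
#'   chains per histology section), `params`.
#' @export
restore_pipeline <- function(sim, params = pipeline_params(), progress = TRUE) {
  t_start <- Sys.time()
  say <- function(...) if (progress) message(sprintf(...))
  nb <- sim$slicing$n_blocks
  ## ---- R1: blockface stacks and histology-to-blockface -----------------
  stacks <- vector("list", nb)
  r1 <- vector("list", nb)
  for (b in seq_len(nb)) {
    sec <- sim$sections[[b]]
    imgs <- lapply(sec$blockface, function(bf)
      lighting_difference(bf$parallel, bf$perpendicular))
    stacks[[b]] <- align_blockface_stack(imgs, params$stack,
                                         content_threshold = params$bf_threshold)
    r1[[b]] <- lapply(sec$histology, function(h) {
      ## slides with no tissue (ends of a block) have nothing to register
      if (sum(h$tissue_seg$values) < 20) return(NULL)
      idx <- match_section_to_blockface(h$depth, stacks[[b]])
      bf_seg <- threshold_image2d(stacks[[b]]$images[[idx]], params$bf_threshold)
      if (sum(bf_seg$values) < 20) return(NULL)
      reg <- register_histology_to_blockface(h$tissue_seg, bf_seg, params$r1)
      c(reg, list(blockface_index = idx, depth = h$depth))
    })
    say("R1 block %d/%d done (%.1f s elapsed)", b, nb,
        as.numeric(Sys.time() - t_start, units = "secs"))
  }
  ## ---- R2: block surfaces and sequential reconstruction ----------------
  blocks <- vector("list", nb)
  for (b in seq_len(nb)) {
    lab <- stack_tissue_label(stacks[[b]], params$bf_threshold)
    surf <- label_surface(lab, target_spacing = params$surface_spacing)
    zr <- sim$slicing$blocks[[b]]$z_range
    cp <- c(if (b == 1) NA else zr[1], if (b == nb) NA else zr[2])
    blocks[[b]] <- block_surface_set(surf, b, cut_planes = cp,
                                     cut_tolerance = params$cut_tolerance,
                                     decimate_cell = params$decimate_cell)
  }
  ex_surface <- label_surface(sim$excision$tissue_label,
                              target_spacing = params$surface_spacing,
                              decimate_cell = params$exterior_decimate * 0.9)
  recon <- reconstruct_blocks(blocks, ex_surface,
                              params_face = params$face,
                              params_exterior = params$exterior,
                              mode = params$mode,
                              exterior_decimate = params$exterior_decimate)
  say("R2 done (%.1f s elapsed)", as.numeric(Sys.time() - t_start, units = "secs"))
  ## ---- R3: feature surfaces ex vivo -> in vivo --------------------------
  feats_ex <- list(); feats_in <- list()
  for (cl in names(sim$phantom$feature_meshes)) {
    code <- PHANTOM_CLASSES[cl]
    msk <- mask_from_class(sim$excision$class_volume, code)
    if (sum(msk$values) < 8) next
    feats_ex[[cl]] <- label_surface(msk, target_spacing = params$surface_spacing,
                                    smooth_sigma = 0.5,
                                    decimate_cell = params$feature_decimate)
    feats_in[[cl]] <- sim$phantom$feature_meshes[[cl]]
  }
  r3 <- register_exvivo_to_invivo(feats_ex, feats_in, params$r3)
  say("R3 done (%.1f s elapsed)", as.numeric(Sys.time() - t_start, units = "secs"))
  ## ---- full chains per histology section --------------------------------
  section_chains <- vector("list", nb)
  group_chains <- vector("list", nb)   # shared stack -> in vivo chain per block
  ## grid-sampled copies of the stage flows (1 mm): evaluating the dense
  ## inverse maps for label construction is then one interpolation per
  ## step instead of one kernel evaluation per control point, and the
  ## shared exterior/feature chains are discretized once, not per block
  ext_fast <- discretize_chain(recon$exterior_chain, 1)
  r3_fast <- discretize_chain(r3$chain, 1)
  for (b in seq_len(nb)) {
    group_chains[[b]] <- transform_chain(
      discretize_chain(recon$block_chains[[b]], 1), ext_fast, r3_fast)
    section_chains[[b]] <- lapply(r1[[b]], function(rr) {
      if (is.null(rr)) return(NULL)
      build_full_chain(rr$chain, recon$block_chains[[b]],
                       recon$exterior_chain, r3$chain, rr$depth)
    })
  }
  structure(list(stacks = stacks, r1 = r1, blocks = blocks, recon = recon,
                 r3 = r3, section_chains = section_chains,
                 group_chains = group_chains, params = params,
                 elapsed_s = as.numeric(Sys.time() - t_start, units = "secs")),
            class = "historeg_fit")
}

#' @export
print.historeg_fit <- function(x, ...) {
  cat(sprintf("<historeg_fit: %d blocks, %d histology sections, mode %s, %.1f s>\n",
              length(x$blocks), sum(lengths(x$r1)), x$params$mode, x$elapsed_s))
  invisible(x)
}

## Landmarks on a histology section: pixels well inside the tissue mask.
section_landmarks <- function(sec, n = 5, seed = 1) {
  set.seed(seed)
  m <- sec$tissue_seg$values > 0.5
  er <- m
  for (k in 1:3) {
    er <- er & rbind(m[-1, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
      cbind(m[, -1], FALSE) & cbind(FALSE, m[, -ncol(m)])
    m <- er
  }
  idx <- which(er, arr.ind = TRUE) - 1
  if (nrow(idx) < n) return(NULL)
  pick <- idx[sample(nrow(idx), n), , drop = FALSE]
  pixel_to_world2(sec$tissue_seg, pick)
}

#' Evaluate a pipeline fit against the simulator's ground truth
#'
#' Computes per-stage target registration errors on landmarks that never
#' drove any registration, the cumulative error (sum of stage means), the
#' end-to-end composed-chain error, and — when `histology_volume` is `TRUE`
#' — the volumetric necrosis label rebuilt in the in vivo frame with its
#' overlap metrics against the simulator's necrosis label.
#'
#' @param sim output of [simulate_destructive_pipeline()].
#' @param fit output of [restore_pipeline()].
#' @param histology_volume build the volumetric label (the slowest step).
#' @param landmark_seed seed for evaluation landmark placement.
#' @return list with `stage_tre` (data.frame), `cumulative_mm`,
#'   `composed_tre` and optionally `volume` (label + metrics).
#' @export
evaluate_restoration <- function(sim, fit, histology_volume = TRUE,
                                 landmark_seed = 1) {
  nb <- sim$slicing$n_blocks
  spec <- sim$phantom$spec
  nlm <- spec$landmarks_per_stage
  ## ---- R1 TRE: per-section 2D landmarks ---------------------------------
  usable_mid <- function(b) {
    ok <- which(!vapply(fit$r1[[b]], is.null, logical(1)))
    if (!length(ok)) return(NA_integer_)
    ok[ceiling(length(ok) / 2)]
  }
  r1_err <- c()
  for (b in seq_len(nb)) {
    hsec <- sim$sections[[b]]$histology
    s_mid <- usable_mid(b)
    if (is.na(s_mid)) next
    sec <- hsec[[s_mid]]
    lm_bf <- section_landmarks(sec, nlm, landmark_seed + b)
    if (is.null(lm_bf)) next
    ## landmarks were drawn on the distorted histology image; their true
    ## undistorted (blockface-plane) positions come from the stored field
    lm_hist <- lm_bf
    lm_true_bf <- apply_diffeomorphism(sec$distortion, lm_hist, inverse = TRUE)
    ## stack frame = camera frame of the anchor blockface image
    jit1 <- sim$sections[[b]]$blockface[[fit$stacks[[b]]$anchor]]$jitter_px *
      rep(spec$section_inplane_spacing, 2)
    target <- sweep(lm_true_bf, 2, jit1)
    est <- apply_chain(fit$r1[[b]][[s_mid]]$chain, lm_hist)
    r1_err <- c(r1_err, row_norms(est - target))
  }
  ## ---- R2 TRE: block-frame landmarks through block+exterior chains ------
  r2_err <- c(); r2_err_z <- c()
  g <- sim$excision$class_volume
  pts <- volume_grid_points(g)
  for (b in seq_len(nb)) {
    blk <- sim$slicing$blocks[[b]]
    sel <- which(g$values > 0 & pts[, 3] >= blk$z_range[1] + 0.4 &
                   pts[, 3] < blk$z_range[2] - 0.4)
    if (length(sel) < nlm) next
    set.seed(landmark_seed + 100 + b)
    p_ex <- pts[sample(sel, nlm), , drop = FALSE]
    p_blk <- apply_chain(blk$chain, p_ex)     # true block coordinates
    jit1 <- sim$sections[[b]]$blockface[[fit$stacks[[b]]$anchor]]$jitter_px *
      rep(spec$section_inplane_spacing, 2)
    p_stack <- cbind(sweep(p_blk[, 1:2, drop = FALSE], 2, jit1),
                     p_blk[, 3])
    est <- apply_chain(block_to_exvivo_chain(fit$recon, b), p_stack)
    r2_err <- c(r2_err, row_norms(est - p_ex))
    r2_err_z <- c(r2_err_z, abs(est[, 3] - p_ex[, 3]))
  }
  ## ---- R3 TRE: ex vivo landmarks through the feature chain --------------
  set.seed(landmark_seed + 200)
  sel <- which(g$values > 0)
  p_ex <- pts[sample(sel, nlm * nb), , drop = FALSE]
  p_in <- apply_chain(invert_chain(sim$excision$chain), p_ex)
  est <- apply_chain(fit$r3$chain, p_ex)
  r3_err <- row_norms(est - p_in)
  ## ---- composed chain on histology landmarks ----------------------------
  comp_err <- c()
  for (b in seq_len(nb)) {
    hsec <- sim$sections[[b]]$histology
    s_mid <- usable_mid(b)
    if (is.na(s_mid)) next
    sec <- hsec[[s_mid]]
    lm_hist <- section_landmarks(sec, nlm, landmark_seed + 300 + b)
    if (is.null(lm_hist)) next
    p3 <- cbind(lm_hist, sec$depth)
    truth <- apply_chain(phantom_ground_truth_chain(sim, b, s_mid), p3)
    est <- apply_chain(fit$section_chains[[b]][[s_mid]], p3)
    comp_err <- c(comp_err, row_norms(est - truth))
  }
  stage_tre <- data.frame(
    stage = c("R1", "R2", "R3"),
    mean_mm = c(mean(r1_err), mean(r2_err), mean(r3_err)),
    sd_mm = c(stats::sd(r1_err), stats::sd(r2_err), stats::sd(r3_err)),
    n = c(length(r1_err), length(r2_err), length(r3_err)))
  out <- list(stage_tre = stage_tre,
              cumulative_mm = cumulative_error(stage_tre$mean_mm),
              composed_tre = list(mean = mean(comp_err),
                                  sd = stats::sd(comp_err), n = length(comp_err)),
              r2_z_error_mm = mean(r2_err_z))
  if (histology_volume) {
    secs <- list()
    for (b in seq_len(nb)) {
      hsec <- sim$sections[[b]]$histology
      for (s in seq_along(hsec)) {
        if (is.null(fit$r1[[b]][[s]])) next
        secs[[length(secs) + 1]] <- list(label = hsec[[s]]$necrosis_seg,
                                         chain2d = fit$r1[[b]][[s]]$chain,
                                         group = b,
                                         depth = hsec[[s]]$depth)
      }
    }
    g0 <- sim$phantom$class_volume
    vx <- volume_grid_points(g0)
    occ <- which(sim$phantom$tissue_label$values > 0)
    lo <- apply(vx[occ, , drop = FALSE], 2, min) - 2
    hi <- apply(vx[occ, , drop = FALSE], 2, max) + 2
    roi <- vx[, 1] >= lo[1] & vx[, 1] <= hi[1] & vx[, 2] >= lo[2] &
      vx[, 2] <= hi[2] & vx[, 3] >= lo[3] & vx[, 3] <= hi[3]
    vol <- build_histology_volume(secs, g0, group_chains = fit$group_chains,
                                  roi = roi,
                                  max_gap = spec$section_spacing_um / 1000 * 1.6)
    met <- precision_recall_dice(vol, sim$phantom$necrosis_label)
    met$hausdorff_mm <- hausdorff_distance(vol, sim$phantom$necrosis_label)
    out$volume <- list(label = vol, metrics = met,
                       volume_mm3 = sum(vol$values) * voxel_volume(vol),
                       truth_mm3 = sum(sim$phantom$necrosis_label$values) *
                         voxel_volume(sim$phantom$necrosis_label))
  }
  out
}

#' Run the complete simulate-and-restore workflow from a configuration
#'
#' Drives phantom generation, the destructive simulation, the three
#' restoring registration stages, volumetric label construction and
#' evaluation from a single configuration (a YAML file path or an
#' equivalent nested list), writing evaluation tables, transforms and
#' volumes to an output directory.  One global seed governs every
#' stochastic element, so reruns with the same configuration reproduce all
#' numeric outputs.
#'
#' @param config path to a YAML file or a list with optional blocks
#'   `phantom` (arguments of [phantom_spec()]), `pipeline` (`mode`,
#'   `histology_volume`), and `output` (`dir`, `write_volumes`).
#' @param output_dir overrides `config$output$dir`.
#' @return (invisibly) list with `sim`, `fit`, `evaluation`, `dir`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config))
    stop_historeg("config must be a YAML path or a list", "historeg_config_error")
  known <- c("phantom", "pipeline", "output")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop_historeg(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
                  "historeg_config_error")
  ph_args <- config$phantom %||% list()
  bad <- setdiff(names(ph_args), names(formals(phantom_spec)))
  if (length(bad))
    stop_historeg(paste0("unknown phantom keys: ", paste(bad, collapse = ", ")),
                  "historeg_config_error")
  spec <- do.call(phantom_spec, ph_args)
  pl <- config$pipeline %||% list()
  params <- pipeline_params(mode = pl$mode %||% "full3d")
  dir <- output_dir %||% config$output$dir %||% "historeg_results"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(dir, "run.log")
  logline <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                       sprintf(...)), file = logf, append = TRUE)
  logline("run start, seed %d, mode %s", spec$seed, params$mode)
  sim <- simulate_destructive_pipeline(spec)
  logline("phantom simulated: %d blocks", sim$slicing$n_blocks)
  fit <- restore_pipeline(sim, params, progress = FALSE)
  logline("restoration done in %.1f s", fit$elapsed_s)
  ev <- evaluate_restoration(sim, fit,
                             histology_volume = pl$histology_volume %||% TRUE)
  logline("evaluation done; cumulative TRE %.3f mm", ev$cumulative_mm)
  ## Fig-4-style stage TRE table and Table-1-style label metrics
  utils::write.csv(ev$stage_tre, file.path(dir, "stage_tre.csv"),
                   row.names = FALSE)
  if (!is.null(ev$volume)) {
    met <- ev$volume$metrics
    utils::write.csv(data.frame(
      label = "histology_necrosis_reconstruction",
      volume_mm3 = ev$volume$volume_mm3,
      reference_mm3 = ev$volume$truth_mm3,
      precision = met$precision, recall = met$recall, dice = met$dice,
      hausdorff_mm = met$hausdorff_mm),
      file.path(dir, "label_metrics.csv"), row.names = FALSE)
    if (isTRUE(config$output$write_volumes %||% TRUE))
      write_volume(ev$volume$label, file.path(dir, "histology_volume.nii"))
  }
  jsonlite::write_json(list(
    seed = spec$seed, mode = params$mode, elapsed_s = fit$elapsed_s,
    stage_tre_mm = stats::setNames(ev$stage_tre$mean_mm, ev$stage_tre$stage),
    cumulative_mm = ev$cumulative_mm,
    composed_tre_mm = ev$composed_tre$mean),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  logline("outputs written to %s", dir)
  invisible(list(sim = sim, fit = fit, evaluation = ev, dir = dir))
}
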