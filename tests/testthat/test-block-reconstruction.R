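test_that("lighting difference isolates surface tissue", {
  a <- image2d(matrix(5, 6, 6), c(1, 1), c(0, 0))
  expect_true(all(lighting_difference(a, a)$values == 0))
  b <- image2d(matrix(2, 6, 6), c(1, 1), c(0, 0))
  expect_true(all(lighting_difference(a, b)$values == 3))
  off <- image2d(matrix(5, 6, 6), c(1, 1), c(1, 0))
  expect_error(lighting_difference(a, off), class = "historeg_geometry_error")
  ## phantom show-through: difference recovers the exposed-surface signal
  spec <- small_phantom_spec(seed = 11, camera_jitter_px = 0)
  sim <- simulate_destructive_pipeline(spec)
  bf <- sim$sections[[2]]$blockface[[4]]
  ld <- lighting_difference(bf$parallel, bf$perpendicular)
  tis <- bf$clean_seg$values > 0.5
  ## exposed tissue is bright; outside only the faint paraffin rim remains
  expect_gt(mean(ld$values[tis]), 80)
  expect_lt(mean(ld$values[!tis]), 45)
  expect_gt(mean(ld$values[tis]) - mean(ld$values[!tis]), 60)
})

test_that("blockface stack alignment recovers camera jitter", {
  ## pure jitter, constant content: the clean known-jitter experiment
  spec <- small_phantom_spec(seed = 12, section_distortion_magnitude = 0)
  sim <- simulate_destructive_pipeline(spec)
  base <- lighting_difference(sim$sections[[2]]$blockface[[6]]$parallel,
                              sim$sections[[2]]$blockface[[6]]$perpendicular)
  set.seed(1)
  jit_px <- cbind(sample(-2:2, 9, TRUE), sample(-2:2, 9, TRUE))
  jit_px[1, ] <- 0
  sp <- base$spacing
  imgs <- lapply(1:9, function(i) {
    xy <- historeg:::image2d_grid_points(base)
    shifted <- matrix(sample_image2d(base, sweep(xy, 2, jit_px[i, ] * sp, "+")),
                      nrow(base$values), ncol(base$values))
    image2d(shifted, sp, base$origin, (i - 1) * 0.05)
  })
  st <- align_blockface_stack(imgs, content_threshold = 60)
  for (i in 2:9) {
    truth <- -(jit_px[i, ] - jit_px[1, ]) * sp
    expect_lt(max(abs(st$affines[[i]]$translation - truth)), 0.1)  # 0.2 px
  }
  ## phantom series: depth-varying content adds morph-induced error, which
  ## stays well below the pixel scale of the simulated jitter
  sec <- sim$sections[[2]]
  imgs2 <- lapply(sec$blockface, function(bf)
    lighting_difference(bf$parallel, bf$perpendicular))
  st2 <- align_blockface_stack(imgs2, content_threshold = 60)
  jit <- t(vapply(sec$blockface, `[[`, numeric(2), "jitter_px")) *
    spec$section_inplane_spacing
  a0 <- st2$anchor   # stack frame anchors to the first content image
  for (i in seq(a0 + 1, length(imgs2), by = 3)) {
    truth <- -(jit[i, ] - jit[a0, ])
    expect_lt(max(abs(st2$affines[[i]]$translation - truth)), 0.6)
  }
  ## volume geometry: blockface increment as slice spacing
  expect_equal(st2$volume$spacing[3], spec$blockface_spacing_um / 1000)
  ## alignment of image k is independent of later images
  st_partial <- align_blockface_stack(imgs2[1:10], content_threshold = 60)
  for (i in 1:10)
    expect_equal(st_partial$affines[[i]]$translation,
                 st2$affines[[i]]$translation)
  expect_error(align_blockface_stack(list()), class = "historeg_empty_error")
})

test_that("sections match their nearest blockface image with shallow ties", {
  stack <- list(depths = seq(0, 1, by = 0.05))
  expect_equal(match_section_to_blockface(0.25, stack), 6)
  expect_equal(match_section_to_blockface(0.275, stack), 6)  # tie -> shallower
  expect_equal(match_section_to_blockface(0.26, stack), 6)   # nearest is 0.25
  expect_error(match_section_to_blockface(2, stack),
               class = "historeg_range_error")
})

test_that("histology-to-blockface registration inverts a known 2D distortion", {
  spec <- small_phantom_spec(seed = 13, camera_jitter_px = 0)
  sim <- simulate_destructive_pipeline(spec)
  sec <- sim$sections[[2]]$histology
  s <- ceiling(length(sec) / 2)
  h <- sec[[s]]
  bf <- sim$sections[[2]]$blockface[[
    match_section_to_blockface(h$depth, list(depths = vapply(
      sim$sections[[2]]$blockface, `[[`, numeric(1), "depth")))]]
  reg <- register_histology_to_blockface(
    h$tissue_seg, bf$clean_seg,
    image_reg_params(pyramid_levels = c(2, 1), max_iters = 60))
  expect_gte(reg$dice_after, reg$dice_before)
  expect_gt(reg$dice_after, 0.98)
  ## the chain composed with the ground-truth distortion is near identity
  ## for boundary-observable components: check on tissue-interior points,
  ## tolerance of the order of the distortion magnitude
  pts <- section_landmarks_test(h, 5)
  truth <- apply_diffeomorphism(h$distortion, pts, inverse = TRUE)
  est <- apply_chain(reg$chain, pts)
  expect_lt(mean(row_norms_test(est - truth)), spec$section_distortion_magnitude)
  expect_error(register_histology_to_blockface(
    image2d(matrix(0, 8, 8), c(1, 1), c(0, 0)), bf$clean_seg),
    class = "historeg_empty_error")
})

test_that("zero-deformation blocks reconstruct to near-identity chains", {
  spec <- small_phantom_spec(seed = 14, excision_magnitude = 0,
                             excision_rigid_deg = 0, excision_rigid_mm = 0,
                             block_magnitude = 0, camera_jitter_px = 0)
  ph <- generate_phantom(spec)
  ex <- simulate_excision(ph, spec)
  sl <- simulate_gross_slicing(ex, spec)
  built <- phantom_block_sets(sl, ex, decimate_cell = 1.8)
  rec <- reconstruct_blocks(built$bss, built$ex_surface,
                            params_face = currents_params(sigma = 1,
                                                          sigma_schedule = 1,
                                                          max_iters = 25),
                            params_exterior = currents_params(
                              sigma = 2, sigma_schedule = 2,
                              velocity_kernel_scale = 1, max_iters = 25))
  expect_true(rec$center > 1 && rec$center < sl$n_blocks)
  g <- ex$class_volume
  pts <- volume_grid_points(g)
  errs <- c()
  for (b in seq_len(sl$n_blocks)) {
    zr <- sl$blocks[[b]]$z_range
    sel <- which(g$values > 0 & pts[, 3] >= zr[1] + 0.4 & pts[, 3] < zr[2] - 0.4)
    if (length(sel) < 4) next
    p <- pts[sample(sel, 4), , drop = FALSE]
    errs <- c(errs, row_norms_test(
      apply_chain(block_to_exvivo_chain(rec, b), p) - p))
  }
  ## residuals at the 1.8 mm registration decimation are of the order of
  ## the clustering cell
  expect_lt(mean(errs), 1.8)
  ## dissimilarity of the joined exterior strictly decreased
  expect_lt(rec$energies$exterior_after, rec$energies$exterior_before)
  expect_error(reconstruct_blocks(list(), built$ex_surface),
               class = "historeg_empty_error")
})

test_that("reconstruction error grows with simulated block deformation", {
  errs_by_mag <- vapply(c(0.2, 0.8, 1.6), function(mag) {
    spec <- small_phantom_spec(seed = 15, block_magnitude = mag,
                               excision_magnitude = 0, excision_rigid_deg = 0,
                               excision_rigid_mm = 0, camera_jitter_px = 0)
    ph <- generate_phantom(spec)
    ex <- simulate_excision(ph, spec)
    sl <- simulate_gross_slicing(ex, spec)
    built <- phantom_block_sets(sl, ex, decimate_cell = 1.8)
    rec <- reconstruct_blocks(built$bss, built$ex_surface,
                              params_face = currents_params(sigma = 1,
                                                            sigma_schedule = 1,
                                                            max_iters = 20),
                              params_exterior = currents_params(
                                sigma = 2, sigma_schedule = 2,
                                velocity_kernel_scale = 1, max_iters = 20))
    g <- ex$class_volume
    pts <- volume_grid_points(g)
    errs <- c()
    set.seed(1)
    for (b in seq_len(sl$n_blocks)) {
      zr <- sl$blocks[[b]]$z_range
      sel <- which(g$values > 0 & pts[, 3] >= zr[1] + 0.4 & pts[, 3] < zr[2] - 0.4)
      if (length(sel) < 4) next
      p_ex <- pts[sample(sel, 4), , drop = FALSE]
      p_blk <- apply_chain(sl$blocks[[b]]$chain, p_ex)
      errs <- c(errs, row_norms_test(
        apply_chain(block_to_exvivo_chain(rec, b), p_blk) - p_ex))
    }
    mean(errs)
  }, numeric(1))
  ## monotone in the deformation magnitude (weakly, across 3 magnitudes)
  expect_lt(errs_by_mag[1], errs_by_mag[3])
})
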