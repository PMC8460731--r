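test_that("phantom generation is deterministic with sound geometry", {
  spec <- small_phantom_spec(seed = 5)
  ph1 <- generate_phantom(spec)
  ph2 <- generate_phantom(spec)
  expect_identical(ph1$class_volume$values, ph2$class_volume$values)
  expect_identical(ph1$landmarks$points, ph2$landmarks$points)
  ## necrosis volume close to the analytic ellipsoid volume (default-size
  ## lesion; a smaller one has proportionally larger voxelization error)
  spec_d <- phantom_spec(seed = 5)
  ph_d <- generate_phantom(spec_d)
  vol <- sum(ph_d$necrosis_label$values) * voxel_volume(ph_d$necrosis_label)
  expect_lt(abs(vol / (4 / 3 * pi * prod(spec_d$necrosis_radii)) - 1), 0.1)
  ## necrosis strictly inside tissue; landmarks inside tissue
  expect_true(all(ph1$tissue_label$values[ph1$necrosis_label$values > 0] == 1))
  lm_in <- sample_volume(ph1$tissue_label, ph1$landmarks$points,
                         interpolation = "nearest")
  expect_true(all(lm_in == 1))
  ## an impossible lesion is rejected
  expect_error(generate_phantom(phantom_spec(necrosis_radii = c(20, 20, 20))),
               class = "historeg_geometry_error")
})

test_that("excision applies a bounded, invertible ground-truth deformation", {
  spec <- small_phantom_spec(seed = 6)
  ph <- generate_phantom(spec)
  ex <- simulate_excision(ph, spec)
  disp <- apply_chain(ex$chain, ph$landmarks$points) - ph$landmarks$points
  bound <- spec$excision_magnitude + spec$excision_rigid_mm * sqrt(3) +
    2 * sin(spec$excision_rigid_deg * pi / 180 / 2) * 20
  expect_true(all(row_norms_test(disp) <= bound))
  ## ground-truth flow passes the diffeomorphism checks
  phi <- ex$chain$elements[[1]]$transform
  chk <- check_diffeomorphism(phi, n = 5)
  expect_true(chk$ok)
  ## zero magnitude with zero rigid part is the identity
  spec0 <- small_phantom_spec(seed = 6, excision_magnitude = 0,
                              excision_rigid_deg = 0, excision_rigid_mm = 0)
  ex0 <- simulate_excision(generate_phantom(spec0), spec0)
  p <- matrix(runif(30, 4, 18), 10, 3)
  expect_lt(max(abs(apply_chain(ex0$chain, p) - p)), 1e-12)
})

test_that("gross slicing counts blocks and partitions the tissue", {
  spec <- small_phantom_spec(seed = 7, excision_magnitude = 0,
                             excision_rigid_deg = 0, excision_rigid_mm = 0,
                             block_magnitude = 0)
  ph <- generate_phantom(spec)
  ex <- simulate_excision(ph, spec)
  sl <- simulate_gross_slicing(ex, spec)
  zext <- diff(range(which(apply(ex$class_volume$values > 0, 3, any)))) + 1
  nb_expect <- ceiling(zext / spec$block_thickness)
  if (nb_expect >= 2 &&
      (zext - (nb_expect - 1) * spec$block_thickness) < spec$block_thickness / 3)
    nb_expect <- nb_expect - 1
  expect_equal(sl$n_blocks, nb_expect)
  ## zero per-block deformation: blocks re-stack to the ex vivo tissue
  total <- 0
  for (blk in sl$blocks) total <- total + sum(blk$class_volume$values > 0) *
    voxel_volume(blk$class_volume)
  ex_total <- sum(ex$class_volume$values > 0) * voxel_volume(ex$class_volume)
  expect_lt(abs(total / ex_total - 1), 0.05)
  expect_error(simulate_gross_slicing(ex, small_phantom_spec(block_thickness = 50)),
               class = "historeg_slicing_error")
})

test_that("sectioning produces the stated image counts and depths", {
  spec <- phantom_spec(seed = 8)   # 3 mm blocks, 50 um / 250 um
  ph <- generate_phantom(spec)
  ex <- simulate_excision(ph, spec)
  sl <- simulate_gross_slicing(ex, spec)
  b <- sl$blocks[[2]]              # interior block, full thickness
  sec <- simulate_sectioning(b, spec)
  expect_equal(length(sec$blockface), 60)   # 3000 um / 50 um
  expect_equal(length(sec$histology), 12)   # 3000 um / 250 um
  depths <- vapply(sec$histology, `[[`, numeric(1), "depth")
  expect_true(all(abs((depths - depths[1]) %% 0.25) < 1e-9))
  ## zero distortion: histology equals the matching blockface tissue map
  spec0 <- phantom_spec(seed = 8, section_distortion_magnitude = 0,
                        camera_jitter_px = 0)
  sec0 <- simulate_sectioning(sl$blocks[[2]], spec0)
  h <- sec0$histology[[5]]
  bf <- sec0$blockface[[historeg:::match_section_to_blockface(
    h$depth, list(depths = vapply(sec0$blockface, `[[`, numeric(1), "depth")))]]
  expect_equal(h$tissue_seg$values, bf$clean_seg$values)
  thin <- b; thin$z_range <- c(0, 0.1)
  expect_error(simulate_sectioning(thin, spec),
               class = "historeg_sectioning_error")
})

test_that("the ground-truth chain maps histology landmarks to their ancestors", {
  spec <- small_phantom_spec(seed = 9)
  sim <- simulate_destructive_pipeline(spec)
  for (b in c(1, sim$slicing$n_blocks)) {
    hs <- sim$sections[[b]]$histology
    s <- ceiling(length(hs) / 2)
    gt <- phantom_ground_truth_chain(sim, b, s)
    u <- cbind(runif(4, 8, 14), runif(4, 8, 14), hs[[s]]$depth)
    ## manual sequential application of the stored stage inverses
    v <- apply_diffeomorphism(hs[[s]]$distortion, u[, 1:2], inverse = TRUE)
    w <- apply_chain(invert_chain(sim$slicing$blocks[[b]]$chain), cbind(v, u[, 3]))
    x <- apply_chain(invert_chain(sim$excision$chain), w)
    expect_lt(max(abs(apply_chain(gt, u) - x)), 1e-6)
  }
})

test_that("rendered modalities differ in contrast but share geometry", {
  spec <- small_phantom_spec(seed = 10)
  ph <- generate_phantom(spec)
  mr <- render_phantom_volume(ph$class_volume, "mr_invivo", spec)
  bf <- render_phantom_volume(ph$class_volume, "blockface", spec)
  expect_identical(dim(mr$values), dim(bf$values))
  inside <- ph$class_volume$values == 1
  expect_gt(abs(mean(mr$values[inside]) - mean(bf$values[inside])), 20)
})
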