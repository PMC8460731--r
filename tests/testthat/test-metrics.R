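test_that("target registration error pairs by label with exact distances", {
  p <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)
  a <- landmark_set(p, c("L1", "L2"))
  expect_equal(target_registration_error(a, a)$distances,
               c(L1 = 0, L2 = 0))
  off <- landmark_set(sweep(p, 2, c(1, 0, 0), "+"), c("L1", "L2"))
  tre <- target_registration_error(off, a)
  expect_equal(unname(tre$mean), 1); expect_equal(unname(tre$sd), 0)
  pyth <- landmark_set(p + rbind(c(3, 4, 0), c(0, 0, 5)), c("L1", "L2"))
  expect_equal(unname(target_registration_error(pyth, a)$distances), c(5, 5))
  ## label pairing, not order
  shuffled <- landmark_set(p[2:1, ], c("L2", "L1"))
  expect_equal(unname(target_registration_error(shuffled, a)$mean), 0)
  expect_error(target_registration_error(
    landmark_set(p, c("A", "B")), a), class = "historeg_correspondence_error")
})

test_that("TRE is invariant under a common rigid motion", {
  set.seed(1)
  a <- landmark_set(matrix(rnorm(15), 5, 3))
  b <- landmark_set(a$points + matrix(rnorm(15, sd = 0.3), 5, 3), a$labels)
  R <- affine_transform(rot3(c(1, 2, 3), 0.7), c(4, -2, 9))
  expect_equal(target_registration_error(transform_landmarks(a, R),
                                         transform_landmarks(b, R))$mean,
               target_registration_error(a, b)$mean, tolerance = 1e-9)
})

test_that("cumulative error is the sum of stage means", {
  expect_equal(cumulative_error(c(0.117, 0.24, 0.64)), 0.997)
  expect_equal(cumulative_error(0.5), 0.5)
  expect_equal(cumulative_error(c(0, 0, 0)), 0)
})

test_that("precision, recall and Dice count voxels correctly", {
  mk <- function(v) label_volume(array(v, c(3, 2, 1)))
  a <- mk(c(1, 1, 1, 1, 0, 0))            # TP 3, FP 1 against b
  b <- mk(c(1, 1, 1, 0, 1, 1))            # FN 2
  m <- precision_recall_dice(a, b)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$dice, 2 * 3 / (2 * 3 + 1 + 2))
  same <- precision_recall_dice(b, b)
  expect_equal(unlist(same), c(precision = 1, recall = 1, dice = 1))
  disj <- precision_recall_dice(mk(c(1, 0, 0, 0, 0, 0)), mk(c(0, 1, 0, 0, 0, 0)))
  expect_equal(unlist(disj), c(precision = 0, recall = 0, dice = 0))
  expect_error(precision_recall_dice(a, mk(rep(0, 6))),
               class = "historeg_empty_error")
})

test_that("Dice is symmetric and precision/recall swap with arguments", {
  set.seed(2)
  mk <- function() label_volume(array(rbinom(60, 1, 0.5), c(5, 4, 3)))
  a <- mk(); b <- mk()
  expect_equal(precision_recall_dice(a, b)$dice, precision_recall_dice(b, a)$dice)
  expect_equal(precision_recall_dice(a, b)$precision,
               precision_recall_dice(b, a)$recall)
})

test_that("Hausdorff distance is spacing-aware and symmetric", {
  z <- array(0, c(11, 5, 5))
  a <- z; a[3, 3, 3] <- 1
  b <- z; b[8, 3, 3] <- 1
  la <- label_volume(a, spacing = c(1, 1, 1))
  lb <- label_volume(b, spacing = c(1, 1, 1))
  expect_equal(hausdorff_distance(la, lb), 5)
  expect_equal(hausdorff_distance(lb, la), 5)
  expect_equal(hausdorff_distance(la, la), 0)
  ## nested balls radius 5 and 8 mm: boundary distance 3 within half a voxel
  n <- 21
  g <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  r2 <- rowSums((g - 10)^2)
  small <- label_volume(array(as.numeric(r2 < 25), rep(n, 3)))
  big <- label_volume(array(as.numeric(r2 < 64), rep(n, 3)))
  expect_lt(abs(hausdorff_distance(small, big) - 3), 0.75)
  expect_error(hausdorff_distance(small, label_volume(array(0, rep(n, 3)))),
               class = "historeg_empty_error")
})

test_that("Hausdorff satisfies a triangle-type bound on random labels", {
  set.seed(3)
  mk <- function() {
    v <- array(0, c(8, 8, 8))
    v[sample(512, 25)] <- 1
    label_volume(v)
  }
  for (i in 1:5) {
    a <- mk(); b <- mk(); cc <- mk()
    expect_lte(hausdorff_distance(a, cc),
               hausdorff_distance(a, b) + hausdorff_distance(b, cc) + 1e-9)
  }
})

test_that("two-sample tests match stats::t.test and a permutation oracle", {
  set.seed(4)
  a <- rnorm(12, 1); b <- rnorm(15, 0.2)
  res <- two_sample_test(a, b, "independent")
  ## permutation approximation of the two-sided p-value
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  perm <- replicate(20000, {
    s <- sample(length(pool))
    abs(mean(pool[s[1:12]]) - mean(pool[s[-(1:12)]]))
  })
  expect_lt(abs(res$p - mean(perm >= obs)), 0.02)
  ## scale invariance of t
  res2 <- two_sample_test(2 * a, 2 * b, "independent")
  expect_equal(res$t, res2$t, tolerance = 1e-12)
  ## degenerate paired case
  same <- two_sample_test(a, a, "related")
  expect_equal(same$t, 0)
  expect_error(two_sample_test(1, c(1, 2), "independent"),
               class = "historeg_sample_error")
  expect_error(two_sample_test(c(1, 2, 3), c(1, 2), "related"),
               class = "historeg_sample_error")
})
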