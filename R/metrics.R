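#' Target registration error between matched landmark sets
#'
#' Euclidean distance between deformed and target landmarks, paired by
#' label.  The summary (mean, sd) is the per-stage accuracy figure used
#' throughout pipeline evaluation.
#'
#' @param deformed,target [landmark_set] objects with matching labels.
#' @return list with `distances` (named per-landmark mm), `mean`, `sd`.
#' @export
target_registration_error <- function(deformed, target) {
  if (!setequal(deformed$labels, target$labels))
    stop_historeg("landmark labels do not correspond", "historeg_correspondence_error")
  ord <- match(target$labels, deformed$labels)
  d <- row_norms(deformed$points[ord, , drop = FALSE] - target$points)
  names(d) <- target$labels
  list(distances = d, mean = mean(d), sd = stats::sd(d))
}

#' Cumulative registration error
#'
#' The upper bound on total pipeline error, estimated as the arithmetic sum
#' of per-stage mean errors.
#'
#' @param stage_means numeric vector of stage mean TREs, mm.
#' @return scalar mm.
#' @export
cumulative_error <- function(stage_means) {
  if (length(stage_means) < 1)
    stop_historeg("need at least one stage", "historeg_empty_error")
  sum(stage_means)
}

check_same_grid <- function(a, b) {
  if (!all(dim(a$values) == dim(b$values)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9)
    stop_historeg("label volumes are not on the same grid", "historeg_geometry_error")
}

#' Voxel overlap metrics between a test and a reference label
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and Dice
#' `2TP/(2TP+FP+FN)` over voxels of a shared grid.
#'
#' @param test,reference [label_volume] objects on the same grid.
#' @return list with `precision`, `recall`, `dice` in `[0, 1]`.
#' @export
precision_recall_dice <- function(test, reference) {
  check_same_grid(test, reference)
  a <- test$values > 0.5; b <- reference$values > 0.5
  if (!any(b)) stop_historeg("empty reference label: recall undefined", "historeg_empty_error")
  if (!any(a)) stop_historeg("empty test label: precision undefined", "historeg_empty_error")
  tp <- sum(a & b); fp <- sum(a & !b); fn <- sum(!a & b)
  list(precision = tp / (tp + fp), recall = tp / (tp + fn),
       dice = 2 * tp / (2 * tp + fp + fn))
}

## Boundary voxels of a binary mask: set voxels with a 6-neighbourhood
## non-set neighbour (volume edge counts as outside).
boundary_voxels <- function(mask) {
  dm <- dim(mask)
  shift <- function(a, ax, by) {
    n <- dm[ax]
    idx <- seq_len(n) + by
    pad <- idx < 1 | idx > n
    idx[pad] <- 1
    out <- index_axis(a, ax, idx)
    if (any(pad)) {
      args <- rep(list(quote(expr = )), 3); args[[ax]] <- which(pad)
      out <- do.call(`[<-`, c(list(out), args, list(value = FALSE)))
    }
    out
  }
  m <- mask > 0.5
  nb <- shift(m, 1, 1) & shift(m, 1, -1) & shift(m, 2, 1) & shift(m, 2, -1) &
    shift(m, 3, 1) & shift(m, 3, -1)
  m & !nb
}

#' Hausdorff distance between two labels
#'
#' Symmetric maximum of directed boundary-to-boundary distances, computed
#' on boundary voxel centres in world millimetres (spacing-aware).
#'
#' @param a,b non-empty [label_volume] objects in a common world frame.
#' @return scalar mm.
#' @export
hausdorff_distance <- function(a, b) {
  if (!any(a$values > 0.5) || !any(b$values > 0.5))
    stop_historeg("empty label volume", "historeg_empty_error")
  pts <- function(v) {
    idx <- which(boundary_voxels(v$values), arr.ind = TRUE) - 1
    voxel_to_world(v, idx)
  }
  pa <- pts(a); pb <- pts(b)
  ## block-wise directed distances to bound memory on large boundaries
  directed <- function(x, y) {
    worst <- 0
    bs <- max(1L, floor(2e6 / nrow(y)))
    for (s in seq(1, nrow(x), by = bs)) {
      blk <- x[s:min(s + bs - 1, nrow(x)), , drop = FALSE]
      dmin <- sqrt(pmax(apply(cross_dist_sq(blk, y), 1, min), 0))
      worst <- max(worst, max(dmin))
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

#' Two-sample t-test (independent or related)
#'
#' Equal-variance independent design or paired design; returns the t
#' statistic and the two-sided p-value.  Biomarker metrics across subjects
#' are compared with the independent design; per-landmark errors of two
#' registration variants with the related design.
#'
#' @param a,b numeric samples (equal lengths required for `related`).
#' @param design `"independent"` or `"related"`.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_test <- function(a, b, design = c("independent", "related")) {
  design <- match.arg(design)
  if (length(a) < 2 || length(b) < 2)
    stop_historeg("each sample needs at least 2 observations", "historeg_sample_error")
  if (design == "related" && length(a) != length(b))
    stop_historeg("related design requires equal sample sizes", "historeg_sample_error")
  if (design == "related" && stats::sd(a - b) == 0) {
    ## degenerate paired case (identical differences): t is 0 or unbounded
    m <- mean(a - b)
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0, df = length(a) - 1))
  }
  ht <- if (design == "independent")
    stats::t.test(a, b, var.equal = TRUE)
  else stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}
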