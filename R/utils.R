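#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_historeg <- function(msg, class) {
  stop(structure(class = c(class, "historeg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

as_point_matrix <- function(pts, d = NULL) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (!is.null(d) && ncol(pts) != d)
    stop_historeg(sprintf("expected %d-column point matrix, got %d columns", d, ncol(pts)),
                  "historeg_geometry_error")
  pts
}

## Row-wise Euclidean norms.
row_norms <- function(m) sqrt(rowSums(m * m))

## Squared Euclidean distance matrix between rows of a and rows of b.
cross_dist_sq <- function(a, b) {
  aa <- rowSums(a * a)
  bb <- rowSums(b * b)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## Deterministic sub-seed derivation: one global seed governs all stages.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}
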