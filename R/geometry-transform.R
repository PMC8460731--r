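#' Affine spatial transform
#'
#' Acts on world points as `x -> linear %*% x + translation`.  Dimension (2
#' or 3) is taken from `linear`.  2D affines may be applied to 3-column
#' point sets, in which case they act in-plane and leave the third
#' coordinate untouched (a histology-section transform embedded in 3D).
#'
#' @param linear d x d matrix with non-zero determinant.
#' @param translation length-d vector, mm.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(3), translation = NULL) {
  linear <- as.matrix(linear)
  d <- nrow(linear)
  if (ncol(linear) != d || !(d %in% c(2, 3)))
    stop_historeg("linear must be a 2x2 or 3x3 matrix", "historeg_parameter_error")
  if (abs(det(linear)) < 1e-12)
    stop_historeg("affine linear part must be invertible", "historeg_parameter_error")
  translation <- as.double(translation %||% rep(0, d))
  if (length(translation) != d)
    stop_historeg("translation length must match linear dimension", "historeg_parameter_error")
  structure(list(linear = linear, translation = translation, dim = d),
            class = "affine_transform")
}

#' @rdname affine_transform
#' @param shift length-d translation vector for a pure translation.
#' @export
translation_transform <- function(shift) {
  shift <- as.double(shift)
  affine_transform(diag(length(shift)), shift)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform %dD, |det| = %.4g, t = (%s) mm>\n", x$dim,
              abs(det(x$linear)), paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

invert_affine <- function(a) {
  li <- solve(a$linear)
  affine_transform(li, -as.vector(li %*% a$translation))
}

## Compose two affines: (a2 o a1)(x) = a2(a1(x)).  Same dimension required.
compose_affine <- function(a2, a1) {
  affine_transform(a2$linear %*% a1$linear,
                   as.vector(a2$linear %*% a1$translation) + a2$translation)
}

#' Diffeomorphism as an integrated velocity flow
#'
#' A smooth invertible map represented by a time-indexed sequence of smooth
#' velocity fields integrated with explicit Euler steps.  The forward map
#' applies the step maps `x -> x + dt * v_k(x)` for `k = 1..T`; the inverse
#' applies them in reverse order with negated velocity, refined by a short
#' fixed-point iteration, so that `phi(phi^-1(x)) = x` holds to a small
#' tolerance everywhere the flow is resolved.
#'
#' Two velocity parameterisations are supported per step:
#' \itemize{
#'   \item `"grid"`: velocity sampled on a regular axis-aligned grid
#'     (components interpolated linearly, zero outside the grid);
#'   \item `"kernel"`: a reproducing-kernel field
#'     `v(x) = drift + sum_i k(x, q_i) alpha_i` with a Cauchy kernel of
#'     scale `sigma` — the form produced by unlabeled point-set matching.
#' }
#'
#' @param steps list of velocity steps (see [grid_velocity_step()] /
#'   [kernel_velocity_step()]).
#' @param domain_bounds 2 x d matrix, rows = (min, max) of the mm box the
#'   flow is defined on (used for validity checks).
#' @param dim spatial dimension, 2 or 3.
#' @param validate if `TRUE`, check positive Jacobian determinants and
#'   inverse consistency on a probe grid at construction.
#' @param tol inverse-consistency tolerance in mm (default 0.1 of the probe
#'   grid spacing is used when `NULL`).
#' @return An object of class `diffeomorphism`.
#' @export
diffeomorphism <- function(steps = list(), domain_bounds, dim = 3,
                           validate = TRUE, tol = NULL) {
  domain_bounds <- as.matrix(domain_bounds)
  if (!all(dim(domain_bounds) == c(2, dim)))
    stop_historeg("domain_bounds must be a 2 x dim matrix", "historeg_parameter_error")
  obj <- structure(list(steps = steps, domain_bounds = domain_bounds, dim = dim),
                   class = "diffeomorphism")
  if (validate && length(steps) > 0) {
    chk <- check_diffeomorphism(obj, tol = tol)
    if (!chk$ok)
      stop_historeg(paste0("diffeomorphism invariants violated: ", chk$why),
                    "historeg_diffeo_error")
  }
  obj
}

#' @export
print.diffeomorphism <- function(x, ...) {
  cat(sprintf("<diffeomorphism %dD, %d flow step(s)>\n", x$dim, length(x$steps)))
  invisible(x)
}

#' @rdname diffeomorphism
#' @param v array of velocity components: dims `(nx, ny, d)` in 2D or
#'   `(nx, ny, nz, d)` in 3D, mm per unit flow time.
#' @param spacing,origin geometry of the velocity grid (mm).
#' @param dt Euler step length in flow time.
#' @export
grid_velocity_step <- function(v, spacing, origin, dt = 1) {
  list(type = "grid", v = v, spacing = as.double(spacing),
       origin = as.double(origin), dt = as.double(dt))
}

#' @rdname diffeomorphism
#' @param q control points, K x d mm.
#' @param alpha K x d momenta (mm velocity at unit kernel weight).
#' @param sigma kernel scale, mm.
#' @param drift constant length-d velocity added to the kernel field.
#' @export
kernel_velocity_step <- function(q, alpha, sigma, drift = NULL, dt = 1) {
  q <- as_point_matrix(q); alpha <- as_point_matrix(alpha, ncol(q))
  list(type = "kernel", q = q, alpha = alpha, sigma = as.double(sigma),
       drift = as.double(drift %||% rep(0, ncol(q))), dt = as.double(dt))
}

## Evaluate one step's velocity field at points (K x d).
eval_step_velocity <- function(step, pts) {
  d <- ncol(pts)
  if (step$type == "grid") {
    idx <- sweep(sweep(pts, 2, step$origin), 2, step$spacing, "/")
    out <- matrix(0, nrow(pts), d)
    for (c in seq_len(d)) {
      comp <- if (d == 2) step$v[, , c] else step$v[, , , c]
      out[, c] <- if (d == 2) interp_grid2(comp, idx, fill = 0)
      else interp_grid3(comp, idx, fill = 0)
    }
    out
  } else if (step$type == "kernel") {
    k <- 1 / (1 + cross_dist_sq(pts, step$q) / step$sigma^2)
    sweep(k %*% step$alpha, 2, step$drift, "+")
  } else stop_historeg("unknown velocity step type", "historeg_parameter_error")
}

#' Apply a diffeomorphism to points
#'
#' @param phi a [diffeomorphism].
#' @param pts K x d world points (mm); 2D flows accept K x 3 points and act
#'   in-plane.
#' @param inverse if `TRUE`, evaluate the inverse map.
#' @return K x d (or K x 3) matrix of mapped points.
#' @export
apply_diffeomorphism <- function(phi, pts, inverse = FALSE) {
  pts <- as_point_matrix(pts)
  extra <- NULL
  if (ncol(pts) == 3 && phi$dim == 2) {  # in-plane action of a section flow
    extra <- pts[, 3, drop = FALSE]
    pts <- pts[, 1:2, drop = FALSE]
  }
  if (ncol(pts) != phi$dim)
    stop_historeg("point dimension does not match diffeomorphism", "historeg_geometry_error")
  x <- pts
  if (!inverse) {
    for (s in phi$steps) x <- x + s$dt * eval_step_velocity(s, x)
  } else {
    for (s in rev(phi$steps)) {
      y <- x
      x <- y - s$dt * eval_step_velocity(s, y)
      for (it in 1:3) x <- y - s$dt * eval_step_velocity(s, x)
    }
  }
  if (!is.null(extra)) x <- cbind(x, extra, deparse.level = 0)
  x
}

## Probe grid over the domain bounds (n nodes per axis).
domain_probe_grid <- function(phi, n = 7) {
  d <- phi$dim
  axes <- lapply(seq_len(d), function(c)
    seq(phi$domain_bounds[1, c], phi$domain_bounds[2, c], length.out = n))
  as.matrix(do.call(expand.grid, axes))
}

#' Check diffeomorphism invariants
#'
#' Verifies (i) the Jacobian determinant of the forward map is positive at
#' every node of a probe grid over the domain, and (ii) round-trip
#' consistency `phi(phi^-1(x)) = x` within `tol` mm.
#'
#' @param phi a [diffeomorphism].
#' @param n probe nodes per axis.
#' @param tol round-trip tolerance, mm; default one tenth of the probe
#'   spacing.
#' @return list with `ok`, `why`, `min_jacobian`, `max_roundtrip_mm`.
#' @export
check_diffeomorphism <- function(phi, n = 7, tol = NULL) {
  g <- domain_probe_grid(phi, n)
  d <- phi$dim
  h <- max((phi$domain_bounds[2, ] - phi$domain_bounds[1, ]) / (n - 1)) * 1e-2
  h <- max(h, 1e-4)
  fwd <- apply_diffeomorphism(phi, g)
  jac_cols <- vector("list", d)
  for (c in seq_len(d)) {
    e <- matrix(0, 1, d); e[c] <- h
    gp <- sweep(g, 2, e, "+"); gm <- sweep(g, 2, e, "-")
    jac_cols[[c]] <- (apply_diffeomorphism(phi, gp) - apply_diffeomorphism(phi, gm)) / (2 * h)
  }
  dets <- if (d == 2) {
    jac_cols[[1]][, 1] * jac_cols[[2]][, 2] - jac_cols[[1]][, 2] * jac_cols[[2]][, 1]
  } else {
    a <- jac_cols[[1]]; b <- jac_cols[[2]]; cc <- jac_cols[[3]]
    a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  }
  rt <- apply_diffeomorphism(phi, apply_diffeomorphism(phi, g, inverse = TRUE))
  err <- max(row_norms(rt - g))
  if (is.null(tol))
    tol <- 0.1 * max((phi$domain_bounds[2, ] - phi$domain_bounds[1, ]) / (n - 1))
  ok <- all(dets > 0) && err <= tol
  why <- if (any(dets <= 0)) sprintf("non-positive Jacobian (min %.3g)", min(dets))
  else if (err > tol) sprintf("round-trip error %.3g mm exceeds %.3g mm", err, tol)
  else ""
  list(ok = ok, why = why, min_jacobian = min(dets), max_roundtrip_mm = err)
}

#' Ordered composition of spatial transforms
#'
#' A transform chain is an ordered list of elements, each an
#' [affine_transform] or [diffeomorphism] tagged with a direction; applying
#' the chain applies each element in sequence.  The empty chain is the
#' identity.
#'
#' @param ... chain elements created with [chain_element()], or
#'   affine/diffeomorphism objects (wrapped as forward elements), or other
#'   `transform_chain`s (spliced).
#' @return An object of class `transform_chain`.
#' @export
transform_chain <- function(...) {
  raw <- list(...)
  elements <- list()
  for (el in raw) {
    if (inherits(el, "transform_chain")) elements <- c(elements, el$elements)
    else if (inherits(el, "chain_element")) elements <- c(elements, list(el))
    else if (inherits(el, c("affine_transform", "diffeomorphism")))
      elements <- c(elements, list(chain_element(el)))
    else stop_historeg("unsupported chain element", "historeg_parameter_error")
  }
  structure(list(elements = elements), class = "transform_chain")
}

#' @rdname transform_chain
#' @param transform an [affine_transform] or [diffeomorphism].
#' @param direction `"forward"` or `"inverse"`.
#' @export
chain_element <- function(transform, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  structure(list(transform = transform, direction = direction),
            class = "chain_element")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain, %d element(s)>\n", length(x$elements)))
  for (el in x$elements)
    cat(sprintf("  %s %s\n", class(el$transform)[1], el$direction))
  invisible(x)
}

#' Apply a transform chain to points
#'
#' Sequential composition: element 1 is applied first.  2D elements act
#' in-plane on 3D points.
#'
#' @param chain a [transform_chain] (or a single transform).
#' @param pts K x 2 or K x 3 matrix of world points, mm.
#' @return matrix of mapped points, same shape as `pts`.
#' @export
apply_chain <- function(chain, pts) {
  pts <- as_point_matrix(pts)
  if (inherits(chain, c("affine_transform", "diffeomorphism")))
    chain <- transform_chain(chain)
  for (el in chain$elements) {
    tr <- el$transform
    inv <- el$direction == "inverse"
    if (inherits(tr, "affine_transform")) {
      a <- if (inv) invert_affine(tr) else tr
      if (a$dim == 2 && ncol(pts) == 3) {
        pts[, 1:2] <- sweep(pts[, 1:2, drop = FALSE] %*% t(a$linear), 2,
                            a$translation, "+")
      } else {
        if (a$dim != ncol(pts))
          stop_historeg("affine dimension does not match points", "historeg_geometry_error")
        pts <- sweep(pts %*% t(a$linear), 2, a$translation, "+")
      }
    } else if (inherits(tr, "diffeomorphism")) {
      pts <- apply_diffeomorphism(tr, pts, inverse = inv)
    } else stop_historeg("unsupported chain element", "historeg_parameter_error")
  }
  pts
}

#' @rdname apply_chain
#' @export
invert_chain <- function(chain) {
  if (inherits(chain, c("affine_transform", "diffeomorphism")))
    chain <- transform_chain(chain)
  flipped <- lapply(rev(chain$elements), function(el)
    chain_element(el$transform,
                  if (el$direction == "forward") "inverse" else "forward"))
  do.call(transform_chain, flipped)
}

#' Named landmark point set
#'
#' 3D landmark coordinates with unique labels and the name of the
#' coordinate space they live in.  Landmarks are used to *evaluate*
#' registration accuracy (target registration error); they never drive a
#' registration.
#'
#' @param points K x 3 matrix, mm.
#' @param labels character vector of K unique identifiers.
#' @param space name of the coordinate space.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, labels = NULL, space = "world") {
  points <- as_point_matrix(points, 3)
  if (nrow(points) < 1) stop_historeg("landmark_set needs at least one point", "historeg_empty_error")
  labels <- as.character(labels %||% sprintf("L%02d", seq_len(nrow(points))))
  if (anyDuplicated(labels) || length(labels) != nrow(points))
    stop_historeg("landmark labels must be unique, one per point", "historeg_parameter_error")
  structure(list(points = points, labels = labels, space = space),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set, %d point(s) in space '%s'>\n", nrow(x$points), x$space))
  invisible(x)
}

#' @rdname landmark_set
#' @param lm a `landmark_set`.
#' @param chain transform (chain) to push the landmarks through.
#' @param space name for the resulting space.
#' @export
transform_landmarks <- function(lm, chain, space = lm$space) {
  landmark_set(apply_chain(chain, lm$points), lm$labels, space)
}
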