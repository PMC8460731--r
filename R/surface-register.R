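#' Parameters for currents-based surface registration
#'
#' @param sigma currents kernel scale, mm.  Defaults: ~1 mm for block
#'   face-to-face matching, ~2 mm (order of the block thickness) for
#'   exterior/ex vivo and ex-vivo/in-vivo stages.
#' @param sigma_schedule coarse-to-fine schedule of currents scales; default
#'   `c(4, 2, 1) * sigma`.
#' @param velocity_kernel_scale scale of the Cauchy kernel generating the
#'   velocity fields, mm; default `2 * sigma`.
#' @param flow_steps nominal number of Euler integration steps for a flow.
#' @param step_size maximum vertex displacement per accepted optimizer step, mm.
#' @param max_iters iteration cap per scale.
#' @param convergence_tol relative energy-change threshold; optimization
#'   stops after 5 consecutive iterations below it.
#' @param smoothness_weight weight of the velocity-field RKHS norm added to
#'   the matching term in the flow objective.
#' @return list of class `currents_params`.
#' @export
currents_params <- function(sigma = 2, sigma_schedule = NULL,
                            velocity_kernel_scale = NULL, flow_steps = 10,
                            step_size = 0.5, max_iters = 150,
                            convergence_tol = 1e-6, smoothness_weight = 1e-3) {
  if (sigma <= 0) stop_historeg("sigma must be positive", "historeg_parameter_error")
  if (flow_steps < 1 || max_iters < 1)
    stop_historeg("flow_steps and max_iters must be >= 1", "historeg_parameter_error")
  structure(list(sigma = sigma,
                 sigma_schedule = sigma_schedule %||% (c(2, 1) * sigma),
                 velocity_kernel_scale = velocity_kernel_scale %||% (2 * sigma),
                 flow_steps = flow_steps, step_size = step_size,
                 max_iters = max_iters, convergence_tol = convergence_tol,
                 smoothness_weight = smoothness_weight),
            class = "currents_params")
}

mesh_cache <- function(mesh) list(centers = face_centers(mesh),
                                  normals = face_normals(mesh))

## Currents energy of moved vertices V against a cached target.
currents_energy_vs_cache <- function(V, faces, cache, sigma) {
  m <- triangle_mesh(V, faces, check_degenerate = FALSE)
  c1 <- face_centers(m); n1 <- face_normals(m)
  currents_terms(c1, n1, cache$centers, cache$normals, sigma)
}

#' Affine surface registration under the currents metric
#'
#' Minimizes the currents dissimilarity between the affinely moved source
#' mesh and the target mesh over the 12 affine parameters, coarse-to-fine
#' over the kernel scale schedule.  Coordinates are centred on the moving
#' mesh centroid so rotation and translation are well scaled, the
#' translation is initialized by aligning vertex centroids, and each scale
#' is solved by quasi-Newton (BFGS) descent with the analytic parameter
#' gradient.  The linear part starts at the identity so that for moderate
#' misalignments the optimization converges to the nearest energy minimum
#' rather than a symmetry-related one.
#'
#' @param moving,target [triangle_mesh] objects.
#' @param params [currents_params].
#' @param constraint `"none"`, or `"z_translation_only"` to restrict motion
#'   along z to a pure translation (third row of the linear part frozen;
#'   rigid rotations restricted to the z axis).
#' @param model `"affine"` (12 parameters) or `"rigid"` (rotation +
#'   translation).  Open, nearly flat surfaces — the cut faces of tissue
#'   blocks — leave whole affine directions unconstrained (any map
#'   preserving the face plane), so block-to-block face matching uses the
#'   rigid model and leaves residual deformation to the flow stage.
#' @return list with `transform` ([affine_transform]), `energy`: a list of
#'   per-scale traces of accepted (improving) evaluations (each
#'   non-increasing), `converged` flag, and final `dissimilarity`.
#' @export
affine_register_surfaces <- function(moving, target, params = currents_params(),
                                     constraint = c("none", "z_translation_only"),
                                     model = c("affine", "rigid")) {
  constraint <- match.arg(constraint)
  model <- match.arg(model)
  check_nonempty_mesh(moving, "moving"); check_nonempty_mesh(target, "target")
  cache <- mesh_cache(target)
  V0 <- moving$vertices; faces <- moving$faces
  mu <- colMeans(V0)
  Vc <- sweep(V0, 2, mu)
  t_init <- colMeans(target$vertices) - mu
  trace_env <- new.env()
  per_scale <- list()
  rodrigues <- function(w) {
    a <- sqrt(sum(w^2))
    if (a < 1e-12) return(diag(3) + skew(w))
    K <- skew(w / a)
    diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  }
  skew <- function(w) matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  zconstr <- constraint == "z_translation_only"
  if (model == "affine") {
    th <- c(as.vector(diag(3)), t_init)
    zmask <- if (zconstr) c(3, 6, 9) else integer(0)   # row M[3, ] frozen
    lin_of <- function(th) matrix(th[1:9], 3, 3)
    tr_of <- function(th) th[10:12]
  } else {
    ## rigid: axis-angle rotation + translation; in z_translation_only mode
    ## only the z-axis rotation component is free (no tilting)
    free_w <- if (zconstr) 3 else 1:3
    th <- c(rep(0, length(free_w)), t_init)
    lin_of <- function(th) {
      w <- numeric(3); w[free_w] <- th[seq_along(free_w)]
      rodrigues(w)
    }
    tr_of <- function(th) th[length(free_w) + 1:3]
    zmask <- integer(0)
  }
  e_cur <- NA_real_
  for (sigma in params$sigma_schedule) {
    fn <- function(th) {
      M <- lin_of(th)
      if (abs(det(M)) < 1e-10) return(1e100)
      e <- currents_energy_vs_cache(
        sweep(Vc %*% t(M), 2, mu + tr_of(th), "+"), faces, cache, sigma)
      if (e < trace_env$best) {
        trace_env$best <- e
        trace_env$energies <- c(trace_env$energies, e)
      }
      e
    }
    trace_env$best <- Inf  # scales change the energy; restart the trace gate
    trace_env$energies <- numeric(0)
    if (model == "affine") {
      gr <- function(th) {
        M <- lin_of(th)
        V <- sweep(Vc %*% t(M), 2, mu + th[10:12], "+")
        g <- currents_dissimilarity_grad(
          triangle_mesh(V, faces, check_degenerate = FALSE),
          target, sigma, target_cache = cache)
        gth <- c(as.vector(crossprod(g, Vc)), colSums(g))
        gth[zmask] <- 0
        gth
      }
      o <- stats::optim(th, fn, gr, method = "BFGS",
                        control = list(maxit = params$max_iters,
                                       reltol = max(params$convergence_tol, 1e-9)))
      th <- o$par
      if (length(zmask)) th[zmask] <- c(0, 0, 1)
      e_cur <- o$value
    } else {
      ## rigid: preconditioned gradient descent with backtracking and a
      ## per-iteration displacement cap, so facing surfaces that start
      ## nearly aligned cannot jump to a distant symmetry basin
      nw <- length(free_w)
      scale2 <- c(rep(0.05, nw), rep(1, 3))^2
      maxr <- max(row_norms(Vc))
      e_cur <- fn(th)
      step <- params$step_size
      flat <- 0
      h <- c(rep(1e-4, nw), rep(1e-3, 3))
      for (it in seq_len(params$max_iters)) {
        g <- vapply(seq_along(th), function(k) {
          tp <- th; tp[k] <- tp[k] + h[k]
          tm <- th; tm[k] <- tm[k] - h[k]
          (fn(tm) * -1 + fn(tp)) / (2 * h[k])
        }, numeric(1))
        dir <- -g * scale2
        dmax <- sqrt(sum(dir[seq_len(nw)]^2)) * maxr +
          sqrt(sum(dir[nw + 1:3]^2))
        if (dmax < 1e-14) break
        eps <- step / dmax
        accepted <- FALSE
        for (bt in 1:20) {
          thn <- th + eps * dir
          e_new <- fn(thn)
          if (e_new < e_cur) { accepted <- TRUE; break }
          eps <- eps / 2
        }
        if (!accepted) break
        rel <- (e_cur - e_new) / max(abs(e_cur), 1e-300)
        th <- thn; e_cur <- e_new
        step <- min(eps * dmax * 1.5, params$step_size)
        flat <- if (rel < params$convergence_tol) flat + 1 else 0
        if (flat >= 5) break
      }
    }
    per_scale[[length(per_scale) + 1]] <- trace_env$energies
  }
  M <- lin_of(th); tt <- tr_of(th)
  converged <- is.finite(e_cur)
  transform <- affine_transform(M, mu + tt - as.vector(M %*% mu))
  list(transform = transform, energy = per_scale,
       converged = converged, dissimilarity = e_cur)
}

#' Diffeomorphic surface registration by greedy currents flow
#'
#' Descends the currents dissimilarity in a reproducing-kernel space of
#' velocity fields (Cauchy kernel of scale `velocity_kernel_scale`): each
#' accepted iteration evaluates the vertex-position gradient of the energy,
#' smooths it through the kernel, and advects the moving surface by one
#' Euler step, recording the step as a kernel velocity field.  The recorded
#' flow extends smoothly to all of space and is returned as a
#' [diffeomorphism].  The objective adds `smoothness_weight` times the
#' accumulated RKHS norm of the velocity to the matching term, so steps are
#' only accepted while the match improves faster than the deformation cost
#' grows.
#'
#' @inheritParams affine_register_surfaces
#' @param constraint `"none"`, or `"z_translation_only"`: the z-component of
#'   every velocity field is projected to its spatial mean so the map's z
#'   action is one global translation.
#' @return list with `transform` ([diffeomorphism]), `moved` mesh, `energy`
#'   trace, `converged`, `status` (`"ok"` or `"failed"`), `dissimilarity`.
#' @export
diffeo_register_surfaces <- function(moving, target, params = currents_params(),
                                     constraint = c("none", "z_translation_only")) {
  constraint <- match.arg(constraint)
  check_nonempty_mesh(moving, "moving"); check_nonempty_mesh(target, "target")
  cache <- mesh_cache(target)
  faces <- moving$faces
  q <- moving$vertices
  sigV <- params$velocity_kernel_scale
  lam <- params$smoothness_weight
  steps <- list()
  energies <- numeric(0)
  e_cur <- currents_energy_vs_cache(q, faces, cache, params$sigma)
  reg_total <- 0
  step <- params$step_size
  flat <- 0; converged <- FALSE
  for (it in seq_len(params$max_iters)) {
    g <- currents_dissimilarity_grad(
      triangle_mesh(q, faces, check_degenerate = FALSE),
      target, params$sigma, target_cache = cache)
    K <- cauchy_kernel_matrix(q, q, sigV)
    v <- -(K %*% g)                   # RKHS-smoothed descent direction
    drift <- c(0, 0, 0)
    alpha_dir <- -g
    if (constraint == "z_translation_only") {
      drift[3] <- mean(v[, 3])
      alpha_dir[, 3] <- 0
      v[, 3] <- drift[3]
    }
    vmax <- max(row_norms(v))
    if (vmax < 1e-14) { converged <- TRUE; break }
    eps0 <- step / vmax
    accepted <- FALSE
    eps <- eps0
    for (bt in 1:20) {
      qn <- q + eps * v
      e_new <- currents_energy_vs_cache(qn, faces, cache, params$sigma)
      ## RKHS norm of this step's velocity (drift part excluded)
      reg_step <- eps^2 * sum(alpha_dir * (K %*% alpha_dir))
      if (e_new + lam * (reg_total + reg_step) < e_cur + lam * reg_total) {
        accepted <- TRUE; break
      }
      eps <- eps / 2
    }
    if (!accepted) break
    steps[[length(steps) + 1]] <-
      kernel_velocity_step(q, eps * alpha_dir, sigV, drift = eps * drift, dt = 1)
    rel <- (e_cur - e_new) / max(abs(e_cur), 1e-300)
    q <- qn; e_cur <- e_new; reg_total <- reg_total + eps^2 *
      sum(alpha_dir * (K %*% alpha_dir))
    energies <- c(energies, e_cur)
    step <- min(eps * vmax * 1.5, params$step_size)
    flat <- if (rel < params$convergence_tol) flat + 1 else 0
    if (flat >= 5) { converged <- TRUE; break }
  }
  lo <- pmin(apply(moving$vertices, 2, min), apply(target$vertices, 2, min)) - 2 * sigV
  hi <- pmax(apply(moving$vertices, 2, max), apply(target$vertices, 2, max)) + 2 * sigV
  phi <- diffeomorphism(steps, rbind(lo, hi), dim = 3, validate = FALSE)
  chk <- if (length(steps) > 0) check_diffeomorphism(phi, n = 5) else
    list(ok = TRUE, why = "", min_jacobian = 1, max_roundtrip_mm = 0)
  status <- if (chk$ok) "ok" else "failed"
  if (!chk$ok)
    warning(paste0("surface flow failed diffeomorphism checks: ", chk$why))
  list(transform = phi,
       moved = triangle_mesh(q, faces, check_degenerate = FALSE),
       energy = energies, converged = converged, status = status,
       dissimilarity = e_cur, check = chk)
}

#' Sample a kernel-parameterised flow onto a regular grid
#'
#' Rewrites each velocity step of a diffeomorphism as a grid velocity field
#' sampled at `spacing` mm over the flow's domain.  Application to large
#' point sets (image resampling) then costs one interpolation per step
#' instead of one kernel evaluation per control point.
#'
#' @param phi a [diffeomorphism].
#' @param spacing grid spacing, mm (scalar or length-d).
#' @return a [diffeomorphism] with grid-parameterised steps.
#' @export
discretize_diffeomorphism <- function(phi, spacing = 1) {
  d <- phi$dim
  spacing <- rep(as.double(spacing), length.out = d)
  lo <- phi$domain_bounds[1, ]; hi <- phi$domain_bounds[2, ]
  ns <- pmax(ceiling((hi - lo) / spacing) + 1, 2)
  axes <- lapply(seq_len(d), function(c) lo[c] + (seq_len(ns[c]) - 1) * spacing[c])
  g <- as.matrix(do.call(expand.grid, axes))
  steps <- lapply(phi$steps, function(s) {
    v <- eval_step_velocity(s, g)
    arr <- array(v, dim = c(ns, d))
    grid_velocity_step(arr, spacing, lo, dt = s$dt)
  })
  diffeomorphism(steps, phi$domain_bounds, dim = d, validate = FALSE)
}
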