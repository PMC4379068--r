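# Intensity-based registration: SSD-driven affine (same modality) and
# NMI-driven rigid body (across modalities).  Both use a coarse-to-fine
# multiresolution pyramid with derivative-free (Nelder-Mead) minimization
# at each level, warm-starting the next.  The returned transform maps
# moving world coordinates into fixed world coordinates.

#' Registration settings
#'
#' @param cost `"ssd"` (sum of squared differences, intra-modal) or `"nmi"`
#'   (normalized mutual information, inter-modal).
#' @param dof degrees of freedom: 6 (rigid), 9 (rigid + anisotropic scale,
#'   no shear) or 12 (full affine).
#' @param pyramid_levels number of multiresolution levels (>= 1); level `l`
#'   downsamples by `2^(l-1)`.
#' @param smoothing_fwhm Gaussian FWHM in mm applied identically to both
#'   images before registration (0 = none).
#' @param histogram_bins joint-histogram bins per axis for NMI (>= 8).
#' @param max_iterations optimizer iteration cap per pyramid level.
#' @param convergence_tol relative cost-change tolerance.
#' @param sampling stride (in voxels) of the cost-evaluation subgrid at the
#'   finest level; coarser levels always use stride 1.
#' @return a `reg_control` list.
#' @export
reg_control <- function(cost = c("ssd", "nmi"), dof = 12L,
                        pyramid_levels = 3L, smoothing_fwhm = 0,
                        histogram_bins = 64L, max_iterations = 400L,
                        convergence_tol = 1e-6, sampling = 2L) {
  cost <- match.arg(cost)
  stopifnot(dof %in% c(6L, 9L, 12L), pyramid_levels >= 1L,
            histogram_bins >= 8L, convergence_tol > 0, sampling >= 1L)
  structure(list(cost = cost, dof = as.integer(dof),
                 pyramid_levels = as.integer(pyramid_levels),
                 smoothing_fwhm = smoothing_fwhm,
                 histogram_bins = as.integer(histogram_bins),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 sampling = as.integer(sampling)),
            class = "reg_control")
}

# Parameter vector <-> transform, by dof.
theta_names <- function(dof) {
  switch(as.character(dof),
         "6"  = c("tx", "ty", "tz", "rx", "ry", "rz"),
         "9"  = c("tx", "ty", "tz", "rx", "ry", "rz", "sx", "sy", "sz"),
         "12" = c("tx", "ty", "tz", "rx", "ry", "rz", "sx", "sy", "sz",
                  "kxy", "kxz", "kyz"))
}

theta_to_transform <- function(theta, dof) {
  p <- c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0,
         sx = 1, sy = 1, sz = 1, kxy = 0, kxz = 0, kyz = 0)
  p[theta_names(dof)] <- theta
  do.call(make_affine, as.list(p))
}

transform_to_theta <- function(t, dof) {
  unname(t$params[theta_names(dof)])
}

theta_parscale <- function(dof) {
  ps <- c(rep(2, 3), rep(10, 3), rep(0.05, 3), rep(0.02, 3))
  ps[seq_len(dof)]
}

# Mask resampled (nearest) onto a pyramid-level grid, as a plain logical
# vector; logical(0) when no mask is in play.
downsample_mask <- function(mask, level_grid) {
  if (is.null(mask)) return(logical(0))
  if (same_grid(mask$grid, level_grid)) return(as.logical(mask$mask))
  m <- image_volume(array(as.numeric(mask$mask), dim = mask$grid$dims),
                    mask$grid)
  as.vector(reslice_to_grid(m, level_grid, "nearest")$values > 0.5)
}

# Downsample by an integer factor: anti-alias blur then reslice onto the
# coarse grid whose voxel centers sit at the mean position of each f^3 block.
downsample_volume <- function(image, factor) {
  if (factor == 1L) return(image)
  sm <- smooth_gaussian(image, fwhm = grid_voxel_size(image$grid) * factor)
  S <- diag(c(factor, factor, factor, 1))
  S[1:3, 4] <- (factor - 1) / 2
  coarse <- volume_grid(pmax(1L, image$grid$dims %/% factor),
                        affine = image$grid$affine %*% S)
  reslice_to_grid(sm, coarse, "trilinear")
}

# Finite-difference step per parameter for the Gauss-Newton Jacobian.
theta_fd_step <- function(dof) {
  fd <- c(rep(1e-2, 3), rep(1e-2, 3), rep(1e-4, 3), rep(1e-4, 3))
  fd[seq_len(dof)]
}

# Residual vector (fixed - moving(theta)) at one pyramid level.
level_resid_fn <- function(moving, fixed, control, step, fmask = logical(0)) {
  fdim <- fixed$grid$dims
  mdim <- moving$grid$dims
  pre <- solve(moving$grid$affine)
  post <- fixed$grid$affine
  mvals <- as.double(moving$values)
  fvals <- as.double(fixed$values)
  function(theta) {
    t <- theta_to_transform(theta, control$dof)
    M <- pre %*% solve(t$matrix) %*% post
    cpp_resid_ssd(mvals, mdim, fvals, fdim, M, step, fmask)
  }
}

# Levenberg-Marquardt minimization of the mean squared residual.  Returns
# list(theta, cost, iterations, converged).
optimize_lm <- function(resid_fn, theta, dof, max_iter, tol) {
  fd <- theta_fd_step(dof)
  r <- resid_fn(theta)
  cost <- mean(r^2)
  lambda <- 1e-3
  evals <- 1L
  converged <- FALSE
  n_improved <- 0L
  for (iter in seq_len(max_iter)) {
    J <- matrix(0, length(r), dof)
    for (j in seq_len(dof)) {
      tp <- theta
      tp[j] <- tp[j] + fd[j]
      J[, j] <- (resid_fn(tp) - r) / fd[j]
    }
    evals <- evals + dof
    H <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (try_i in 1:8) {
      A <- H + lambda * diag(diag(H) + 1e-12, dof)
      delta <- tryCatch(-solve(A, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        rc <- resid_fn(cand)
        evals <- evals + 1L
        cc <- mean(rc^2)
        if (is.finite(cc) && cc < cost) {
          rel <- (cost - cc) / max(cost, 1e-30)
          theta <- cand; r <- rc; cost <- cc
          lambda <- max(lambda / 3, 1e-10)
          improved <- TRUE
          n_improved <- n_improved + 1L
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 5
    }
    if (!improved || converged) break
  }
  # a run that never improved on a nonzero cost could not follow the
  # gradient at all (flat or degenerate problem): report divergence
  converged <- converged || n_improved > 0L || cost <= 1e-30
  list(theta = theta, cost = cost, iterations = evals,
       converged = converged)
}

# Negative cost to *minimize* for a parameter vector at one pyramid level.
level_cost_fn <- function(moving, fixed, control, step, fmask = logical(0)) {
  fdim <- fixed$grid$dims
  mdim <- moving$grid$dims
  pre <- solve(moving$grid$affine)
  post <- fixed$grid$affine
  mvals <- as.double(moving$values)
  fvals <- as.double(fixed$values)
  if (control$cost == "nmi") {
    frng <- range(fvals); mrng <- range(mvals)
    if (diff(frng) < 1e-12 || diff(mrng) < 1e-12)
      stop("degenerate histogram: constant image supplied to NMI registration")
    bins <- control$histogram_bins
  }
  function(theta) {
    t <- theta_to_transform(theta, control$dof)
    M <- pre %*% solve(t$matrix) %*% post
    if (control$cost == "ssd") {
      cpp_cost_ssd(mvals, mdim, fvals, fdim, M, step, fmask)
    } else {
      H <- cpp_joint_hist(mvals, mdim, fvals, fdim, M, step, bins,
                          frng[1], frng[2], mrng[1], mrng[2], fmask)
      -nmi_from_hist(H)
    }
  }
}

# Normalized mutual information (H(A)+H(B))/H(A,B) of a joint histogram.
nmi_from_hist <- function(H) {
  n <- sum(H)
  if (n <= 0) return(0)
  P <- H / n
  px <- rowSums(P); py <- colSums(P)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hxy <- ent(P)
  if (hxy <= 0) return(0)
  (ent(px) + ent(py)) / hxy
}

register_intensity <- function(moving, fixed, control, init, mask = NULL) {
  stopifnot(inherits(moving, "image_volume"), inherits(fixed, "image_volume"))
  if (!grids_overlap(moving$grid, fixed$grid))
    stop("moving and fixed grids have disjoint fields of view")
  if (!is.null(mask) && !same_grid(mask$grid, fixed$grid))
    stop("cost mask must live on the fixed image grid")
  if (is.null(init)) init <- identity_affine()
  if (control$smoothing_fwhm > 0) {
    moving <- smooth_gaussian(moving, control$smoothing_fwhm)
    fixed <- smooth_gaussian(fixed, control$smoothing_fwhm)
  }
  theta <- transform_to_theta(init, control$dof)
  parscale <- theta_parscale(control$dof)
  iterations <- 0L
  converged <- FALSE
  factors <- 2L^((control$pyramid_levels:1L) - 1L)
  factors <- factors[factors * 4L <= min(fixed$grid$dims)]  # keep >= 4 voxels
  if (length(factors) == 0L) factors <- 1L
  final_fn <- NULL
  for (f in factors) {
    mov_l <- downsample_volume(moving, f)
    fix_l <- downsample_volume(fixed, f)
    fmask_l <- downsample_mask(mask, fix_l$grid)
    step <- if (f == 1L) control$sampling else 1L
    fn <- level_cost_fn(mov_l, fix_l, control, step, fmask_l)
    if (control$cost == "ssd") {
      # damped Gauss-Newton on the per-sample residuals
      rfn <- level_resid_fn(mov_l, fix_l, control, step, fmask_l)
      opt <- optimize_lm(rfn, theta, control$dof,
                         max_iter = min(control$max_iterations, 50L),
                         tol = control$convergence_tol)
      theta <- opt$theta
      iterations <- iterations + opt$iterations
      converged <- opt$converged
    } else {
      opt <- stats::optim(theta, fn, method = "Nelder-Mead",
                          control = list(maxit = control$max_iterations,
                                         reltol = control$convergence_tol,
                                         parscale = parscale))
      theta <- opt$par
      iterations <- iterations + opt$counts[1]
      converged <- (opt$convergence == 0L)
    }
    final_fn <- fn
  }
  # monotone-improvement guarantee at the finest level
  c_init <- final_fn(transform_to_theta(init, control$dof))
  c_final <- final_fn(theta)
  if (!is.finite(c_final) || c_final > c_init) {
    theta <- transform_to_theta(init, control$dof)
    c_final <- c_init
    converged <- FALSE
  }
  structure(list(transform = theta_to_transform(theta, control$dof),
                 final_cost = if (control$cost == "nmi") -c_final else c_final,
                 initial_cost = if (control$cost == "nmi") -c_init else c_init,
                 iterations = as.integer(iterations),
                 converged = converged,
                 control = control),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("registration_result (", x$control$cost, ", dof ", x$control$dof,
      "): cost ", signif(x$final_cost, 6), ", ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(x$transform)
  invisible(x)
}

#' Affine registration by sum-of-squared-differences minimization
#'
#' Intra-modal spatial normalization: finds the affine transform carrying
#' the moving image into the fixed image's space by minimizing the mean
#' squared intensity difference over the fixed grid (out-of-field moving
#' samples count as 0), with a coarse-to-fine pyramid and Nelder-Mead
#' minimization.  Deterministic for fixed inputs and init.  Optimizer
#' failure is reported through `converged = FALSE`, never as an error.
#'
#' @param moving,fixed [image_volume]s with overlapping fields of view.
#' @param control a [reg_control] with `cost = "ssd"`.
#' @param init initial `affine_transform` (default identity).
#' @param mask optional [brain_mask] on the fixed grid restricting the
#'   cost evaluation (the masked sum); `NULL` uses the whole volume.
#' @return a `registration_result`: `transform` (moving world -> fixed
#'   world), `final_cost`, `iterations`, `converged`.
#' @export
register_affine_ssd <- function(moving, fixed,
                                control = reg_control("ssd", dof = 12L),
                                init = NULL, mask = NULL) {
  if (control$cost != "ssd") stop("control$cost must be 'ssd'")
  register_intensity(moving, fixed, control, init, mask)
}

#' Rigid-body registration by normalized-mutual-information maximization
#'
#' Inter-modal coregistration: maximizes NMI = (H(A)+H(B))/H(A,B) computed
#' from a joint histogram over the overlap region, over the 6 rigid-body
#' parameters.  Constant images are rejected (degenerate histogram).
#'
#' @inheritParams register_affine_ssd
#' @param control a [reg_control] with `cost = "nmi"` and `dof = 6`.
#' @return a `registration_result` whose `final_cost` is the achieved NMI.
#' @export
register_rigid_nmi <- function(moving, fixed,
                               control = reg_control("nmi", dof = 6L),
                               init = NULL, mask = NULL) {
  if (control$cost != "nmi") stop("control$cost must be 'nmi'")
  if (control$dof != 6L) stop("NMI registration is rigid-body: dof must be 6")
  register_intensity(moving, fixed, control, init, mask)
}
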