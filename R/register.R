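#' Registration configuration
#'
#' Defaults are sized for 48^3 phantom grids. The objective is
#' `E(v) = sum((M o exp(v) - F)^2) + reg_weight * LE(v)` with
#' `LE(v) = mu/4 sum_ij ||D_i v_j + D_j v_i||^2 + lambda/2 ||div v||^2`
#' (central differences, replicated edges). Optimization is steepest
#' descent with Armijo step halving on the exact objective, coarse to fine.
#'
#' @param n_levels multiresolution levels (coarsest is `2^(n_levels-1)`-fold
#'   downsampled).
#' @param iters_per_level iteration cap per level (scalar or vector,
#'   coarse first).
#' @param squaring_steps scaling-and-squaring steps N for `exp`.
#' @param elastic_mu,elastic_lambda linear-elastic penalty weights.
#' @param reg_weight overall penalty weight lambda.
#' @param step_size initial update size, voxels of maximum displacement.
#' @param smooth_grad_fwhm Gaussian FWHM (voxels) applied to the descent
#'   direction; 0 disables. A fluid-like preconditioner that keeps updates
#'   smooth.
#' @param tol relative objective decrease below which a level stops.
#' @param min_step smallest accepted Armijo step before a level stops.
#' @return list of class `reg_config`.
#' @export
reg_config <- function(n_levels = 3L, iters_per_level = c(40L, 30L, 20L),
                       squaring_steps = 6L, elastic_mu = 1, elastic_lambda = 0.5,
                       reg_weight = 0.05, step_size = 0.4,
                       smooth_grad_fwhm = 4, tol = 1e-5, min_step = 1e-4) {
  stopifnot(n_levels >= 1L, squaring_steps >= 1L,
            elastic_mu >= 0, elastic_lambda >= 0, reg_weight >= 0)
  if (length(iters_per_level) == 1L)
    iters_per_level <- rep(iters_per_level, n_levels)
  iters_per_level <- rep_len(as.integer(iters_per_level), n_levels)
  structure(list(n_levels = as.integer(n_levels),
                 iters_per_level = iters_per_level,
                 squaring_steps = as.integer(squaring_steps),
                 elastic_mu = elastic_mu, elastic_lambda = elastic_lambda,
                 reg_weight = reg_weight, step_size = step_size,
                 smooth_grad_fwhm = smooth_grad_fwhm,
                 tol = tol, min_step = min_step),
            class = "reg_config")
}

# downsample a 3-D array by 2 (smooth then stride-2 sample)
downsample2 <- function(arr) {
  d <- dim(arr)
  dc <- pmax(2L, as.integer(ceiling(d / 2)))
  sm <- gaussian_smooth3(arr, 0.85)
  pts <- cbind(
    rep.int(2 * (seq_len(dc[1]) - 1L), dc[2] * dc[3]),
    rep.int(rep(2 * (seq_len(dc[2]) - 1L), each = dc[1]), dc[3]),
    rep(2 * (seq_len(dc[3]) - 1L), each = dc[1] * dc[2])
  )
  array(interp_array3(sm, pts), dc)
}

# upsample a coarse velocity lattice (shape_c x 3) to fine shape (x2 coords)
upsample_velocity2 <- function(v, fine_shape) {
  pts <- cbind(
    rep.int((seq_len(fine_shape[1]) - 1L) / 2, fine_shape[2] * fine_shape[3]),
    rep.int(rep((seq_len(fine_shape[2]) - 1L) / 2, each = fine_shape[1]),
            fine_shape[3]),
    rep((seq_len(fine_shape[3]) - 1L) / 2, each = fine_shape[1] * fine_shape[2])
  )
  out <- array(0, c(fine_shape, 3L))
  for (c in 1:3)
    out[, , , c] <- array(2 * interp_array3(v[, , , c], pts), fine_shape)
  out
}

# exp of a raw velocity lattice on a unit grid (internal fast path)
exp_lattice <- function(v, n_steps, interp = "linear") {
  g <- voxel_grid(dim(v)[1:3])
  exp_velocity(velocity_field(g, v), n_steps, interp = interp)$u
}

warp_lattice <- function(arr, u) {
  d <- dim(arr)
  pts <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  ) + cbind(as.vector(u[, , , 1]), as.vector(u[, , , 2]), as.vector(u[, , , 3]))
  array(interp_array3(arr, pts), d)
}

#' Diffeomorphic registration of two volumes (DARTEL-style)
#'
#' Estimates a stationary velocity field `v` such that the moving image
#' resampled through `exp(v)` matches the fixed image, minimizing the
#' mean-squared difference plus a linear-elastic penalty on `v`.
#' The accepted objective sequence is non-increasing by construction.
#'
#' @param fixed,moving [scalar_volume]s on one grid, pre-aligned
#'   (see [affine_prealign]) and in comparable intensity ranges.
#' @param cfg a [reg_config].
#' @return list with `velocity` ([velocity_field]), `msd_initial`,
#'   `msd_final`, `energy_trace` (per accepted step, final level) and
#'   `converged`.
#' @export
register_diffeo <- function(fixed, moving, cfg = reg_config()) {
  stopifnot(inherits(fixed, "scalar_volume"), inherits(moving, "scalar_volume"))
  stop_if_grid_mismatch(fixed$grid, moving$grid, "fixed and moving")
  Fs <- list(fixed$values); Ms <- list(moving$values)
  for (l in seq_len(cfg$n_levels - 1L)) {
    Fs[[l + 1L]] <- downsample2(Fs[[l]])
    Ms[[l + 1L]] <- downsample2(Ms[[l]])
  }
  v <- NULL
  trace <- NULL
  for (lev in rev(seq_len(cfg$n_levels))) {
    Fv <- Fs[[lev]]; Mv <- Ms[[lev]]
    d <- dim(Fv)
    v <- if (is.null(v)) array(0, c(d, 3L)) else upsample_velocity2(v, d)
    res <- optimize_level(Fv, Mv, v, cfg,
                          iters = cfg$iters_per_level[cfg$n_levels - lev + 1L])
    v <- res$v
    trace <- res$trace
  }
  u <- exp_lattice(v, cfg$squaring_steps)
  warped <- warp_lattice(moving$values, u)
  list(velocity = velocity_field(fixed$grid, v),
       msd_initial = mean((moving$values - fixed$values)^2),
       msd_final = mean((warped - fixed$values)^2),
       energy_trace = trace,
       converged = res$converged)
}

# fused 3-channel trilinear gather; um is N x 3 (column-major lattices),
# tgt is N x 3 voxel coords; shares clamping and weights across channels
interp3m <- function(um, tgt, d) {
  x <- pmin.int(pmax.int(tgt[, 1], 0), d[1] - 1)
  y <- pmin.int(pmax.int(tgt[, 2], 0), d[2] - 1)
  z <- pmin.int(pmax.int(tgt[, 3], 0), d[3] - 1)
  i0 <- pmin.int(floor(x), d[1] - 2); fx <- x - i0
  j0 <- pmin.int(floor(y), d[2] - 2); fy <- y - j0
  k0 <- pmin.int(floor(z), d[3] - 2); fz <- z - k0
  base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  i000 <- base;        i100 <- base + sx
  i010 <- base + sy;   i110 <- base + sx + sy
  i001 <- base + sz;   i101 <- base + sx + sz
  i011 <- base + sy + sz; i111 <- base + sx + sy + sz
  out <- um   # same shape
  for (c in 1:3) {
    uc <- um[, c]
    c00 <- uc[i000] + fx * (uc[i100] - uc[i000])
    c10 <- uc[i010] + fx * (uc[i110] - uc[i010])
    c01 <- uc[i001] + fx * (uc[i101] - uc[i001])
    c11 <- uc[i011] + fx * (uc[i111] - uc[i011])
    c0 <- c00 + fy * (c10 - c00)
    c1 <- c01 + fy * (c11 - c01)
    out[, c] <- c0 + fz * (c1 - c0)
  }
  out
}

# scaling-and-squaring on matrix-form velocity (N x 3), linear interpolant
exp_fast <- function(vm, d, n_steps, pts) {
  um <- vm / 2^n_steps
  for (s in seq_len(n_steps)) um <- um + interp3m(um, pts + um, d)
  um
}

optimize_level <- function(Fv, Mv, v, cfg, iters) {
  mu <- cfg$elastic_mu; la <- cfg$elastic_lambda; lw <- cfg$reg_weight
  N <- cfg$squaring_steps
  sig <- fwhm_to_sigma(cfg$smooth_grad_fwhm)
  d <- dim(Fv)
  nvox <- prod(d)
  pts <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  as_mat <- function(v) matrix(v, nvox, 3)
  as_arr <- function(m) array(m, c(d, 3L))
  warp_m <- function(um) array(interp_array3(Mv, pts + um), d)
  energy_parts <- function(vm) {
    um <- exp_fast(vm, d, N, pts)
    w <- warp_m(um)
    list(E = sum((w - Fv)^2) +
           lw * elastic_energy(as_arr(vm), mu, la), w = w)
  }
  vm <- as_mat(v)
  ep <- energy_parts(vm)
  E <- ep$E; w <- ep$w
  trace <- E
  step <- cfg$step_size
  for (it in seq_len(iters)) {
    r <- w - Fv
    g <- array(0, c(d, 3L))
    for (ax in 1:3) g[, , , ax] <- 2 * r * diff_central(w, ax)
    g <- g + lw * elastic_gradient(as_arr(vm), mu, la)
    if (sig > 0) for (c in 1:3) g[, , , c] <- gaussian_smooth3(g[, , , c], sig)
    gm <- as_mat(g)
    gmax <- max(abs(gm))
    if (gmax == 0) break
    accepted <- FALSE
    while (step >= cfg$min_step) {
      vm_new <- vm - (step / gmax) * gm
      ep <- energy_parts(vm_new)
      if (ep$E <= E) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break            # no descent at min step: level done
    dE <- E - ep$E
    vm <- vm_new; E <- ep$E; w <- ep$w
    trace <- c(trace, E)
    step <- min(step * 1.5, 1)
    if (dE < cfg$tol * max(E, .Machine$double.eps)) break
  }
  list(v = as_arr(vm), trace = trace, converged = TRUE)
}

#' Affine pre-alignment of two binary/smooth masks
#'
#' Matches centroids, principal axes (no reflection) and an isotropic scale
#' equal to the cube root of the mass ratio. Returns the 4x4 world-space
#' matrix `A` with `x_fixed = A %*% x_moving`. When the moment tensor is
#' degenerate (near-equal eigenvalues or ambiguous axis pairing) the
#' rotation is dropped and only centroid + scale are matched.
#'
#' @param fixed_mask,moving_mask [scalar_volume]s (nonnegative mass maps).
#' @return 4x4 numeric matrix.
#' @export
affine_prealign <- function(fixed_mask, moving_mask) {
  mom <- function(vol) {
    w <- as.vector(vol$values)
    if (sum(w) <= 0) stop("affine_prealign: empty mask")
    pts <- voxel_to_world(vol$grid, grid_points(vol$grid))
    m0 <- sum(w)
    ctr <- colSums(pts * w) / m0
    xc <- sweep(pts, 2, ctr)
    cov <- crossprod(xc * sqrt(w)) / m0
    list(mass = m0 * vol$grid$voxel_volume, ctr = ctr, cov = cov)
  }
  mf <- mom(fixed_mask); mm <- mom(moving_mask)
  s <- (mf$mass / mm$mass)^(1 / 3)
  ef <- eigen(mf$cov, symmetric = TRUE)
  em <- eigen(mm$cov, symmetric = TRUE)
  R <- diag(3)
  gaps_ok <- function(ev) all(diff(rev(ev$values)) / max(ev$values) > 0.05 |
                                diff(rev(ev$values)) > 0)
  dotm <- t(ef$vectors) %*% em$vectors
  rel_gap <- function(ev) min(abs(diff(ev$values))) / max(abs(ev$values))
  if (rel_gap(ef) > 0.05 && rel_gap(em) > 0.05 &&
      all(abs(diag(dotm)) > 0.5)) {
    D <- diag(sign(diag(dotm)))
    R <- ef$vectors %*% D %*% t(em$vectors)
    if (det(R) < 0) {
      k <- which.min(abs(diag(dotm)))
      D[k, k] <- -D[k, k]
      R <- ef$vectors %*% D %*% t(em$vectors)
    }
  }
  A <- diag(4)
  A[1:3, 1:3] <- R * s
  A[1:3, 4] <- mf$ctr - (R * s) %*% mm$ctr
  A
}

#' Resample a volume through a world-space affine onto a target grid
#'
#' `A` maps moving-world to fixed-world (as returned by [affine_prealign]);
#' the moving image is pulled back onto `target_grid`.
#'
#' @param volume [scalar_volume] or [label_volume] to resample.
#' @param A 4x4 world-space affine.
#' @param target_grid target [voxel_grid] (default: the volume's own grid).
#' @export
apply_affine <- function(volume, A, target_grid = volume$grid) {
  ptsw <- voxel_to_world(target_grid, grid_points(target_grid))
  srcw <- cbind(ptsw, 1) %*% t(solve(A))
  srcv <- world_to_voxel(volume$grid, srcw[, 1:3, drop = FALSE])
  if (inherits(volume, "label_volume")) {
    label_volume(target_grid,
                 array(nearest_sample(volume$labels, srcv), target_grid$shape))
  } else {
    scalar_volume(target_grid,
                  array(interp_array3(volume$values, srcv), target_grid$shape))
  }
}

#' Build a population-average template by iterative registration
#'
#' Alternates registering every image to the current template with
#' replacing the template by the mean of the warped images (the residual
#' sum of squared differences is non-increasing across outer iterations in
#' practice and is returned for inspection). When `paired` images are
#' supplied (e.g. brains enclosed in the endocasts being registered), the
#' same warps are applied to them and their mean is returned as
#' `paired_template` — the population-average brain.
#'
#' @param images list of [scalar_volume]s on one grid (pre-aligned).
#' @param cfg a [reg_config].
#' @param n_outer outer template iterations (default 3).
#' @param paired optional list of [scalar_volume]s paired with `images`.
#' @return list with `template`, `velocities` (list of [velocity_field]),
#'   `paired_template` (or NULL), `residual_trace`.
#' @export
build_template <- function(images, cfg = reg_config(), n_outer = 3L,
                           paired = NULL) {
  stopifnot(length(images) >= 2L)
  grid <- images[[1]]$grid
  for (im in images) stop_if_grid_mismatch(grid, im$grid, "template images")
  if (!is.null(paired)) stopifnot(length(paired) == length(images))
  tpl <- scalar_volume(grid, Reduce(`+`, lapply(images, `[[`, "values")) /
                         length(images))
  vels <- vector("list", length(images))
  resid <- numeric(0)
  for (outer in seq_len(n_outer)) {
    warped <- vector("list", length(images))
    for (i in seq_along(images)) {
      reg <- register_diffeo(tpl, images[[i]], cfg)
      vels[[i]] <- reg$velocity
      u <- exp_lattice(reg$velocity$v, cfg$squaring_steps)
      warped[[i]] <- warp_lattice(images[[i]]$values, u)
    }
    resid <- c(resid, sum(vapply(warped, function(w) sum((w - tpl$values)^2),
                                 0)))
    tpl <- scalar_volume(grid, Reduce(`+`, warped) / length(images))
  }
  paired_tpl <- NULL
  if (!is.null(paired)) {
    pw <- lapply(seq_along(paired), function(i) {
      u <- exp_lattice(vels[[i]]$v, cfg$squaring_steps)
      warp_lattice(paired[[i]]$values, u)
    })
    paired_tpl <- scalar_volume(grid, Reduce(`+`, pw) / length(paired))
  }
  list(template = tpl, velocities = vels, paired_template = paired_tpl,
       residual_trace = resid)
}
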