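#' Stationary velocity fields and deformations
#'
#' Deformations are parameterized by a single (stationary) velocity field
#' `v` in voxel-displacement units; its exponential, computed by
#' scaling-and-squaring, is a diffeomorphism and `exp(-v)` is its inverse.
#' Deformations use the pull-back convention: for each fixed-grid voxel
#' `x`, `phi(x) = x + u(x)` is the source voxel coordinate to sample, so
#' `warp(I, phi)(x) = I(phi(x))`.
#'
#' @param grid a [voxel_grid].
#' @param v 4-D array `shape x 3` of voxel displacements per unit flow time.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(grid, v) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- as.array(v)
  if (!identical(dim(v), c(as.integer(grid$shape), 3L)))
    stop("velocity_field: lattice must be shape x 3")
  if (!all(is.finite(v))) stop("velocity_field: non-finite values")
  structure(list(grid = grid, v = v), class = "velocity_field")
}

new_deformation <- function(grid, u) {
  structure(list(grid = grid, u = u), class = "deformation")
}

#' Identity deformation on a grid
#' @param grid a [voxel_grid].
#' @export
identity_deformation <- function(grid) {
  new_deformation(grid, array(0, c(grid$shape, 3L)))
}

#' Exponential of a stationary velocity field (scaling-and-squaring)
#'
#' Computes `phi = exp(v)` as `(id + v/2^N)` self-composed `N` times.
#' The inverse map is `exp_velocity(-v)`.
#'
#' @param v a [velocity_field].
#' @param n_steps number of squaring steps N (default 6).
#' @param interp interpolant for resampling the accumulated displacement
#'   during squaring: `"cubic"` (Catmull-Rom, default) or `"linear"`.
#'   The registration optimizer uses the linear path internally for speed;
#'   final deformations are computed with the cubic one.
#' @return a `deformation` whose field `u` holds `phi - id`.
#' @export
exp_velocity <- function(v, n_steps = 6L, interp = c("cubic", "linear")) {
  stopifnot(inherits(v, "velocity_field"), n_steps >= 1L)
  interp <- match.arg(interp)
  fn <- if (interp == "cubic") interp_array3_cubic else interp_array3
  u <- v$v / 2^n_steps
  pts <- grid_points(v$grid)
  for (s in seq_len(n_steps)) {
    tgt <- pts + cbind(as.vector(u[, , , 1]), as.vector(u[, , , 2]),
                       as.vector(u[, , , 3]))
    u2 <- u
    for (c in 1:3)
      u2[, , , c] <- array(fn(u[, , , c], tgt), dim(u)[1:3])
    u <- u + u2
  }
  new_deformation(v$grid, u)
}

#' Compose two deformations
#'
#' `compose_deformation(a, b)` returns the deformation `x -> a(b(x))`, so
#' `warp(I, compose(a, b)) == warp(warp(I, a), b)` up to interpolation.
#'
#' @param a,b `deformation` objects on one grid.
#' @param interp interpolant for resampling `a`'s displacement
#'   (`"cubic"` default, `"linear"`).
#' @export
compose_deformation <- function(a, b, interp = c("cubic", "linear")) {
  stop_if_grid_mismatch(a$grid, b$grid, "deformations")
  interp <- match.arg(interp)
  fn <- if (interp == "cubic") interp_array3_cubic else interp_array3
  pts <- grid_points(a$grid)
  tgt <- pts + cbind(as.vector(b$u[, , , 1]), as.vector(b$u[, , , 2]),
                     as.vector(b$u[, , , 3]))
  u <- b$u
  for (c in 1:3)
    u[, , , c] <- b$u[, , , c] +
      array(fn(a$u[, , , c], tgt), dim(b$u)[1:3])
  new_deformation(a$grid, u)
}

#' Warp a volume through a deformation
#'
#' @param volume a [scalar_volume] or [label_volume].
#' @param phi a `deformation` on the same grid.
#' @param mode `"trilinear"` (scalar) or `"nearest"` (labels); defaults by class.
#' @return volume of the same class, resampled.
#' @export
warp_volume <- function(volume, phi, mode = NULL) {
  grid <- volume$grid
  stop_if_grid_mismatch(grid, phi$grid, "volume and deformation")
  pts <- grid_points(grid) +
    cbind(as.vector(phi$u[, , , 1]), as.vector(phi$u[, , , 2]),
          as.vector(phi$u[, , , 3]))
  if (is.null(mode))
    mode <- if (inherits(volume, "label_volume")) "nearest" else "trilinear"
  if (mode == "nearest") {
    arr <- if (inherits(volume, "label_volume")) volume$labels else volume$values
    out <- array(nearest_sample(arr, pts), grid$shape)
    if (inherits(volume, "label_volume")) label_volume(grid, out)
    else scalar_volume(grid, out)
  } else {
    arr <- if (inherits(volume, "label_volume")) volume$labels else volume$values
    scalar_volume(grid, array(interp_array3(arr, pts), grid$shape))
  }
}

#' Jacobian determinant of a deformation (central differences)
#'
#' @param phi a `deformation`.
#' @return a [scalar_volume] of determinants of `d(phi)/dx`.
#' @export
jacobian_determinant <- function(phi) {
  d <- dim(phi$u)[1:3]
  J <- vector("list", 9)
  for (c in 1:3) {
    ph <- phi$u[, , , c]
    # phi = id + u; d(phi_c)/dx_ax = d(u_c)/dx_ax + [ax == c]
    for (ax in 1:3) {
      J[[(c - 1) * 3 + ax]] <- diff_central(ph, ax) + as.numeric(ax == c)
    }
  }
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
         J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
         J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  scalar_volume(voxel_grid(d, phi$grid$affine), det)
}

# --- finite differences via banded axis matrices (exact adjoints) ---------

diff_matrix <- function(n) {
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ip <- min(i + 1L, n); im <- max(i - 1L, 1L)
    D[i, ip] <- D[i, ip] + 0.5
    D[i, im] <- D[i, im] - 0.5
  }
  D
}

axis_apply <- function(arr, axis, M) {
  d <- dim(arr)
  n <- d[axis]
  if (axis == 1L) {
    array(M %*% matrix(arr, n, d[2] * d[3]), d)
  } else if (axis == 2L) {
    p <- aperm(arr, c(2, 1, 3))
    aperm(array(M %*% matrix(p, n, d[1] * d[3]), c(n, d[1], d[3])), c(2, 1, 3))
  } else {
    p <- aperm(arr, c(3, 1, 2))
    aperm(array(M %*% matrix(p, n, d[1] * d[2]), c(n, d[1], d[2])), c(2, 3, 1))
  }
}

diff_central <- function(arr, axis) axis_apply(arr, axis, diff_matrix(dim(arr)[axis]))
diff_central_t <- function(arr, axis) axis_apply(arr, axis, t(diff_matrix(dim(arr)[axis])))

# linear elastic energy of a velocity lattice v (shape x 3):
# mu/4 * sum_ij (D_i v_j + D_j v_i)^2 + lambda/2 * (div v)^2
elastic_energy <- function(v, mu, lambda) {
  d <- dim(v)[1:3]
  Dv <- array(0, c(d, 3, 3))       # Dv[,,,i,j] = D_i v_j
  for (i in 1:3) for (j in 1:3) Dv[, , , i, j] <- diff_central(v[, , , j], i)
  e <- 0
  for (i in 1:3) for (j in 1:3)
    e <- e + sum((Dv[, , , i, j] + Dv[, , , j, i])^2)
  divv <- Dv[, , , 1, 1] + Dv[, , , 2, 2] + Dv[, , , 3, 3]
  mu / 4 * e + lambda / 2 * sum(divv^2)
}

elastic_gradient <- function(v, mu, lambda) {
  d <- dim(v)[1:3]
  Dv <- array(0, c(d, 3, 3))
  for (i in 1:3) for (j in 1:3) Dv[, , , i, j] <- diff_central(v[, , , j], i)
  divv <- Dv[, , , 1, 1] + Dv[, , , 2, 2] + Dv[, , , 3, 3]
  g <- array(0, dim(v))
  for (j in 1:3) {
    acc <- array(0, d)
    for (i in 1:3)
      acc <- acc + diff_central_t(Dv[, , , i, j] + Dv[, , , j, i], i)
    g[, , , j] <- mu * acc + lambda * diff_central_t(divv, j)
  }
  g
}
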