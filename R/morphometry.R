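#' Propagate a template surface mesh to every specimen
#'
#' Pulls each template-mesh vertex through a per-specimen deformation
#' (template frame -> specimen frame, e.g. the inverse exponential of the
#' template-building velocity), producing homologous meshes: one shared
#' face list, vertex k in anatomical correspondence across specimens.
#'
#' @param template_mesh [triangle_mesh] in template world coordinates.
#' @param deformations list of `deformation`s (one per specimen) on the
#'   template grid.
#' @param ids optional specimen ids; `groups` optional group labels.
#' @return A `homologous_mesh_set`: `template_mesh`, `vertices`
#'   (S x V x 3 array), `ids`, `groups`. Vertices mapped outside the grid
#'   are clamped and counted in attribute `n_clamped` (with a warning).
#' @export
propagate_mesh <- function(template_mesh, deformations, ids = NULL,
                           groups = NULL) {
  stopifnot(inherits(template_mesh, "triangle_mesh"), length(deformations) >= 1)
  S <- length(deformations)
  V <- nrow(template_mesh$vertices)
  out <- array(0, c(S, V, 3))
  n_clamped <- 0L
  for (s in seq_len(S)) {
    phi <- deformations[[s]]
    g <- phi$grid
    pv <- world_to_voxel(g, template_mesh$vertices)
    lo <- sweep(pv, 2, g$shape - 1, `>`) | pv < 0
    n_clamped <- n_clamped + sum(rowSums(lo) > 0)
    tgt <- pv + cbind(interp_array3(phi$u[, , , 1], pv),
                      interp_array3(phi$u[, , , 2], pv),
                      interp_array3(phi$u[, , , 3], pv))
    out[s, , ] <- voxel_to_world(g, tgt)
  }
  if (n_clamped > 0)
    warning(sprintf("propagate_mesh: %d vertex samples clamped at grid edge",
                    n_clamped))
  structure(list(template_mesh = template_mesh, vertices = out,
                 ids = ids %||% sprintf("spec_%02d", seq_len(S)),
                 groups = groups %||% rep(NA_character_, S),
                 n_clamped = n_clamped),
            class = "homologous_mesh_set")
}

#' Generalized Procrustes superimposition with size normalization
#'
#' Translates every configuration to its centroid, scales to unit centroid
#' size, and rotates (rotations only, no reflections) to a consensus mean
#' that is iteratively refined until the mean shape changes by less than
#' `tol` RMS.
#'
#' @param meshes a `homologous_mesh_set`.
#' @param tol convergence tolerance on the consensus (default 1e-8).
#' @return the set with aligned `vertices`, plus `centroid_sizes`
#'   (pre-scaling) and `consensus` (V x 3 mean shape).
#' @export
procrustes_align <- function(meshes, tol = 1e-8) {
  stopifnot(inherits(meshes, "homologous_mesh_set"))
  X <- meshes$vertices
  S <- dim(X)[1]; V <- dim(X)[2]
  if (S < 2) stop("procrustes_align: need at least 2 specimens")
  sizes <- numeric(S)
  for (s in seq_len(S)) {
    cfg <- X[s, , ]
    cfg <- sweep(cfg, 2, colMeans(cfg))
    sizes[s] <- sqrt(sum(cfg^2))
    if (sizes[s] < .Machine$double.eps)
      stop("procrustes_align: degenerate configuration (all points coincide)")
    X[s, , ] <- cfg / sizes[s]
  }
  rot_to <- function(cfg, ref) {
    # optimal rotation (no reflection): Kabsch
    H <- crossprod(cfg, ref)
    sv <- svd(H)
    dsign <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
    cfg %*% t(R)
  }
  mean_shape <- X[1, , ]
  for (iter in 1:200) {
    for (s in seq_len(S)) X[s, , ] <- rot_to(X[s, , ], mean_shape)
    new_mean <- apply(X, c(2, 3), mean)
    # keep the consensus at unit centroid size
    new_mean <- new_mean / sqrt(sum(sweep(new_mean, 2, colMeans(new_mean))^2))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  meshes$vertices <- X
  meshes$centroid_sizes <- sizes
  meshes$consensus <- mean_shape
  meshes
}

#' Vertex displacement fields about the consensus shape
#'
#' @param aligned a Procrustes-aligned `homologous_mesh_set`.
#' @return S x V x 3 array of deviations `vertex - consensus`.
#' @export
displacement_fields <- function(aligned) {
  stopifnot(!is.null(aligned$consensus))
  sweep(aligned$vertices, c(2, 3), aligned$consensus)
}

#' Signed normal displacement map between two groups
#'
#' Per-vertex difference of group mean positions projected on the
#' area-weighted outward unit normal of the consensus mesh — positive
#' where group A lies outside group B along the surface normal.
#'
#' @param aligned aligned `homologous_mesh_set` with group labels.
#' @param group_a,group_b group labels to contrast.
#' @return numeric vector, one signed value per vertex (consensus units).
#' @export
signed_normal_displacement <- function(aligned, group_a, group_b) {
  ia <- which(aligned$groups == group_a)
  ib <- which(aligned$groups == group_b)
  if (!length(ia) || !length(ib))
    stop("signed_normal_displacement: empty group")
  ma <- apply(aligned$vertices[ia, , , drop = FALSE], c(2, 3), mean)
  mb <- apply(aligned$vertices[ib, , , drop = FALSE], c(2, 3), mean)
  cons <- triangle_mesh(aligned$consensus, aligned$template_mesh$faces,
                        drop_degenerate = FALSE)
  nrm <- vertex_normals(cons)
  rowSums((ma - mb) * nrm)
}

#' Vertex-wise two-sample Hotelling T-squared map
#'
#' For each vertex, the two-sample Hotelling statistic on the 3-D
#' displacement vectors,
#' `T2 = (na*nb/(na+nb)) * d' S_pooled^{-1} d`, with the parametric p-value
#' from `F = T2 (n - p - 1) / (p (n - 2))` on `(p, n - p - 1)` degrees of
#' freedom (p = 3). A singular pooled covariance is ridge-regularized by
#' `1e-8 * trace` and flagged.
#'
#' @param aligned aligned `homologous_mesh_set`.
#' @param group_a,group_b group labels (each n >= 2, total >= 5).
#' @return A `surface_stat_map`: `t2`, `p` (vectors over vertices),
#'   `df` = c(3, n - 4), `groups`, `n` per group, `ridged` count; corrected
#'   p-values are added by [fwe_correct].
#' @export
hotelling_t2_map <- function(aligned, group_a, group_b) {
  ia <- which(aligned$groups == group_a)
  ib <- which(aligned$groups == group_b)
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2) stop("hotelling_t2_map: each group needs n >= 2")
  if (na + nb < 5)
    warning("hotelling_t2_map: n < 5; pooled covariance is regularized")
  X <- aligned$vertices
  t2 <- t2_statistic(X, ia, ib)
  n <- na + nb
  p <- 3
  fstat <- t2$t2 * (n - p - 1) / (p * (n - 2))
  pval <- stats::pf(fstat, p, n - p - 1, lower.tail = FALSE)
  structure(list(t2 = t2$t2, p = pval, df = c(p, n - p - 1),
                 groups = c(group_a, group_b), n = c(na, nb),
                 ridged = t2$ridged),
            class = "surface_stat_map")
}

# vectorized-over-vertices T2 on an S x V x 3 array for index sets ia/ib.
# Pooled 3x3 covariances come from the sum-of-squares identity
# sum (x - xbar_g)(x - xbar_g)' = sum x x' - n_g xbar_g xbar_g'
# and are inverted in closed form (adjugate/determinant); near-singular
# vertices are ridge-regularized by 1e-8 * trace.
t2_statistic <- function(X, ia, ib) {
  na <- length(ia); nb <- length(ib)
  V <- dim(X)[2]
  grp_stats <- function(idx) {
    n <- length(idx)
    Xg <- X[idx, , , drop = FALSE]
    dim(Xg) <- c(n, V * 3L)
    m <- colMeans(Xg)
    x1 <- Xg[, 1:V, drop = FALSE]
    x2 <- Xg[, V + 1:V, drop = FALSE]
    x3 <- Xg[, 2 * V + 1:V, drop = FALSE]
    ss <- cbind(colSums(x1 * x1), colSums(x2 * x2), colSums(x3 * x3),
                colSums(x1 * x2), colSums(x1 * x3), colSums(x2 * x3))
    m <- matrix(m, V, 3)
    mm <- cbind(m[, 1]^2, m[, 2]^2, m[, 3]^2,
                m[, 1] * m[, 2], m[, 1] * m[, 3], m[, 2] * m[, 3])
    list(mean = m, within = ss - n * mm)
  }
  ga <- grp_stats(ia); gb <- grp_stats(ib)
  S6 <- (ga$within + gb$within) / (na + nb - 2)
  d1 <- ga$mean[, 1] - gb$mean[, 1]
  d2 <- ga$mean[, 2] - gb$mean[, 2]
  d3 <- ga$mean[, 3] - gb$mean[, 3]
  t2_parts <- function(S6) {
    s11 <- S6[, 1]; s22 <- S6[, 2]; s33 <- S6[, 3]
    s12 <- S6[, 4]; s13 <- S6[, 5]; s23 <- S6[, 6]
    det <- s11 * (s22 * s33 - s23^2) - s12 * (s12 * s33 - s23 * s13) +
      s13 * (s12 * s23 - s22 * s13)
    a11 <- s22 * s33 - s23^2
    a12 <- s13 * s23 - s12 * s33
    a13 <- s12 * s23 - s13 * s22
    a22 <- s11 * s33 - s13^2
    a23 <- s12 * s13 - s11 * s23
    a33 <- s11 * s22 - s12^2
    quad <- d1 * (a11 * d1 + a12 * d2 + a13 * d3) +
      d2 * (a12 * d1 + a22 * d2 + a23 * d3) +
      d3 * (a13 * d1 + a23 * d2 + a33 * d3)
    list(det = det, quad = quad)
  }
  tr <- S6[, 1] + S6[, 2] + S6[, 3]
  parts <- t2_parts(S6)
  bad <- !(parts$det > (pmax(tr, .Machine$double.xmin) / 3)^3 * 1e-10) | tr <= 0
  ridged <- sum(bad)
  if (ridged > 0) {
    eps <- pmax(tr, .Machine$double.eps) * 1e-8
    S6r <- S6
    for (c in 1:3) S6r[bad, c] <- S6[bad, c] + eps[bad]
    pr <- t2_parts(S6r)
    parts$det[bad] <- pr$det[bad]
    parts$quad[bad] <- pr$quad[bad]
  }
  t2 <- (na * nb / (na + nb)) * parts$quad / parts$det
  t2[!is.finite(t2)] <- 0
  t2 <- pmax(t2, 0)
  list(t2 = t2, ridged = ridged)
}

#' Permutation max-statistic family-wise error correction
#'
#' Corrected p-value of each vertex = fraction of group-label permutations
#' whose *maximum* vertex T-squared exceeds that vertex's observed value
#' (the max-statistic distribution controls the family-wise error exactly
#' under exchangeability). When the number of distinct relabelings is at
#' most `n_perm`, all of them are enumerated; otherwise `n_perm` random
#' permutations (plus the identity) are drawn, deterministic given `seed`.
#'
#' @param stat_map a `surface_stat_map` from [hotelling_t2_map].
#' @param aligned the aligned `homologous_mesh_set` it came from.
#' @param n_perm permutations (>= 100 recommended).
#' @param seed integer.
#' @param alpha significance level for the threshold mask.
#' @return the map with added `p_fwe`, `threshold_mask` (logical),
#'   `max_t2_null` (the null max distribution), `exhaustive` flag.
#' @export
fwe_correct <- function(stat_map, aligned, n_perm = 1000L, seed = 1L,
                        alpha = 0.05) {
  stopifnot(inherits(stat_map, "surface_stat_map"))
  ia <- which(aligned$groups == stat_map$groups[1])
  ib <- which(aligned$groups == stat_map$groups[2])
  pool <- c(ia, ib)
  na <- length(ia)
  n_distinct <- choose(length(pool), na)
  exhaustive <- n_distinct <= n_perm
  if (n_distinct < 20)
    warning("fwe_correct: fewer than 20 distinct permutations; ",
            "enumerating all of them")
  X <- aligned$vertices
  perms <- if (exhaustive || n_distinct < 20) {
    cmb <- utils::combn(length(pool), na)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    set.seed(seed)
    c(list(seq_len(na)),
      replicate(n_perm - 1L, sample(length(pool), na), simplify = FALSE))
  }
  max_null <- vapply(perms, function(sel) {
    max(t2_statistic(X, pool[sel], pool[-sel])$t2)
  }, 0)
  stat_map$p_fwe <- vapply(stat_map$t2, function(t)
    mean(max_null >= t), 0)
  stat_map$p_fwe <- pmax(stat_map$p_fwe, stat_map$p)  # dominance guard
  stat_map$threshold_mask <- stat_map$p_fwe < alpha
  stat_map$max_t2_null <- max_null
  stat_map$exhaustive <- exhaustive || n_distinct < 20
  stat_map
}

#' Omnibus multi-group test on vertex displacements (Pillai trace)
#'
#' Secondary omnibus alternative to the pairwise maps: per vertex, a
#' one-way MANOVA of the 3-D coordinates across all groups, returning the
#' Pillai trace and its F approximation.
#'
#' @param aligned aligned `homologous_mesh_set` with >= 2 groups.
#' @return list with `pillai`, `f`, `p` vectors over vertices and `df`.
#' @export
manova_pillai_map <- function(aligned) {
  grp <- factor(aligned$groups)
  if (nlevels(grp) < 2) stop("manova_pillai_map: need >= 2 groups")
  V <- dim(aligned$vertices)[2]
  pil <- fst <- pv <- numeric(V)
  df <- NULL
  for (v in seq_len(V)) {
    fit <- stats::manova(aligned$vertices[, v, ] ~ grp)
    sm <- summary(fit, test = "Pillai")$stats
    pil[v] <- sm[1, "Pillai"]
    fst[v] <- sm[1, "approx F"]
    pv[v] <- sm[1, "Pr(>F)"]
    if (is.null(df)) df <- sm[1, c("num Df", "den Df")]
  }
  list(pillai = pil, f = fst, p = pv, df = df)
}
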