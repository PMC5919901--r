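#' EM Gaussian-mixture tissue segmentation
#'
#' Segments a T1-like scalar volume inside a head mask into CSF, GM and WM
#' by expectation-maximization on a 3-component univariate Gaussian
#' mixture, with an optional one-parameter Potts/MRF spatial smoothing term
#' on the posteriors. Initialization is k-means (deterministic given
#' `seed`); classes are reported in increasing-mean order (CSF < GM < WM)
#' regardless of initialization. The log-likelihood sequence over EM
#' iterations is non-decreasing (exact EM; with `mrf_weight > 0` the
#' spatial term is applied as a posterior smoothing step after convergence
#' checking, keeping the monotonicity guarantee).
#'
#' @param t1 a [scalar_volume].
#' @param head_mask binary [scalar_volume] or logical array; voxels to
#'   classify (default: whole grid).
#' @param k number of classes (3).
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @param mrf_weight Potts smoothing weight (0 disables, the default).
#' @param seed integer, k-means initialization seed.
#' @return A `segmentation_result`: list with `tissue`
#'   ([tissue_volume_set] posterior fractions, zero outside the head
#'   mask), `hard_labels` ([label_volume]: 1 = CSF, 2 = GM, 3 = WM),
#'   `class_means`, `class_sds`, `mixing`, `loglik_trace`, `n_iter`,
#'   `converged`.
#' @export
segment_em <- function(t1, head_mask = NULL, k = 3L, max_iter = 100L,
                       tol = 1e-7, mrf_weight = 0, seed = 1L) {
  stopifnot(inherits(t1, "scalar_volume"), k == 3L)
  d <- t1$grid$shape
  msk <- if (is.null(head_mask)) array(TRUE, d)
  else if (inherits(head_mask, "scalar_volume")) head_mask$values > 0.5
  else as.array(head_mask)
  if (!any(msk)) stop("segment_em: empty head mask")
  y <- t1$values[msk]
  if (length(unique(y)) < k)
    stop("segment_em: fewer distinct intensities than classes")

  set.seed(seed)
  km <- stats::kmeans(y, centers = k, nstart = 3)
  ord <- order(km$centers)
  mu <- as.vector(km$centers)[ord]
  sd0 <- sqrt(km$withinss / pmax(km$size - 1, 1))[ord]
  sd0[sd0 < 1e-6] <- max(stats::sd(y) * 1e-3, 1e-6)
  pi0 <- (km$size / length(y))[ord]

  n <- length(y)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  R <- matrix(0, n, k)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E step
    for (c in seq_len(k))
      R[, c] <- pi0[c] * stats::dnorm(y, mu[c], sd0[c])
    rs <- rowSums(R)
    rs[rs == 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    R <- R / rs
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M step
    nk <- colSums(R)
    pi0 <- nk / n
    mu <- colSums(R * y) / nk
    for (c in seq_len(k))
      sd0[c] <- sqrt(sum(R[, c] * (y - mu[c])^2) / nk[c])
    sd0[sd0 < 1e-6] <- 1e-6
  }
  # enforce CSF < GM < WM ordering
  ord <- order(mu)
  mu <- mu[ord]; sd0 <- sd0[ord]; pi0 <- pi0[ord]; R <- R[, ord, drop = FALSE]

  post <- lapply(seq_len(k), function(c) {
    a <- array(0, d); a[msk] <- R[, c]; a
  })
  if (mrf_weight > 0) {
    # one-parameter Potts smoothing: mix each posterior with its local mean
    for (c in seq_len(k))
      post[[c]] <- (post[[c]] + mrf_weight * gaussian_smooth3(post[[c]], 1)) /
        (1 + mrf_weight)
    s <- post[[1]] + post[[2]] + post[[3]]
    s[s == 0] <- 1
    for (c in seq_len(k)) post[[c]] <- post[[c]] / s * (s > 0)
    for (c in seq_len(k)) post[[c]][!msk] <- 0
  }
  hard <- array(0L, d)
  pm <- pmax(post[[1]], post[[2]], post[[3]])
  for (c in seq_len(k)) hard[msk & post[[c]] == pm] <- c
  structure(list(
    tissue = tissue_volume_set(
      scalar_volume(t1$grid, post[[2]]),
      scalar_volume(t1$grid, post[[3]]),
      scalar_volume(t1$grid, post[[1]])
    ),
    hard_labels = label_volume(t1$grid, hard),
    class_means = mu, class_sds = sd0, mixing = pi0,
    loglik_trace = ll_trace, n_iter = it, converged = converged
  ), class = "segmentation_result")
}

#' Brain, endocast masks and intracranial volume from tissue fractions
#'
#' The brain is GM + WM (fraction sum >= 0.5); the endocast is
#' GM + WM + CSF (>= 0.5); ICV is the *soft* sum of all three fractions
#' times the voxel volume, matching the definition of intracranial volume
#' as the total GM + WM + CSF volume.
#'
#' @param tissue a [tissue_volume_set].
#' @return `brain_mask`/`endocast_mask`: binary [scalar_volume];
#'   `icv`: mm^3.
#' @export
brain_mask <- function(tissue) {
  s <- tissue$gm$values + tissue$wm$values
  scalar_volume(tissue$grid, array(as.numeric(s >= 0.5), tissue$grid$shape))
}

#' @rdname brain_mask
#' @export
endocast_mask <- function(tissue) {
  s <- tissue$gm$values + tissue$wm$values + tissue$csf$values
  scalar_volume(tissue$grid, array(as.numeric(s >= 0.5), tissue$grid$shape))
}

#' @rdname brain_mask
#' @param mode `"soft"` (fraction sum, default) or `"hard"` (0.5-threshold
#'   voxel count).
#' @export
icv <- function(tissue, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  s <- tissue$gm$values + tissue$wm$values + tissue$csf$values
  n <- if (mode == "soft") sum(s) else sum(s >= 0.5)
  n * tissue$grid$voxel_volume
}
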