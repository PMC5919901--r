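#' Surface deviation between an estimated and a true mesh
#'
#' For every vertex of the estimated mesh, the Euclidean distance to the
#' nearest point of the true surface (exact point-to-triangle distance over
#' candidate triangles found via nearest true vertices). One-directional
#' (estimated -> true) by default; `bidirectional = TRUE` also returns the
#' reverse direction and the symmetric Hausdorff summary.
#'
#' @param estimated,true [triangle_mesh]es in a common frame.
#' @param k_candidates nearest true vertices whose incident triangles are
#'   tested per query point (default 8).
#' @param bidirectional also compute true -> estimated.
#' @return list with `per_vertex` (deviations, estimated vertices),
#'   `mean`, `sd`, `max`; if bidirectional, `reverse` (same fields) and
#'   `hausdorff`.
#' @export
surface_deviation <- function(estimated, true, k_candidates = 8L,
                              bidirectional = FALSE) {
  stopifnot(inherits(estimated, "triangle_mesh"), inherits(true, "triangle_mesh"))
  if (nrow(estimated$vertices) == 0 || nrow(true$vertices) == 0)
    stop("surface_deviation: empty mesh")
  dev <- point_mesh_distance(estimated$vertices, true, k_candidates)
  out <- list(per_vertex = dev, mean = mean(dev), sd = stats::sd(dev),
              max = max(dev))
  if (bidirectional) {
    rdev <- point_mesh_distance(true$vertices, estimated, k_candidates)
    out$reverse <- list(per_vertex = rdev, mean = mean(rdev),
                        sd = stats::sd(rdev), max = max(rdev))
    out$hausdorff <- max(out$max, out$reverse$max)
  }
  out
}

# min distance from each query point to a mesh; candidate triangles are
# those touching the k nearest mesh vertices
point_mesh_distance <- function(pts, mesh, k = 8L) {
  V <- mesh$vertices; Fc <- mesh$faces
  # triangles incident to each vertex
  vt <- split(rep(seq_len(nrow(Fc)), 3), as.vector(Fc))
  n <- nrow(pts)
  out <- numeric(n)
  # nearest vertices by chunked distance computation
  chunk <- max(1L, floor(2e7 / nrow(V)))
  Vn <- rowSums(V^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    P <- pts[s:e, , drop = FALSE]
    D2 <- outer(rowSums(P^2), Vn, "+") - 2 * tcrossprod(P, V)
    for (q in seq_len(nrow(P))) {
      nv <- order(D2[q, ])[seq_len(min(k, ncol(D2)))]
      cand <- unique(unlist(vt[as.character(nv)], use.names = FALSE))
      out[s + q - 1L] <- sqrt(min(vapply(cand, function(f)
        point_triangle_dist2(P[q, ], V[Fc[f, 1], ], V[Fc[f, 2], ],
                             V[Fc[f, 3], ]), 0)))
    }
  }
  out
}

# squared distance point-triangle (Eberly-style region decomposition)
point_triangle_dist2 <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sum((p - a)^2))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sum((p - b)^2))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sum((p - (a + t * ab))^2))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sum((p - c)^2))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sum((p - (a + t * ac))^2))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sum((p - (b + t * (c - b)))^2))
  }
  denom <- va + vb + vc
  v <- vb / denom; w <- vc / denom
  sum((p - (a + v * ab + w * ac))^2)
}

#' Voxelwise accuracy of an estimated parcellation against ground truth
#'
#' Per region: TP/FP/TN/FN voxel counts within the evaluation domain (the
#' bounding box of the union of both nonzero label sets, dilated by 3
#' voxels — counting the whole empty grid would inflate TN), the standard
#' accuracy `(TP + TN) / total`, an alternative truth-share ratio
#' `(TP + FN) / total` reported alongside for reference, and Dice.
#'
#' @param estimated,truth [label_volume]s on a shared grid.
#' @return data frame: region_id, tp, fp, tn, fn, accuracy,
#'   truth_share, dice.
#' @export
parcel_accuracy <- function(estimated, truth) {
  stop_if_grid_mismatch(estimated$grid, truth$grid, "estimated and truth")
  e <- estimated$labels; t <- truth$labels
  un <- e > 0 | t > 0
  if (!any(un)) stop("parcel_accuracy: both volumes empty")
  idx <- which(un, arr.ind = TRUE)
  d <- dim(e)
  lo <- pmax(apply(idx, 2, min) - 3L, 1L)
  hi <- pmin(apply(idx, 2, max) + 3L, d)
  eb <- e[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  tb <- t[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  tot <- length(eb)
  ids <- sort(union(unique(as.vector(eb)), unique(as.vector(tb))))
  ids <- ids[ids > 0]
  do.call(rbind, lapply(ids, function(r) {
    er <- eb == r; tr <- tb == r
    tp <- sum(er & tr); fp <- sum(er & !tr); fn <- sum(!er & tr)
    tn <- tot - tp - fp - fn
    data.frame(region_id = r, tp = tp, fp = fp, tn = tn, fn = fn,
               accuracy = (tp + tn) / tot,
               truth_share = (tp + fn) / tot,
               dice = if (tp + fp + fn == 0) NA_real_
               else 2 * tp / (2 * tp + fp + fn))
  }))
}

# smooth a binary mask for registration (FWHM 2 voxels, the standard
# channel for mask-based registration here)
smooth_mask <- function(mask_vol, fwhm = 2) {
  scalar_volume(mask_vol$grid,
                gaussian_smooth3(mask_vol$values, fwhm_to_sigma(fwhm)))
}

#' Leave-one-out reconstruction benchmark on a phantom cohort
#'
#' For each held-out specimen: a population template (endocast + paired
#' brain) is built from the remaining specimens, the held-out brain is
#' reconstructed from its endocast alone, and scored by surface deviation
#' against the true brain surface and parcel accuracy against the true
#' atlas labels (the template-frame atlas is obtained by registering the
#' canonical phantom's endocast to each fold's template). The
#' single-subject control reconstructs the same specimen using individual
#' donors instead of the template.
#'
#' @param cohort list of `phantom_specimen`s (>= 3) on one grid.
#' @param cfg a [reg_config].
#' @param n_outer template outer iterations (default 1 at benchmark scale).
#' @param n_donors single-subject donors per held-out specimen (default 2).
#' @param canonical the canonical phantom for the atlas (default: built at
#'   the cohort grid size).
#' @return list with `per_specimen` (data frame: specimen, method,
#'   deviation_mean, deviation_sd, mean_dice, mean_accuracy),
#'   `per_region` (region-level mean accuracy/Dice by method),
#'   `failures` (character).
#' @export
leave_one_out_reconstruction <- function(cohort, cfg = reg_config(),
                                         n_outer = 1L, n_donors = 3L,
                                         canonical = NULL) {
  stopifnot(length(cohort) >= 3)
  grid <- cohort[[1]]$grid
  if (is.null(canonical)) canonical <- canonical_phantom(grid$shape)
  atlas <- atlas_parcellation(canonical$atlas_truth, canonical$atlas_table)
  endos <- lapply(cohort, function(s) smooth_mask(endocast_mask(s$tissue)))
  brains <- lapply(cohort, function(s) smooth_mask(brain_mask(s$tissue)))
  canon_endo <- smooth_mask(endocast_mask(canonical$tissue))
  rows <- list(); region_rows <- list(); failures <- character(0)
  for (i in seq_along(cohort)) {
    res <- tryCatch({
      tb <- build_template(endos[-i], cfg, n_outer = n_outer,
                           paired = brains[-i])
      # atlas into the fold's template frame
      regc <- register_diffeo(tb$template, canon_endo, cfg)
      phic <- exp_velocity(regc$velocity, cfg$squaring_steps)
      atlas_tpl <- atlas_parcellation(
        warp_volume(atlas$labels, phic, mode = "nearest"), atlas$table)
      rec <- reconstruct_brain(tb$paired_template, tb$template, endos[[i]],
                               cfg, specimen_id = cohort[[i]]$id,
                               group = cohort[[i]]$group)
      score_reconstruction(rec, atlas_tpl, cohort[[i]], method = "template")
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s/template: %s", cohort[[i]]$id,
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      rows[[length(rows) + 1L]] <- res$summary
      region_rows[[length(region_rows) + 1L]] <- res$regions
    }
    donors <- setdiff(seq_along(cohort), i)
    # spread donors over the cohort rather than reusing the first few
    donors <- donors[round(seq(1, length(donors),
                               length.out = min(n_donors, length(donors))))]
    for (j in donors) {
      res <- tryCatch({
        atlas_j <- atlas_parcellation(cohort[[j]]$atlas_truth, atlas$table)
        rec <- reconstruct_brain(brains[[j]], endos[[j]], endos[[i]], cfg,
                                 specimen_id = cohort[[i]]$id,
                                 group = cohort[[i]]$group)
        # the donor control is scored on parcel accuracy only; surface
        # deviation is reported for the template route
        score_reconstruction(rec, atlas_j, cohort[[i]],
                             method = "single_subject",
                             compute_deviation = FALSE)
      }, error = function(e) {
        failures <<- c(failures, sprintf("%s/donor %s: %s", cohort[[i]]$id,
                                         cohort[[j]]$id, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        rows[[length(rows) + 1L]] <- res$summary
        region_rows[[length(region_rows) + 1L]] <- res$regions
      }
    }
  }
  per_specimen <- do.call(rbind, rows)
  regions <- do.call(rbind, region_rows)
  per_region <- stats::aggregate(cbind(accuracy, dice) ~ region_id + method,
                                 regions, mean)
  list(per_specimen = per_specimen, per_region = per_region,
       failures = failures)
}

score_reconstruction <- function(rec, atlas_frame, specimen, method,
                                 compute_deviation = TRUE) {
  if (compute_deviation) {
    true_brain <- smooth_mask(brain_mask(specimen$tissue))
    est_mesh <- extract_isosurface(rec$brain_prob, 0.5)
    true_mesh <- extract_isosurface(true_brain, 0.5)
    dev <- surface_deviation(est_mesh, true_mesh)
  } else {
    dev <- list(mean = NA_real_, sd = NA_real_)
  }
  parc <- transfer_atlas(atlas_frame, rec)
  acc <- parcel_accuracy(parc, specimen$atlas_truth)
  acc$specimen <- rec$specimen_id
  acc$method <- method
  list(summary = data.frame(
    specimen = rec$specimen_id, method = method,
    deviation_mean = dev$mean, deviation_sd = dev$sd,
    mean_dice = mean(acc$dice, na.rm = TRUE),
    mean_accuracy = mean(acc$accuracy),
    stringsAsFactors = FALSE), regions = acc)
}

#' Cross-cohort reconstruction test
#'
#' Reconstructs each specimen of cohort B from its endocast using cohort
#' A's average brain/endocast, and vice versa — the generalization test of
#' applying one species' template to another. Reports surface-deviation
#' summaries for both directions (always both, even when asymmetric).
#'
#' @param cohort_a,cohort_b lists of `phantom_specimen`s (shared grid).
#' @param cfg a [reg_config]; `n_outer` template iterations.
#' @return list `a_to_b` / `b_to_a`: data frames (specimen,
#'   deviation_mean, deviation_sd) plus direction-level `mean`, `sd`.
#' @export
cross_cohort_test <- function(cohort_a, cohort_b, cfg = reg_config(),
                              n_outer = 1L) {
  tpl <- function(cohort) {
    endos <- lapply(cohort, function(s) smooth_mask(endocast_mask(s$tissue)))
    brains <- lapply(cohort, function(s) smooth_mask(brain_mask(s$tissue)))
    tb <- build_template(endos, cfg, n_outer = n_outer, paired = brains)
    tb
  }
  ta <- tpl(cohort_a); tb <- tpl(cohort_b)
  run_dir <- function(tsrc, cohort) {
    rows <- lapply(cohort, function(spec) {
      rec <- reconstruct_brain(tsrc$paired_template, tsrc$template,
                               smooth_mask(endocast_mask(spec$tissue)), cfg,
                               specimen_id = spec$id, group = spec$group)
      dev <- surface_deviation(
        extract_isosurface(rec$brain_prob, 0.5),
        extract_isosurface(smooth_mask(brain_mask(spec$tissue)), 0.5))
      data.frame(specimen = spec$id, deviation_mean = dev$mean,
                 deviation_sd = dev$sd, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    list(per_specimen = df, mean = mean(df$deviation_mean),
         sd = stats::sd(df$deviation_mean))
  }
  list(a_to_b = run_dir(ta, cohort_b), b_to_a = run_dir(tb, cohort_a))
}
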