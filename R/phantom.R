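#' Canonical brain-inside-endocast phantom
#'
#' Deterministic synthetic "brain" used as the ground-truth anatomy for all
#' validation: two cerebral ellipsoidal hemispheres, two cerebellar lobes
#' and a midline vermis, each with a white-matter core and grey-matter
#' shell, surrounded by CSF inside a cranial cavity. Built mirror-symmetric
#' about the mid-sagittal (x) plane. Carries a 25-region atlas (12 regions
#' per hemisphere plus the cerebellar vermis, grouped into the 13 lobe
#' groups used by all volumetric statistics) and named landmarks on the
#' endocast surface.
#'
#' @param grid_shape integer triple, >= 32 per axis (default 48).
#' @return A `phantom_specimen`: list with `id`, `group`, `tissue`
#'   ([tissue_volume_set]), `t1_like` ([scalar_volume]), `atlas_truth`
#'   ([label_volume]), `landmarks` ([landmark_set]), `true_warp` (NULL for
#'   the canonical phantom) and `grid`.
#' @export
canonical_phantom <- function(grid_shape = c(48L, 48L, 48L)) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 32L))
    stop("canonical_phantom: grid too small to hold all parts (need >= 32)")
  grid <- voxel_grid(grid_shape)
  d <- grid_shape
  sc <- d / 48                       # proportions defined at 48^3
  ctr <- (d - 1) / 2
  ax <- lapply(1:3, function(a) seq_len(d[a]) - 1)
  X <- array(rep(ax[[1]], d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)

  inside_ellipsoid <- function(c0, r) {
    ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
      ((Z - c0[3]) / r[3])^2 <= 1
  }
  # y: posterior -> anterior; z: inferior -> superior; x: left -> right
  cer_r <- c(8.5, 13, 10) * sc
  cerL <- list(c0 = ctr + c(-7.5, 1.5, 2.5) * sc, r = cer_r)
  cerR <- list(c0 = ctr + c(+7.5, 1.5, 2.5) * sc, r = cer_r)
  cb_r <- c(5.5, 5, 4.5) * sc
  cbL <- list(c0 = ctr + c(-6, -11, -7.5) * sc, r = cb_r)
  cbR <- list(c0 = ctr + c(+6, -11, -7.5) * sc, r = cb_r)
  vm <- list(c0 = ctr + c(0, -11, -7.5) * sc, r = c(2.8, 4.5, 4) * sc)

  parts <- list(cerL = cerL, cerR = cerR, cbL = cbL, cbR = cbR, vm = vm)
  masks <- lapply(parts, function(p) inside_ellipsoid(p$c0, p$r))
  brain <- Reduce(`|`, masks)
  wm <- Reduce(`|`, lapply(parts, function(p)
    inside_ellipsoid(p$c0, p$r * 0.62)))
  gm <- brain & !wm

  # endocast = brain dilated ~2 voxels (CSF-filled cavity)
  sm <- gaussian_smooth3(array(as.numeric(brain), d), 1.6 * mean(sc))
  endo <- sm > 0.08
  csf <- endo & !brain

  gm_v <- scalar_volume(grid, array(as.numeric(gm), d))
  wm_v <- scalar_volume(grid, array(as.numeric(wm), d))
  csf_v <- scalar_volume(grid, array(as.numeric(csf), d))
  tissue <- tissue_volume_set(gm_v, wm_v, csf_v)

  atlas <- phantom_atlas(parts, masks, brain, X, Y, Z)
  lmk <- endocast_landmarks(grid, endo, ctr)

  structure(list(
    id = "canonical", group = "canonical", grid = grid,
    tissue = tissue,
    t1_like = t1_like_volume(tissue, noise_sd = 0, seed = 0L),
    atlas_truth = label_volume(grid, atlas$labels),
    atlas_table = atlas$table,
    landmarks = lmk,
    true_warp = NULL
  ), class = "phantom_specimen")
}

# split cerebral hemispheres into 10 lobe regions by (y, z) sectors and the
# cerebellar lobes into anterior/posterior; label layout mirrors an AAL-style
# 25-region scheme: regions 1..12 left, 13..24 right, 25 vermis
phantom_atlas <- function(parts, masks, brain, X, Y, Z) {
  d <- dim(X)
  lab <- array(0L, d)
  lobe_names <- c("Fr_SM", "Fr_I", "Fr_O", "Sm", "Pa_SI",
                  "Pa_TP", "Te_SM", "Te_I", "Oc_SM", "Oc_I")
  cer_region <- function(p, msk) {
    # y fraction within ellipsoid (posterior 0 -> anterior 1), z split
    yf <- (Y - (p$c0[2] - p$r[2])) / (2 * p$r[2])
    zs <- Z >= p$c0[3]
    r <- array(0L, d)
    # anterior (frontal) third: superior-medial / inferior / orbital
    r[msk & yf >= 2 / 3 & zs] <- 1L
    r[msk & yf >= 2 / 3 & !zs & Z >= p$c0[3] - p$r[3] / 2] <- 2L
    r[msk & yf >= 2 / 3 & !zs & Z < p$c0[3] - p$r[3] / 2] <- 3L
    # middle third: sensorimotor strip (sup), parietal SI, temporo-parietal,
    # temporal
    r[msk & yf >= 1 / 3 & yf < 2 / 3 & zs & yf >= 1 / 2] <- 4L
    r[msk & yf >= 1 / 3 & yf < 2 / 3 & zs & yf < 1 / 2] <- 5L
    r[msk & yf >= 1 / 3 & yf < 2 / 3 & !zs & yf >= 1 / 2] <- 6L
    r[msk & yf >= 1 / 3 & yf < 2 / 3 & !zs & yf < 1 / 2] <- 7L
    # posterior third: temporal inferior / occipital sup+mid / occipital inf
    r[msk & yf < 1 / 3 & !zs & Z < p$c0[3] - p$r[3] / 2] <- 8L
    r[msk & yf < 1 / 3 & zs] <- 9L
    r[msk & yf < 1 / 3 & !zs & Z >= p$c0[3] - p$r[3] / 2] <- 10L
    r
  }
  rL <- cer_region(parts$cerL, masks$cerL)
  rR <- cer_region(parts$cerR, masks$cerR)
  lab[rL > 0] <- rL[rL > 0]
  lab[rR > 0] <- rR[rR > 0] + 12L
  # cerebellum: anterior (y >= center) / posterior
  cb_ant <- function(p, msk) msk & (Y >= p$c0[2])
  lab[cb_ant(parts$cbL, masks$cbL)] <- 11L
  lab[masks$cbL & !cb_ant(parts$cbL, masks$cbL)] <- 12L
  lab[cb_ant(parts$cbR, masks$cbR)] <- 23L
  lab[masks$cbR & !cb_ant(parts$cbR, masks$cbR)] <- 24L
  lab[masks$vm] <- 25L
  lab[!brain] <- 0L

  table <- data.frame(
    region_id = 1:25,
    name = c(paste0(lobe_names, "_L"), "Ce_A_L", "Ce_P_L",
             paste0(lobe_names, "_R"), "Ce_A_R", "Ce_P_R", "Ce_V"),
    hemisphere = c(rep("L", 12), rep("R", 12), "midline"),
    lobe_group = c(lobe_names, "Ce_A", "Ce_P",
                   lobe_names, "Ce_A", "Ce_P", "Ce_V"),
    cerebellum = c(rep(FALSE, 10), TRUE, TRUE,
                   rep(FALSE, 10), TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  list(labels = lab, table = table)
}

# named landmarks: ray-cast from the endocast centroid to the 0.5 level of
# the smoothed endocast mask along fixed directions
endocast_landmarks <- function(grid, endo, ctr) {
  sm <- gaussian_smooth3(array(as.numeric(endo), dim(endo)), 1)
  dirs <- rbind(
    c(0, 1, 0), c(0, -1, 0), c(-1, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 0, -1),
    c(1, 1, 0), c(-1, 1, 0), c(1, -1, 0), c(-1, -1, 0),
    c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1)
  )
  dirs <- dirs / sqrt(rowSums(dirs^2))
  names <- c("anterior_pole", "posterior_pole", "left_pole", "right_pole",
             "vertex", "basion_like",
             "ant_right", "ant_left", "post_right", "post_left",
             "sup_right", "sup_left", "sup_anterior", "sup_posterior")
  pts <- matrix(0, nrow(dirs), 3)
  tt <- seq(0, max(dim(endo)), by = 0.25)
  for (i in seq_len(nrow(dirs))) {
    ray <- outer(tt, dirs[i, ]) + rep(ctr, each = length(tt))
    vals <- interp_array3(sm, ray)
    cross <- which(vals[-1] < 0.5 & vals[-length(vals)] >= 0.5)
    if (!length(cross)) stop("endocast_landmarks: ray misses surface")
    j <- cross[1]
    w <- (vals[j] - 0.5) / (vals[j] - vals[j + 1])
    pts[i, ] <- ray[j, ] + w * (ray[j + 1, ] - ray[j, ])
  }
  landmark_set(names, voxel_to_world(grid, pts))
}

# piecewise-constant T1-like intensities (GM 0.6, WM 1.0, CSF 0.2) + noise
t1_like_volume <- function(tissue, noise_sd = 0.05, seed = 0L) {
  d <- tissue$grid$shape
  vals <- 0.6 * tissue$gm$values + 1.0 * tissue$wm$values +
    0.2 * tissue$csf$values
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + array(rnorm(prod(d), 0, noise_sd), d)
  }
  scalar_volume(tissue$grid, vals)
}

#' Cohort specification for the phantom generator
#'
#' Group effect descriptors: `cerebellum_scale` is the *volumetric* factor
#' applied to the whole cerebellum (1 = none) and `right_scale` an
#' additional volumetric factor on its right half, emulating the smaller
#' and left-lateralized Neanderthal-like cerebellum. Individual variation
#' is a Gaussian-smoothed white-noise velocity field (smoothing FWHM
#' `warp_fwhm` voxels) scaled to RMS amplitude `variation_sd` voxels, so
#' every specimen is a diffeomorphic deformation of the canonical phantom.
#'
#' @param n_per_group specimens per group (>= 2).
#' @param grid_shape voxel grid (default 48^3).
#' @param groups named list: each element a list with optional
#'   `cerebellum_scale`, `right_scale` (volumetric factors > 0).
#' @param variation_sd RMS amplitude (voxels) of the random warps.
#' @param warp_fwhm smoothing FWHM of the random velocity (voxels).
#' @param noise_sd intensity noise of T1-like images.
#' @param seed integer master seed.
#' @export
cohort_spec <- function(n_per_group = 4L, grid_shape = c(48L, 48L, 48L),
                        groups = list(MH = list()),
                        variation_sd = 0.8, warp_fwhm = 8,
                        noise_sd = 0.05, seed = 1L) {
  stopifnot(n_per_group >= 2L, variation_sd >= 0)
  for (g in groups) {
    sc <- c(g$cerebellum_scale, g$right_scale)
    if (length(sc) && any(sc <= 0)) stop("cohort_spec: scale factors must be > 0")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_shape = as.integer(rep_len(grid_shape, 3L)),
                 groups = groups, variation_sd = variation_sd,
                 warp_fwhm = warp_fwhm, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# group-effect velocity: radial contraction fields over smooth region weights
group_effect_velocity <- function(canon, effect) {
  d <- canon$grid$shape
  v <- array(0, c(d, 3L))
  lab <- canon$atlas_truth$labels
  tbl <- canon$atlas_table
  add_scale <- function(v, region_mask, vol_scale, half = NULL) {
    if (vol_scale == 1) return(v)
    # weight ~1 over the region and its boundary, smooth decay outside:
    # dilate before smoothing so the region boundary sits on the plateau
    md <- region_mask
    for (i in 1:3) md <- dilate3(md)
    w <- pmin(gaussian_smooth3(array(as.numeric(md), d), 2) / 0.9, 1)
    idx <- which(region_mask)
    ijk <- arrayInd(idx, d)
    c0 <- colMeans(ijk) - 1
    # pull-back: specimen(x) = canonical(phi(x)); shrinking the specimen
    # region by linear factor a needs phi to dilate by 1/a about the centre
    lin_log <- -log(vol_scale) / 3         # volumetric -> linear, log scale
    pts <- grid_points(voxel_grid(d))
    for (c in 1:3)
      v[, , , c] <- v[, , , c] + lin_log * array((pts[, c] - c0[c]), d) * w
    v
  }
  cb_ids <- tbl$region_id[tbl$cerebellum]
  cb_mask <- array(lab %in% cb_ids, d)
  v <- add_scale(v, cb_mask, effect$cerebellum_scale %||% 1)
  if (!is.null(effect$right_scale) && effect$right_scale != 1) {
    right_ids <- tbl$region_id[tbl$cerebellum & tbl$hemisphere == "R"]
    # gate the lateralized field at the mid-sagittal plane so the left
    # side stays untouched (smooth ramp over ~3 voxels)
    xc <- (d[1] - 1) / 2
    pts <- grid_points(voxel_grid(d))
    gate <- array(stats::plogis((pts[, 1] - xc) / 0.75), d)
    vr <- add_scale(array(0, c(d, 3L)), array(lab %in% right_ids, d),
                    effect$right_scale)
    for (c in 1:3) v[, , , c] <- v[, , , c] + vr[, , , c] * gate
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# smoothed white-noise velocity, RMS-scaled; deterministic in seed
random_velocity <- function(d, fwhm, rms, seed) {
  set.seed(seed)
  v <- array(stats::rnorm(prod(d) * 3), c(d, 3L))
  sig <- fwhm_to_sigma(fwhm)
  for (c in 1:3) v[, , , c] <- gaussian_smooth3(v[, , , c], sig)
  cur <- sqrt(mean(v^2))
  if (cur > 0) v <- v * (rms / cur)
  v
}

#' Sample a phantom cohort with group effects and individual variation
#'
#' Each specimen is the canonical phantom pulled back through
#' `exp(v_group + v_indiv)`: the group-effect field (regional volumetric
#' scalings, applied first in construction) plus a random smooth individual
#' field. Ground-truth atlas labels and landmarks are carried through the
#' same deformation, so true regional volumes are known exactly by voxel
#' counting. Bit-reproducible given `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @return list of `phantom_specimen` objects (with `true_warp` holding the
#'   generative [velocity_field] and `true_deformation` its exponential).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  canon <- canonical_phantom(spec$grid_shape)
  d <- spec$grid_shape
  grid <- canon$grid
  out <- list()
  gi <- 0L
  for (gname in names(spec$groups)) {
    gi <- gi + 1L
    v_grp <- group_effect_velocity(canon, spec$groups[[gname]])
    for (i in seq_len(spec$n_per_group)) {
      sub_seed <- (spec$seed * 1000L + gi * 100L + i) %% .Machine$integer.max
      v_ind <- if (spec$variation_sd > 0)
        random_velocity(d, spec$warp_fwhm, spec$variation_sd, sub_seed)
      else array(0, c(d, 3L))
      v_tot <- v_grp + v_ind
      vf <- velocity_field(grid, v_tot)
      phi <- exp_velocity(vf, 6)
      tissue <- tissue_volume_set(
        warp_clip01(canon$tissue$gm, phi),
        warp_clip01(canon$tissue$wm, phi),
        warp_clip01(canon$tissue$csf, phi)
      )
      atlas <- warp_volume(canon$atlas_truth, phi, mode = "nearest")
      # landmarks follow the anatomy: pull-back means the specimen point x
      # maps to canonical phi(x); push landmarks forward through exp(-v)
      phin <- exp_velocity(velocity_field(grid, -v_tot), 6, interp = "linear")
      lmw <- world_to_voxel(grid, canon$landmarks$points)
      lmv <- lmw + cbind(interp_array3(phin$u[, , , 1], lmw),
                         interp_array3(phin$u[, , , 2], lmw),
                         interp_array3(phin$u[, , , 3], lmw))
      lmk <- landmark_set(canon$landmarks$names, voxel_to_world(grid, lmv))
      out[[length(out) + 1L]] <- structure(list(
        id = sprintf("%s_%02d", gname, i), group = gname, grid = grid,
        tissue = tissue,
        t1_like = t1_like_volume(tissue, spec$noise_sd, sub_seed + 7L),
        atlas_truth = atlas,
        atlas_table = canon$atlas_table,
        landmarks = lmk,
        true_warp = vf,
        true_deformation = phi
      ), class = "phantom_specimen")
    }
  }
  out
}

# warp a fraction map and clip to [0, 1] (interpolation overshoot guard)
warp_clip01 <- function(vol, phi) {
  w <- warp_volume(vol, phi)
  w$values[w$values < 0] <- 0
  w$values[w$values > 1] <- 1
  w
}

#' Ground-truth regional volumes of a phantom specimen (mm^3)
#'
#' Voxel counts of `atlas_truth` times the voxel volume.
#' @param specimen a `phantom_specimen`.
#' @return data frame (region_id, name, lobe_group, hemisphere, cerebellum,
#'   volume_mm3).
#' @export
true_parcel_volumes <- function(specimen) {
  lab <- specimen$atlas_truth$labels
  tbl <- specimen$atlas_table
  counts <- tabulate(lab[lab > 0], nbins = max(tbl$region_id))
  data.frame(tbl,
             volume_mm3 = counts[tbl$region_id] * specimen$grid$voxel_volume,
             row.names = NULL)
}

#' Damage an endocast mask with spherical holes
#'
#' @param specimen a `phantom_specimen` (or a binary [scalar_volume]
#'   endocast mask).
#' @param holes list of `list(center = voxel triple, radius = voxels)`.
#' @return list with `damaged` (binary [scalar_volume]), `hole_mask`
#'   (binary [scalar_volume]) and `intact` (the undamaged mask).
#' @export
damaged_endocast <- function(specimen, holes) {
  mask_vol <- if (inherits(specimen, "phantom_specimen"))
    endocast_mask(specimen$tissue) else specimen
  d <- mask_vol$grid$shape
  m <- mask_vol$values > 0.5
  hole <- array(FALSE, d)
  if (length(holes)) {
    ax <- lapply(1:3, function(a) seq_len(d[a]) - 1)
    X <- array(rep(ax[[1]], d[2] * d[3]), d)
    Y <- array(rep(rep(ax[[2]], each = d[1]), d[3]), d)
    Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
    for (h in holes) {
      hb <- (X - h$center[1])^2 + (Y - h$center[2])^2 +
        (Z - h$center[3])^2 <= h$radius^2
      if (!any(hb & m))
        stop("damaged_endocast: hole does not intersect the endocast")
      hole <- hole | hb
    }
  }
  surf <- m & !erode3(m)
  if (length(holes) && sum(hole & surf) > 0.3 * sum(surf))
    stop("damaged_endocast: holes cover more than 30% of the surface")
  damaged <- m & !hole
  list(
    damaged = scalar_volume(mask_vol$grid, array(as.numeric(damaged), d)),
    hole_mask = scalar_volume(mask_vol$grid, array(as.numeric(hole & m), d)),
    intact = scalar_volume(mask_vol$grid, array(as.numeric(m), d))
  )
}

# 6-connected binary erosion
erode3 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(m, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    do.call(`[`, c(list(m), src))
  }
  for (ax in 1:3) out <- out & shift(m, ax, 1L) & shift(m, ax, -1L)
  out
}

dilate3 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(m, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    do.call(`[`, c(list(m), src))
  }
  for (ax in 1:3) out <- out | shift(m, ax, 1L) | shift(m, ax, -1L)
  out
}

#' Synthetic cognition-score table with known generative slopes
#'
#' Generates `n` subjects with ICV, age, sex, seven exogenous task scores
#' (standard normal plus optional confound loadings) and a regional
#' (cerebellar-like) volume that is linear in ICV, age and sex plus
#' `sum(beta_per_task * score)` plus Gaussian noise — the same direction as
#' the analysis model fitted by [cognition_regression], so the generative
#' slopes are recovered exactly in the noiseless case.
#'
#' @param n subjects (>= 20).
#' @param beta_per_task numeric length 7, volume change (cc) per score unit.
#' @param confound_sds named list/vector with `icv`, `age_range`, and task
#'   confound loading `task_icv_load` (defaults sized to HCP-like data).
#' @param noise_sd residual SD of the volume (cc).
#' @param seed integer.
#' @return data frame with subject, task_1..task_7, icv, age, sex, volume,
#'   and attribute `beta_per_task`.
#' @export
cognition_table <- function(n, beta_per_task = rep(0, 7),
                            confound_sds = list(icv = 120, age_range = c(22, 36),
                                                task_icv_load = 0.2),
                            noise_sd = 8, seed = 1L) {
  stopifnot(n >= 20, length(beta_per_task) == 7)
  set.seed(seed)
  icv <- stats::rnorm(n, 1500, confound_sds$icv %||% 120)
  ar <- confound_sds$age_range %||% c(22, 36)
  age <- stats::runif(n, ar[1], ar[2])
  sex <- stats::rbinom(n, 1, 0.5)
  icv_z <- (icv - mean(icv)) / stats::sd(icv)
  load <- confound_sds$task_icv_load %||% 0.2
  scores <- matrix(stats::rnorm(n * 7), n, 7)
  scores <- scores + load * icv_z
  vol <- 140 + 0.06 * (icv - 1500) - 0.3 * (age - mean(ar)) + 4 * sex +
    scores %*% beta_per_task + stats::rnorm(n, 0, noise_sd)
  df <- data.frame(subject = seq_len(n), scores, icv = icv, age = age,
                   sex = sex, volume = as.vector(vol))
  names(df)[2:8] <- paste0("task_", 1:7)
  attr(df, "beta_per_task") <- beta_per_task
  df
}
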