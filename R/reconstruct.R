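#' Atlas parcellation container
#'
#' Couples a label volume in template frame with its region table. The
#' table must carry one row per label id with the hemisphere, the lobe
#' group (the 13 groups used for all volumetric statistics) and a
#' cerebellum flag.
#'
#' @param labels a [label_volume] in the template frame.
#' @param table data frame with columns `region_id`, `name`, `hemisphere`
#'   (`"L"`, `"R"`, `"midline"`), `lobe_group`, `cerebellum` (logical).
#' @export
atlas_parcellation <- function(labels, table) {
  stopifnot(inherits(labels, "label_volume"), is.data.frame(table))
  need <- c("region_id", "name", "hemisphere", "lobe_group", "cerebellum")
  if (!all(need %in% names(table)))
    stop("atlas_parcellation: table missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  ids <- sort(unique(as.vector(labels$labels)))
  ids <- ids[ids > 0]
  orphan <- setdiff(ids, table$region_id)
  if (length(orphan))
    stop("atlas_parcellation: labels without table rows: ",
         paste(orphan, collapse = ", "))
  structure(list(labels = labels, table = table),
            class = "atlas_parcellation")
}

#' Reconstruct a brain inside a fossil endocast
#'
#' The core inference: the fossil endocast is affinely pre-aligned to the
#' population-average endocast, a diffeomorphic deformation from the
#' aligned fossil endocast to the average endocast is estimated
#' ([register_diffeo]; the fossil is the moving image), and the average
#' brain is transformed back into the fossil frame through the inverse
#' exponential. The same stored deformation later transports the atlas
#' ([transfer_atlas]).
#'
#' @param avg_brain,avg_endocast [scalar_volume]s in template frame
#'   (smooth probabilistic masks).
#' @param fossil_endocast binary/smooth [scalar_volume], native fossil frame.
#' @param cfg a [reg_config].
#' @param specimen_id,group identifiers carried through to outputs.
#' @return A `reconstructed_brain`: `brain_mask` (binary [scalar_volume] in
#'   the native fossil frame), `brain_prob` (pre-threshold), `icv` (mm^3,
#'   from the fossil endocast), `deformation_used` (list: `affine` A
#'   mapping fossil world to template world, `velocity` template-frame
#'   [velocity_field], `squaring_steps`), `registration` diagnostics.
#' @export
reconstruct_brain <- function(avg_brain, avg_endocast, fossil_endocast,
                              cfg = reg_config(), specimen_id = "fossil",
                              group = NA_character_) {
  stopifnot(inherits(avg_brain, "scalar_volume"),
            inherits(avg_endocast, "scalar_volume"))
  tpl_grid <- avg_endocast$grid
  A <- affine_prealign(avg_endocast, fossil_endocast)
  fossil_aligned <- apply_affine(fossil_endocast, A, tpl_grid)
  reg <- tryCatch(
    register_diffeo(avg_endocast, fossil_aligned, cfg),
    error = function(e)
      stop(sprintf("reconstruct_brain[%s]: registration failed: %s",
                   specimen_id, conditionMessage(e)))
  )
  # phi = exp(v) maps template voxel -> aligned-fossil voxel;
  # the brain in the aligned fossil frame is avg_brain pulled through exp(-v)
  phin <- exp_velocity(velocity_field(tpl_grid, -reg$velocity$v),
                       cfg$squaring_steps)
  brain_aligned <- warp_volume(avg_brain, phin)
  # back to the native fossil frame through the inverse affine
  brain_native <- apply_affine(brain_aligned, solve(A), fossil_endocast$grid)
  bm <- scalar_volume(fossil_endocast$grid,
                      array(as.numeric(brain_native$values >= 0.5),
                            fossil_endocast$grid$shape))
  structure(list(
    specimen_id = specimen_id, group = group,
    brain_mask = bm, brain_prob = brain_native,
    icv = sum(fossil_endocast$values >= 0.5) *
      fossil_endocast$grid$voxel_volume,
    deformation_used = list(affine = A, velocity = reg$velocity,
                            squaring_steps = cfg$squaring_steps),
    registration = reg[c("msd_initial", "msd_final", "converged")]
  ), class = "reconstructed_brain")
}

#' Transfer an atlas parcellation into the fossil frame
#'
#' Pulls atlas labels from the template frame through the same deformation
#' used for the brain (inverse exponential, then inverse affine), with
#' nearest-label sampling — labels can disappear but never be invented.
#'
#' @param atlas an [atlas_parcellation] in template frame.
#' @param recon a `reconstructed_brain` (or its `deformation_used` list
#'   plus a `target_grid`).
#' @param target_grid native fossil grid (taken from `recon` if present).
#' @param mask_to_brain zero labels outside the reconstructed brain mask
#'   dilated by 1 voxel (default TRUE when `recon` carries a mask).
#' @return [label_volume] in the fossil frame.
#' @export
transfer_atlas <- function(atlas, recon, target_grid = NULL,
                           mask_to_brain = TRUE) {
  stopifnot(inherits(atlas, "atlas_parcellation"))
  def <- if (inherits(recon, "reconstructed_brain"))
    recon$deformation_used else recon
  if (is.null(target_grid)) {
    if (!inherits(recon, "reconstructed_brain"))
      stop("transfer_atlas: target_grid required")
    target_grid <- recon$brain_mask$grid
  }
  stop_if_grid_mismatch(atlas$labels$grid, def$velocity$grid,
                        "atlas and deformation frames")
  phin <- exp_velocity(velocity_field(def$velocity$grid, -def$velocity$v),
                       def$squaring_steps %||% 6L)
  lab_aligned <- warp_volume(atlas$labels, phin, mode = "nearest")
  out <- apply_affine(lab_aligned, solve(def$affine), target_grid)
  if (mask_to_brain && inherits(recon, "reconstructed_brain")) {
    keep <- dilate3(recon$brain_mask$values > 0.5)
    l <- out$labels
    l[!keep] <- 0L
    out <- label_volume(target_grid, l)
  }
  out
}

#' Regional volumes from a parcellation
#'
#' Voxel counts times voxel volume, aggregated by region, by the 13 lobe
#' groups, by hemisphere, and split into cerebrum vs cerebellum.
#'
#' @param parcels a [label_volume].
#' @param table atlas region table (see [atlas_parcellation]).
#' @return list with `regions` (data frame region_id, name, lobe_group,
#'   hemisphere, cerebellum, volume_mm3), `lobe_groups`, `hemispheres`,
#'   `cerebrum_mm3`, `cerebellum_mm3`, `total_mm3`.
#' @export
parcel_volumes <- function(parcels, table) {
  stopifnot(inherits(parcels, "label_volume"))
  lab <- parcels$labels
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  orphan <- setdiff(ids, table$region_id)
  if (length(orphan))
    stop("parcel_volumes: orphan label ids: ", paste(orphan, collapse = ", "))
  counts <- tabulate(lab[lab > 0], nbins = max(table$region_id))
  vv <- parcels$grid$voxel_volume
  regions <- data.frame(table,
                        volume_mm3 = counts[table$region_id] * vv,
                        row.names = NULL)
  lg <- stats::aggregate(volume_mm3 ~ lobe_group, regions, sum)
  hemi <- stats::aggregate(volume_mm3 ~ hemisphere, regions, sum)
  list(regions = regions,
       lobe_groups = lg,
       hemispheres = hemi,
       cerebrum_mm3 = sum(regions$volume_mm3[!regions$cerebellum]),
       cerebellum_mm3 = sum(regions$volume_mm3[regions$cerebellum]),
       total_mm3 = sum(regions$volume_mm3))
}

#' Pseudo-cohorts: individual variation composed onto fossil deformations
#'
#' For every (individual, fossil) pair, composes the individual's
#' template-space warp with the fossil's inverse deformation and measures
#' atlas parcel volumes through the combined map — the device used to
#' expand a handful of fossils into a pseudo-population whose within-group
#' shape variation equals the living cohort's.
#'
#' @param individual_warps list of template-frame [velocity_field]s (one
#'   per living individual, as returned by [build_template]).
#' @param fossil_recons list of `reconstructed_brain`s (their stored
#'   deformations are reused).
#' @param atlas an [atlas_parcellation] in template frame.
#' @param squaring_steps scaling-and-squaring steps.
#' @return data frame: individual, fossil, group, region_id, lobe_group,
#'   cerebellum, volume_mm3 (native fossil scale).
#' @export
expand_fossil_variation <- function(individual_warps, fossil_recons, atlas,
                                    squaring_steps = 6L) {
  stopifnot(length(individual_warps) >= 1, length(fossil_recons) >= 1)
  grid <- atlas$labels$grid
  rows <- list()
  for (fi in seq_along(fossil_recons)) {
    rec <- fossil_recons[[fi]]
    def <- rec$deformation_used
    stop_if_grid_mismatch(grid, def$velocity$grid, "atlas and fossil frames")
    phin_f <- exp_velocity(velocity_field(grid, -def$velocity$v),
                           squaring_steps)
    scale_native <- 1 / det(def$affine[1:3, 1:3])   # aligned -> native mm^3
    for (ii in seq_along(individual_warps)) {
      vi <- individual_warps[[ii]]
      stop_if_grid_mismatch(grid, vi$grid, "atlas and individual frames")
      phi_i <- exp_velocity(vi, squaring_steps)
      comp <- compose_deformation(phi_i, phin_f)
      lab <- warp_volume(atlas$labels, comp, mode = "nearest")
      pv <- parcel_volumes(lab, atlas$table)
      df <- pv$regions[, c("region_id", "lobe_group", "cerebellum",
                           "volume_mm3")]
      df$volume_mm3 <- df$volume_mm3 * scale_native
      df$individual <- ii
      df$fossil <- rec$specimen_id
      df$group <- rec$group
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  out[, c("individual", "fossil", "group", "region_id", "lobe_group",
          "cerebellum", "volume_mm3")]
}
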