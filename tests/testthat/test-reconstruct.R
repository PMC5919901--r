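# global radial expansion field (pull-back => shrinks the anatomy)
scale_field <- function(g) {
  d <- g$shape
  ctr <- (d - 1) / 2
  pts <- paleobrain:::grid_points(g)
  v <- array(0, c(d, 3))
  for (c in 1:3) v[, , , c] <- array(pts[, c] - ctr[c], d)
  v
}

test_that("atlas transfer through trivial deformations is exact", {
  ph <- canonical_32()
  g <- ph$grid
  atlas <- atlas_parcellation(ph$atlas_truth, ph$atlas_table)
  fake_recon <- list(affine = diag(4),
                     velocity = velocity_field(g, array(0, c(g$shape, 3))),
                     squaring_steps = 6L)
  out <- transfer_atlas(atlas, fake_recon, target_grid = g)
  expect_identical(out$labels, ph$atlas_truth$labels)

  # pure translation moves labels by the translation: the affine maps
  # fossil world to template world + 3, so fossil voxel x reads the
  # template at x + 3
  tr <- fake_recon
  tr$affine[1:3, 4] <- c(3, 0, 0)
  out_t <- transfer_atlas(atlas, tr, target_grid = g)
  expect_identical(out_t$labels[1:29, , ], ph$atlas_truth$labels[4:32, , ])

  # labels can vanish but are never invented
  v <- smooth_test_field(c(32, 32, 32), seed = 5, vmax = 1.2)
  wr <- list(affine = diag(4), velocity = velocity_field(g, v),
             squaring_steps = 6L)
  out_w <- transfer_atlas(atlas, wr, target_grid = g)
  expect_true(all(unique(as.vector(out_w$labels)) %in%
                    c(0L, unique(as.vector(ph$atlas_truth$labels)))))
})

test_that("parcel volumes aggregate exactly", {
  d <- c(20, 20, 20)
  g <- voxel_grid(d)
  lab <- array(0L, d)
  lab[1:10, 1:10, 1:10] <- 1L   # 1000 voxels
  lab[11:20, 1:10, 1:10] <- 2L
  tbl <- data.frame(region_id = 1:2, name = c("a", "b"),
                    hemisphere = c("L", "R"), lobe_group = c("g1", "g2"),
                    cerebellum = c(FALSE, TRUE))
  pv <- parcel_volumes(label_volume(g, lab), tbl)
  expect_equal(pv$regions$volume_mm3[1], 1000)
  expect_equal(sum(pv$lobe_groups$volume_mm3), sum(pv$regions$volume_mm3))
  expect_equal(pv$cerebellum_mm3, 1000)
  expect_equal(pv$cerebrum_mm3, 1000)
  expect_error(parcel_volumes(label_volume(g, lab),
                              tbl[1, , drop = FALSE]), "orphan")

  # phantom ground truth equals direct voxel counting
  ph <- canonical_32()
  pv2 <- parcel_volumes(ph$atlas_truth, ph$atlas_table)
  tv <- true_parcel_volumes(ph)
  expect_equal(pv2$regions$volume_mm3, tv$volume_mm3)
  expect_equal(sum(tapply(pv2$regions$volume_mm3, pv2$regions$lobe_group,
                          sum)),
               sum(pv2$regions$volume_mm3))
})

test_that("reconstruction recovers a brain deformed by a known diffeomorphism", {
  ph <- canonical_48()
  g <- ph$grid
  avg_endo <- paleobrain:::smooth_mask(endocast_mask(ph$tissue))
  avg_brain <- paleobrain:::smooth_mask(brain_mask(ph$tissue))
  # identity: the average brain comes back unchanged
  rec0 <- reconstruct_brain(avg_brain, avg_endo, avg_endo,
                            reg_config(iters_per_level = c(20, 12, 6)))
  e0 <- rec0$brain_mask$values > 0.5
  t0 <- avg_brain$values >= 0.5
  expect_gte(2 * sum(e0 & t0) / (sum(e0) + sum(t0)), 0.99)

  # known generative warp at the cohort-default amplitude
  v <- paleobrain:::random_velocity(g$shape, 8, 0.8, 77)
  phi_true <- exp_velocity(velocity_field(g, v), 6)
  fossil_endo <- warp_volume(avg_endo, phi_true)
  true_brain <- warp_volume(avg_brain, phi_true)
  rec <- cached("recon48", reconstruct_brain(avg_brain, avg_endo, fossil_endo,
                                             reg_config()))
  est <- rec$brain_mask$values > 0.5
  tru <- true_brain$values >= 0.5
  expect_gte(2 * sum(est & tru) / (sum(est) + sum(tru)), 0.95)

  # a smaller endocast yields a smaller reconstructed brain
  shrink <- velocity_field(g, paleobrain:::group_effect_velocity(
    ph, list(cerebellum_scale = 1)) + 0.08 * scale_field(g))
  phi_s <- exp_velocity(shrink, 6)
  small_endo <- warp_volume(avg_endo, phi_s)
  rec_small <- reconstruct_brain(avg_brain, avg_endo, small_endo,
                                 reg_config(iters_per_level = c(20, 12, 6)))
  expect_lt(sum(rec_small$brain_mask$values), sum(rec0$brain_mask$values))
})

test_that("pseudo-cohort expansion composes individual and fossil warps", {
  ph <- canonical_32()
  g <- ph$grid
  atlas <- atlas_parcellation(ph$atlas_truth, ph$atlas_table)
  zero_rec <- function(id, grp) {
    structure(list(specimen_id = id, group = grp,
                   brain_mask = brain_mask(ph$tissue),
                   deformation_used = list(
                     affine = diag(4),
                     velocity = velocity_field(g, array(0, c(g$shape, 3))),
                     squaring_steps = 6L)),
              class = "reconstructed_brain")
  }
  iw <- list(velocity_field(g, array(0, c(g$shape, 3))),
             velocity_field(g, smooth_test_field(c(32, 32, 32), 3, vmax = 1)),
             velocity_field(g, smooth_test_field(c(32, 32, 32), 4, vmax = 1)))
  fr <- list(zero_rec("f1", "NT"), zero_rec("f2", "NT"))
  out <- expand_fossil_variation(iw, fr, atlas)
  expect_equal(nrow(out), 3 * 2 * 25)
  expect_setequal(unique(out$fossil), c("f1", "f2"))
  # identity individual x identity fossil reproduces the plain atlas volumes
  plain <- parcel_volumes(ph$atlas_truth, ph$atlas_table)
  sub <- out[out$individual == 1 & out$fossil == "f1", ]
  expect_equal(sub$volume_mm3[order(sub$region_id)],
               plain$regions$volume_mm3[order(plain$regions$region_id)])
})
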