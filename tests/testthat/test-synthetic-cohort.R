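test_that("canonical phantom has the expected anatomy and bookkeeping", {
  ph <- canonical_32()
  lab <- ph$atlas_truth$labels
  ids <- sort(unique(as.vector(lab[lab > 0])))
  expect_gte(length(ids), 25)
  expect_true(all(ids %in% ph$atlas_table$region_id))
  expect_equal(sum(table(ph$atlas_table$lobe_group) > 0), 13)
  expect_gte(length(ph$landmarks$names), 12)
  # built mirror-symmetric about the x centre plane
  bm <- brain_mask(ph$tissue)$values > 0
  expect_identical(bm, bm[dim(bm)[1]:1, , ])
  # one connected endocast component
  em <- endocast_mask(ph$tissue)$values > 0
  expect_equal(n_components(em), 1L)
  expect_error(canonical_phantom(c(16, 16, 16)), "too small")
})

test_that("cohort sampling is reproducible and degenerates to the canonical", {
  spec <- cohort_spec(n_per_group = 2, grid_shape = c(32, 32, 32),
                      variation_sd = 0.5, warp_fwhm = 6, seed = 9)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a[[1]]$tissue$gm$values, b[[1]]$tissue$gm$values)
  expect_identical(a[[2]]$t1_like$values, b[[2]]$t1_like$values)

  spec0 <- cohort_spec(n_per_group = 2, grid_shape = c(32, 32, 32),
                       variation_sd = 0, noise_sd = 0, seed = 1)
  c0 <- sample_cohort(spec0)
  ph <- canonical_32()
  expect_equal(c0[[1]]$tissue$gm$values, ph$tissue$gm$values)
  expect_identical(c0[[1]]$atlas_truth$labels, ph$atlas_truth$labels)
})

test_that("a cerebellar volumetric scale factor is realized in ground truth", {
  coh <- cached("scale_cohort", sample_cohort(
    cohort_spec(n_per_group = 12,
                groups = list(NT = list(cerebellum_scale = 0.85)),
                seed = 5)))
  ph <- canonical_48()
  canon_cb <- sum(ph$atlas_truth$labels %in%
                    ph$atlas_table$region_id[ph$atlas_table$cerebellum])
  cb_ids <- ph$atlas_table$region_id[ph$atlas_table$cerebellum]
  ratios <- vapply(coh, function(s)
    sum(s$atlas_truth$labels %in% cb_ids) / canon_cb, 0)
  expect_gte(mean(ratios), 0.80)
  expect_lte(mean(ratios), 0.90)
})

test_that("specimens stay topologically intact under the generative warps", {
  coh <- cached("mh_cohort_32", sample_cohort(
    cohort_spec(n_per_group = 4, grid_shape = c(32, 32, 32),
                variation_sd = 0.8, warp_fwhm = 6, seed = 11)))
  for (s in coh[1:2]) {
    jd <- jacobian_determinant(s$true_deformation)
    ii <- interior_idx(c(32, 32, 32), 2)
    expect_gt(min(jd$values[ii[[1]], ii[[2]], ii[[3]]]), 0)
    expect_equal(n_components(endocast_mask(s$tissue)$values > 0), 1L)
  }
})

test_that("endocast damage removes exactly the requested voxels", {
  ph <- canonical_32()
  em <- endocast_mask(ph$tissue)
  none <- damaged_endocast(ph, list())
  expect_equal(none$damaged$values, em$values)

  ctr <- ph$landmarks$points[5, ]  # vertex landmark, world == voxel here
  one <- damaged_endocast(ph, list(list(center = ctr, radius = 4)))
  diffidx <- which(one$damaged$values != em$values)
  expect_true(all(one$hole_mask$values[diffidx] == 1))
  expect_gt(length(diffidx), 0)

  two <- damaged_endocast(ph, list(
    list(center = ph$landmarks$points[1, ], radius = 3),
    list(center = ph$landmarks$points[2, ], radius = 3)))
  h1 <- damaged_endocast(ph, list(list(center = ph$landmarks$points[1, ],
                                       radius = 3)))
  h2 <- damaged_endocast(ph, list(list(center = ph$landmarks$points[2, ],
                                       radius = 3)))
  expect_equal(sum(two$hole_mask$values),
               sum(h1$hole_mask$values) + sum(h2$hole_mask$values))

  expect_error(damaged_endocast(ph, list(list(center = ctr, radius = 40))),
               "30%")
  expect_error(damaged_endocast(ph, list(list(center = c(0, 0, 0),
                                              radius = 2))),
               "intersect")
})

test_that("cognition tables have the stated regression structure", {
  # exact recovery without noise
  ct <- cognition_table(200, beta_per_task = c(2, 0, 0, 0, 0, 0, 0),
                        noise_sd = 0, seed = 3)
  fit <- suppressWarnings(cognition_regression(ct))
  expect_lt(abs(fit$slope[1] - 2), 1e-8)
  # df bookkeeping at the full-cohort size
  ct2 <- cognition_table(1095, seed = 1)
  expect_equal(unique(cognition_regression(ct2)$df), 1090)
  # type-I error of nominal tests under beta = 0
  hits <- 0; total <- 0
  for (rep in 1:20) {
    ct0 <- cognition_table(500, beta_per_task = rep(0, 7), seed = 100 + rep)
    cr <- cognition_regression(ct0)
    hits <- hits + sum(cr$p < 0.05)
    total <- total + nrow(cr)
  }
  expect_gte(hits / total, 0.01)
  expect_lte(hits / total, 0.12)
})
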