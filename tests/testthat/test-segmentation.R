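seg_dice <- function(seg, tissue) {
  truth <- 1L * (tissue$csf$values > 0.5) + 2L * (tissue$gm$values > 0.5) +
    3L * (tissue$wm$values > 0.5)
  est <- seg$hard_labels$labels
  vapply(1:3, function(c) {
    2 * sum(est == c & truth == c) / (sum(est == c) + sum(truth == c))
  }, 0)
}

test_that("a noiseless three-level phantom is segmented essentially perfectly", {
  ph <- canonical_32()
  t1 <- paleobrain:::t1_like_volume(ph$tissue, noise_sd = 0)
  seg <- segment_em(t1, endocast_mask(ph$tissue), seed = 2)
  expect_true(all(seg_dice(seg, ph$tissue) >= 0.999))
  expect_true(all(diff(seg$class_means) > 0))
})

test_that("noisy phantoms reach Dice 0.95 per class and EM is monotone", {
  coh <- cached("scale_cohort", sample_cohort(
    cohort_spec(n_per_group = 12,
                groups = list(NT = list(cerebellum_scale = 0.85)),
                seed = 5)))
  s <- coh[[1]]
  seg <- segment_em(s$t1_like, endocast_mask(s$tissue), seed = 2)
  expect_true(all(seg_dice(seg, s$tissue) >= 0.95))
  expect_true(all(diff(seg$loglik_trace) >= -1e-8 * abs(seg$loglik_trace[-1])))
  # class order is resolved to CSF < GM < WM regardless of init seed
  seg2 <- segment_em(s$t1_like, endocast_mask(s$tissue), seed = 77)
  expect_true(all(diff(seg2$class_means) > 0))
  expect_error(segment_em(paleobrain:::t1_like_volume(s$tissue, 0) , NULL,
                          max_iter = 2),
               NA)  # non-convergence is reported, not an error
})

test_that("masks and ICV follow the tissue-fraction definitions", {
  d <- c(10, 10, 10)
  g <- voxel_grid(d)
  zero <- scalar_volume(g, array(0, d))
  csf_only <- tissue_volume_set(zero, zero, scalar_volume(g, array(1, d)))
  expect_equal(icv(csf_only), 1000)
  expect_equal(sum(brain_mask(csf_only)$values), 0)
  expect_equal(sum(endocast_mask(csf_only)$values), 1000)
  empty <- tissue_volume_set(zero, zero, zero)
  expect_equal(icv(empty), 0)
  # brain mask is contained in the endocast mask for arbitrary fractions
  set.seed(8)
  for (rep in 1:5) {
    raw <- array(runif(prod(d) * 3), c(d, 3))
    tot <- raw[, , , 1] + raw[, , , 2] + raw[, , , 3]
    sc <- pmax(tot, 1)
    tt <- tissue_volume_set(scalar_volume(g, raw[, , , 1] / sc),
                            scalar_volume(g, raw[, , , 2] / sc),
                            scalar_volume(g, raw[, , , 3] / sc))
    expect_true(all(brain_mask(tt)$values <= endocast_mask(tt)$values))
  }
  # soft vs hard ICV agree within the partial-volume mass on phantoms
  ph <- canonical_32()
  expect_lt(abs(icv(ph$tissue, "soft") - icv(ph$tissue, "hard")) /
              icv(ph$tissue, "soft"), 0.05)
})

test_that("degenerate segmentation inputs are rejected", {
  g <- voxel_grid(c(8, 8, 8))
  flat <- scalar_volume(g, array(1, c(8, 8, 8)))
  expect_error(segment_em(flat), "distinct intensities")
  expect_error(segment_em(flat, scalar_volume(g, array(0, c(8, 8, 8)))),
               "empty head mask")
})

test_that("EM class means agree with an independent mixture fit", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  ph <- canonical_32()
  t1 <- paleobrain:::t1_like_volume(ph$tissue, noise_sd = 0.05, seed = 14)
  msk <- endocast_mask(ph$tissue)$values > 0.5
  seg <- segment_em(t1, endocast_mask(ph$tissue), seed = 2)
  ref <- Mclust(t1$values[msk], G = 3, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(ref$parameters$mean) - seg$class_means)), 0.02)
})
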