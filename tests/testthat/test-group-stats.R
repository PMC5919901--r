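fossil_table <- function() {
  data.frame(
    specimen = c("Amud1", "LaChapelle1", "LaFerrassie1", "ForbesQuarry1",
                 "Qafzeh9", "Skhul5", "Mladec1", "CroMagnon1"),
    group = rep(c("NT", "EH"), each = 4),
    cerebrum = c(1304, 1159, 1268, 912, 1075, 1053, 1205, 1208),
    cerebellum = c(182, 140, 166, 106, 147, 146, 165, 156),
    stringsAsFactors = FALSE)
}

test_that("volume summaries agree with a two-pass computation", {
  tab <- fossil_table()
  vs <- volume_summary(tab)
  nt <- tab[tab$group == "NT", ]
  m2 <- sum(nt$cerebrum) / 4
  s2 <- sqrt(sum((nt$cerebrum - m2)^2) / 3)
  expect_equal(vs$cerebral_mean[vs$group == "NT"], m2, tolerance = 1e-12)
  expect_equal(vs$cerebral_sd[vs$group == "NT"], s2, tolerance = 1e-12)
  r <- nt$cerebellum / nt$cerebrum
  expect_equal(vs$ratio_mean[vs$group == "NT"], mean(r), tolerance = 1e-12)
  # identical specimens: zero SD, ratio equals the individual ratio
  same <- data.frame(group = "X", cerebrum = rep(1000, 3),
                     cerebellum = rep(130, 3))
  vs2 <- volume_summary(same)
  expect_equal(vs2$cerebral_sd, 0)
  expect_equal(vs2$ratio_mean, 0.13)
  expect_warning(volume_summary(data.frame(group = "X", cerebrum = 1,
                                           cerebellum = 1)), "size 1")
})

test_that("ICV adjustment residualizes exactly", {
  set.seed(4)
  icv_v <- rnorm(60, 1500, 100)
  tab <- data.frame(region = "r", icv = icv_v,
                    volume = 100 + 0.04 * icv_v + rnorm(60, 0, 3))
  adj <- icv_adjust(tab)
  expect_lt(abs(stats::cor(adj$volume_adj, adj$icv)), 1e-10)
  # slope recovery on noiseless data
  tab2 <- data.frame(region = "r", icv = icv_v, volume = 5 + 0.07 * icv_v)
  fit <- stats::lm(volume ~ icv, tab2)
  expect_lt(abs(unname(stats::coef(fit)[2]) - 0.07), 1e-6)
  # shift invariance
  tab3 <- tab; tab3$icv <- tab3$icv + 500
  expect_equal(icv_adjust(tab3)$volume_adj, adj$volume_adj,
               tolerance = 1e-10)
  expect_error(icv_adjust(data.frame(volume = 1:3, icv = rep(1, 3))),
               "constant")
})

test_that("one-way ANOVA bookkeeping matches the full-cohort degrees of freedom", {
  set.seed(2)
  g <- rep(c("NT", "EH", "MH"), c(4, 4, 1185))
  ar <- anova_ryan(rnorm(1193), g)
  expect_equal(ar$omnibus$df2, 1190)
  expect_equal(unique(ar$pairwise$df), 1190)
  # identical groups: F = 0, nothing significant
  ar0 <- anova_ryan(rep(c(1, 2, 3), times = 3),
                    rep(c("a", "b", "c"), each = 3))
  expect_equal(ar0$omnibus$F, 0)
  expect_false(any(ar0$pairwise$significant))
})

test_that("Ryan's procedure reduces to a two-sample t-test at k = 2", {
  set.seed(6)
  x <- c(rnorm(10, 0), rnorm(10, 1))
  g <- rep(c("a", "b"), each = 10)
  ar <- anova_ryan(x, g)
  tt <- stats::t.test(x ~ g, var.equal = TRUE)
  expect_equal(abs(ar$pairwise$t), abs(unname(tt$statistic)),
               tolerance = 1e-10)
  expect_equal(ar$pairwise$p, tt$p.value, tolerance = 1e-10)
  expect_equal(ar$pairwise$alpha_nominal, 0.05)  # 2*alpha/(k*(r-1)) = alpha
})

test_that("Ryan decisions follow a hand-stepped schedule on a printed table", {
  # 3 groups x 4 values; means: a = 0.5, b = 5.5, c = 6.5
  vals <- c(0, 1, 0.5, 0.5, 5, 6, 5.5, 5.5, 6, 7, 6.5, 6.5)
  grp <- rep(c("a", "b", "c"), each = 4)
  ar <- anova_ryan(vals, grp)
  # hand oracle: pooled MSE and t statistics straight from the definitions
  mse <- sum((vals - ave(vals, grp))^2) / 9
  t_ab <- (5.5 - 0.5) / sqrt(mse * (1 / 4 + 1 / 4))
  t_ac <- (6.5 - 0.5) / sqrt(mse * (1 / 4 + 1 / 4))
  t_bc <- (6.5 - 5.5) / sqrt(mse * (1 / 4 + 1 / 4))
  p_ab <- 2 * stats::pt(abs(t_ab), 9, lower.tail = FALSE)
  p_ac <- 2 * stats::pt(abs(t_ac), 9, lower.tail = FALSE)
  p_bc <- 2 * stats::pt(abs(t_bc), 9, lower.tail = FALSE)
  # ordered means a < b < c: a-b and b-c span 2 ranks (alpha' = 2a/3),
  # a-c spans 3 (alpha' = a/3); step-down: a-b, b-c need a-c significant
  sig_ac <- p_ac < 0.05 / 3
  sig_ab <- (p_ab < 2 * 0.05 / 3) && sig_ac
  sig_bc <- (p_bc < 2 * 0.05 / 3) && sig_ac
  pw <- ar$pairwise
  key <- paste(pw$group_i, pw$group_j)
  expect_equal(pw$significant[key == "a b"], sig_ab)
  expect_equal(pw$significant[key == "a c"], sig_ac)
  expect_equal(pw$significant[key == "b c"], sig_bc)
  expect_equal(pw$t[key == "a c"], t_ac, tolerance = 1e-10)
})

test_that("Cohen's d matches its definition", {
  expect_equal(cohens_d(c(0, 2), c(0, 2)), 0)
  a <- c(0.5, 1.5, 1, 1); b <- a - 1
  expect_equal(cohens_d(a, b), 1 / sqrt(mean(c(stats::var(a), stats::var(b)))))
  set.seed(9)
  x <- rnorm(20, 1, 2); y <- rnorm(15, 0, 1.5)
  sp <- sqrt((19 * stats::var(x) + 14 * stats::var(y)) / 33)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("laterality bookkeeping yields the full-cohort pairwise df", {
  set.seed(12)
  N <- 1193
  g <- rep(c("NT", "EH", "MH"), c(4, 4, 1185))
  tab <- do.call(rbind, lapply(seq_len(N), function(i)
    data.frame(specimen = i, group = g[i], region = "Ce_P",
               side = c("L", "R"), volume = rnorm(2, 100, 5),
               icv = rnorm(1, 1500, 100), variant = "sym")))
  la <- laterality_analysis(tab)
  expect_equal(unique(la$Ce_P$between_by_side$L$df), 2380)
  expect_equal(la$Ce_P$simple_side$df2[1], 1190)
})

test_that("laterality volumes combine symmetrically under a cohort flip", {
  ph <- canonical_32()
  tbl <- ph$atlas_table
  # flipping a label volume with L/R id swapping exchanges L and R counts
  flipped <- flip_x(ph$atlas_truth, tbl)
  cl <- table(factor(ph$atlas_truth$labels[ph$atlas_truth$labels > 0],
                     levels = tbl$region_id))
  cf <- table(factor(flipped$labels[flipped$labels > 0],
                     levels = tbl$region_id))
  map <- paleobrain:::lr_swap_map(tbl)
  for (id in tbl$region_id)
    expect_equal(unname(cf[as.character(map[id + 1])]),
                 unname(cl[as.character(id)]))
  # scalar flip is an involution
  sv <- ph$t1_like
  expect_equal(flip_x(flip_x(sv))$values, sv$values)
})

test_that("a symmetric cohort produces a symmetric template and atlas", {
  coh <- cached("mh_cohort_32", sample_cohort(
    cohort_spec(n_per_group = 4, grid_shape = c(32, 32, 32),
                variation_sd = 0.8, warp_fwhm = 6, seed = 11)))
  ph <- canonical_32()
  imgs <- lapply(coh[1:2], function(s)
    paleobrain:::smooth_mask(endocast_mask(s$tissue)))
  atlas <- atlas_parcellation(ph$atlas_truth, ph$atlas_table)
  tpl <- paleobrain:::smooth_mask(endocast_mask(ph$tissue))
  cfg <- reg_config(iters_per_level = c(20, 14, 8))
  sym <- build_symmetrized_atlas(imgs, atlas, tpl, cfg, n_outer = 2)
  st <- sym$sym_template$values
  mismatch <- mean(abs(st - st[dim(st)[1]:1, , ])) / mean(abs(st))
  expect_lt(mismatch, 0.02)
  # label sets preserved, never invented
  expect_true(all(unique(as.vector(sym$sym_atlas$labels)) %in%
                    c(0L, atlas$table$region_id)))
  # L and R cerebellar voxel counts agree closely in the symmetrized atlas
  lab <- sym$sym_atlas$labels
  tbl <- atlas$table
  lcount <- sum(lab %in% tbl$region_id[tbl$cerebellum & tbl$hemisphere == "L"])
  rcount <- sum(lab %in% tbl$region_id[tbl$cerebellum & tbl$hemisphere == "R"])
  expect_lt(abs(lcount - rcount) / max(lcount, rcount), 0.05)
})

test_that("cognition regressions recover generative slopes within sampling error", {
  hits <- 0
  for (rep in 1:50) {
    ct <- cognition_table(150, beta_per_task = c(3, 0, 0, 0, 0, 0, 0),
                          noise_sd = 6, seed = 400 + rep)
    cr <- cognition_regression(ct)
    if (abs(cr$slope[1] - 3) <= 3 * cr$se[1]) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})
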