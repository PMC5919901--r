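test_that("mesh propagation through trivial deformations is exact", {
  tpl <- cached("rt_mesh", extract_isosurface(sphere_volume(16, 5), 0.5))
  g <- voxel_grid(c(16, 16, 16))
  idphi <- identity_deformation(g)
  hs <- propagate_mesh(tpl, list(idphi, idphi))
  expect_equal(hs$vertices[1, , ], tpl$vertices)
  expect_equal(hs$vertices[2, , ], tpl$vertices)
  tphi <- identity_deformation(g)
  tphi$u[, , , 2] <- 1.25
  ht <- propagate_mesh(tpl, list(tphi))
  expect_lt(max(abs(ht$vertices[1, , ] -
                      sweep(tpl$vertices, 2, c(0, -1.25, 0), `-`))), 1e-9)
})

test_that("Procrustes alignment removes rigid motion and scale exactly", {
  hs <- sphere_mesh_set(n_per_group = 2, noise_sd = 0.1, seed = 5)
  base <- hs$vertices[1, , ]
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  hs$vertices[2, , ] <- (base %*% R) * 2 + 5
  hs$vertices[3, , ] <- base
  hs$vertices[4, , ] <- base
  al <- procrustes_align(hs)
  expect_lt(sqrt(mean((al$vertices[1, , ] - al$vertices[2, , ])^2)), 1e-6)
  # centroid sizes are the pre-scaling sizes
  cs <- apply(hs$vertices, 1, function(m)
    sqrt(sum(sweep(m, 2, colMeans(m))^2)))
  expect_equal(al$centroid_sizes, cs)
  # consensus is invariant to specimen order
  perm <- c(3, 1, 4, 2)
  hs2 <- hs
  hs2$vertices <- hs$vertices[perm, , ]
  hs2$groups <- hs$groups[perm]
  al2 <- procrustes_align(hs2)
  expect_lt(sqrt(mean((al2$consensus - al$consensus)^2)), 1e-6)
})

test_that("Hotelling T2 maps match direct formula evaluation", {
  al <- cached("aligned_null", procrustes_align(sphere_mesh_set(
    n_per_group = 10, noise_sd = 0.3, seed = 3)))
  sm <- hotelling_t2_map(al, "A", "B")
  V <- length(sm$t2)
  idx <- round(seq(1, V, length.out = 40))
  manual <- vapply(idx, function(v) {
    A <- al$vertices[1:10, v, ]; B <- al$vertices[11:20, v, ]
    Sp <- (stats::cov(A) * 9 + stats::cov(B) * 9) / 18
    d <- colMeans(A) - colMeans(B)
    drop((10 * 10 / 20) * t(d) %*% solve(Sp, d))
  }, 0)
  expect_lt(max(abs(sm$t2[idx] - manual) / pmax(manual, 1e-8)), 1e-8)
  expect_equal(sm$df, c(3, 16))

  # 3+3 printed fixture, one vertex, against the written-out formula
  X <- array(0, c(6, 1, 3))
  X[1, 1, ] <- c(1.00, 0.20, -0.10)
  X[2, 1, ] <- c(0.80, 0.10, 0.00)
  X[3, 1, ] <- c(1.10, -0.10, 0.30)
  X[4, 1, ] <- c(-0.50, 0.40, 0.30)
  X[5, 1, ] <- c(-0.70, 0.60, 0.20)
  X[6, 1, ] <- c(-0.40, 0.30, -0.20)
  got <- paleobrain:::t2_statistic(X, 1:3, 4:6)$t2
  A <- X[1:3, 1, ]; B <- X[4:6, 1, ]
  Sp <- (stats::cov(A) * 2 + stats::cov(B) * 2) / 4
  d <- colMeans(A) - colMeans(B)
  expect_equal(got, drop((3 * 3 / 6) * t(d) %*% solve(Sp, d)),
               tolerance = 1e-10)

  # identical groups give T2 = 0 everywhere
  al_eq <- al
  al_eq$vertices[11:20, , ] <- al_eq$vertices[1:10, , ]
  sm_eq <- hotelling_t2_map(al_eq, "A", "B")
  expect_equal(max(sm_eq$t2), 0)

  # restriction to one coordinate reduces to the squared two-sample t
  X1 <- al$vertices
  X1[, , 2] <- 0; X1[, , 3] <- 0
  tt <- paleobrain:::t2_statistic(X1, 1:10, 11:20)$t2
  tman <- vapply(idx, function(v)
    unname(stats::t.test(X1[1:10, v, 1], X1[11:20, v, 1],
                         var.equal = TRUE)$statistic^2), 0)
  expect_lt(max(abs(tt[idx] - tman)), 1e-6)
})

test_that("T2 maps are invariant to a global rotation of all specimens", {
  hs <- sphere_mesh_set(n_per_group = 5, noise_sd = 0.3, seed = 8)
  al <- procrustes_align(hs)
  t2a <- hotelling_t2_map(al, "A", "B")$t2
  th <- 0.5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  hs2 <- hs
  for (s in seq_len(dim(hs$vertices)[1]))
    hs2$vertices[s, , ] <- hs$vertices[s, , ] %*% R
  t2b <- hotelling_t2_map(procrustes_align(hs2), "A", "B")$t2
  expect_lt(max(abs(t2a - t2b)), 1e-6)
})

test_that("signed normal displacement reads inflation with the right sign", {
  # uniform inflation is removed by size normalization, so the signed-map
  # mechanics are checked on a hand-built aligned set (consensus = sphere,
  # group A offset outward by +1 along the radius)
  hs <- sphere_mesh_set(n_per_group = 2, noise_sd = 0, seed = 2)
  hs$consensus <- hs$template_mesh$vertices
  for (s in 1:2)
    hs$vertices[s, , ] <- hs$template_mesh$vertices + hs$dirs
  for (s in 3:4)
    hs$vertices[s, , ] <- hs$template_mesh$vertices
  sn <- signed_normal_displacement(hs, "A", "B")
  expect_gt(mean(abs(sn - 1) < 0.05), 0.97)
  sn_rev <- signed_normal_displacement(hs, "B", "A")
  expect_equal(sn, -sn_rev)
  # equal groups give the zero map
  hs0 <- sphere_mesh_set(n_per_group = 2, noise_sd = 0, seed = 2)
  al0 <- procrustes_align(hs0)
  expect_lt(max(abs(signed_normal_displacement(al0, "A", "B"))), 1e-9)
})

test_that("uniform inflation integrates to the volume difference over area", {
  # un-normalized geometry: d(volume) ~ area * offset for small offsets
  tpl <- cached("spheremesh_24_8",
                extract_isosurface(sphere_volume(24, 8), 0.5))
  nrm <- paleobrain:::vertex_normals(tpl)
  infl <- triangle_mesh(tpl$vertices + 0.1 * nrm, tpl$faces,
                        drop_degenerate = FALSE)
  dv <- mesh_volume(infl) - mesh_volume(tpl)
  expect_lt(abs(dv / mesh_area(tpl) - 0.1) / 0.1, 0.05)
})

test_that("permutation FWE keeps dominance and detects an inserted bump", {
  al <- cached("aligned_null", procrustes_align(sphere_mesh_set(
    n_per_group = 10, noise_sd = 0.3, seed = 3)))
  sm <- fwe_correct(hotelling_t2_map(al, "A", "B"), al, n_perm = 300,
                    seed = 11)
  expect_true(all(sm$p_fwe >= sm$p - 1e-12))
  expect_true(all(sm$p_fwe >= 0 & sm$p_fwe <= 1))

  hb <- sphere_mesh_set(n_per_group = 10, noise_sd = 0.3, bump = 3, seed = 3)
  alb <- procrustes_align(hb)
  smb <- fwe_correct(hotelling_t2_map(alb, "A", "B"), alb, n_perm = 300,
                     seed = 11)
  expect_gt(mean(smb$threshold_mask[hb$patch]), 0.9)
  far <- setdiff(seq_along(smb$t2),
                 which(hb$template_mesh$vertices[, 3] >
                         max(hb$template_mesh$vertices[, 3]) - 4))
  expect_gte(mean(!smb$threshold_mask[far]), 0.95)

  # tiny groups (choose(4, 2) = 6 relabelings) fall back to exhaustive
  # enumeration with a warning
  hs <- sphere_mesh_set(n_per_group = 2, noise_sd = 0.3, seed = 4)
  als <- procrustes_align(hs)
  t2s <- suppressWarnings(hotelling_t2_map(als, "A", "B"))
  expect_warning(fwe_correct(t2s, als, n_perm = 100, seed = 1),
                 "20 distinct")
})

test_that("the omnibus Pillai map agrees with stats::manova", {
  hs <- sphere_mesh_set(n_per_group = 6, noise_sd = 0.3, seed = 6)
  hs$vertices <- hs$vertices[, 1:5, , drop = FALSE]  # few vertices suffice
  hs$groups <- rep(c("A", "B", "C"), each = 4)
  al_groups <- hs$groups
  mp <- manova_pillai_map(hs)
  fit <- stats::manova(hs$vertices[, 3, ] ~ factor(al_groups))
  sm <- summary(fit, test = "Pillai")$stats
  expect_equal(mp$pillai[3], unname(sm[1, "Pillai"]))
  expect_equal(mp$p[3], unname(sm[1, "Pr(>F)"]))
})
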