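test_that("TPS reproduces identity and affine maps with zero bending energy", {
  set.seed(1)
  src <- landmark_set(letters[1:10], matrix(runif(30, 0, 20), 10))
  w_id <- fit_tps(src, src)
  expect_lt(w_id$bending_energy, 1e-10)
  probe <- matrix(runif(90, 0, 20), 30)
  expect_lt(max(abs(apply_tps(w_id, probe) - probe)), 1e-6)

  A <- matrix(c(2, 0.1, 0, -0.2, 2, 0, 0, 0.3, 2), 3)
  tvec <- c(1, -2, 3)
  tgt <- landmark_set(src$names, src$points %*% A + rep(tvec, each = 10))
  w_aff <- fit_tps(src, tgt)
  expect_lt(w_aff$bending_energy, 1e-8)
  expect_lt(max(abs(apply_tps(w_aff, probe) -
                      (probe %*% A + rep(tvec, each = 30)))), 1e-6)
})

test_that("TPS interpolates arbitrary landmark pairs exactly", {
  set.seed(2)
  src <- landmark_set(sprintf("p%02d", 1:10), matrix(runif(30, 0, 15), 10))
  tgt <- landmark_set(src$names, src$points + matrix(rnorm(30, 0, 2), 10))
  w <- fit_tps(src, tgt)
  expect_lt(max(abs(apply_tps(w, src$points) - tgt$points)), 1e-8)
  expect_gte(w$bending_energy, 0)
  # bending energy invariant under a joint rigid motion
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  w_rot <- fit_tps(landmark_set(src$names, src$points %*% R + 5),
                   landmark_set(src$names, tgt$points %*% R + 5))
  expect_lt(abs(w_rot$bending_energy - w$bending_energy),
            1e-8 * max(w$bending_energy, 1))
  # degenerate configurations are reported
  flat <- landmark_set(letters[1:5], cbind(runif(5), runif(5), 0))
  expect_error(fit_tps(flat, flat), "coplanar")
})

test_that("mesh warping preserves connectivity", {
  mesh <- cached("rt_mesh", extract_isosurface(sphere_volume(16, 5), 0.5))
  set.seed(3)
  src <- landmark_set(letters[1:8], matrix(runif(24, 2, 13), 8))
  w <- fit_tps(src, src)
  out <- apply_tps(w, mesh)
  expect_identical(out$faces, mesh$faces)
  expect_lt(max(abs(out$vertices - mesh$vertices)), 1e-6)
})

test_that("damaged endocasts are restored from an undamaged reference", {
  ph <- canonical_32()
  em <- endocast_mask(ph$tissue)
  # no holes: idempotent
  none <- damaged_endocast(ph, list())
  r0 <- restore_endocast(none$damaged, none$hole_mask, ph, ph$landmarks)
  expect_equal(r0$restored$values, none$damaged$values)

  dm <- damaged_endocast(ph, list(list(center = ph$landmarks$points[5, ],
                                       radius = 4)))
  rest <- restore_endocast(dm$damaged, dm$hole_mask, ph, ph$landmarks)
  hm <- dm$hole_mask$values > 0.5
  est <- rest$restored$values > 0.5
  tru <- em$values > 0.5
  dice_hole <- 2 * sum(est & tru & hm) / (sum(est & hm) + sum(tru & hm))
  expect_gte(dice_hole, 0.98)
  # untouched outside holes
  expect_identical(est[!hm], (dm$damaged$values > 0.5)[!hm])

  # more landmarks help (or at least never hurt) hole recovery
  err_with <- function(lmk) {
    r <- restore_endocast(dm$damaged, dm$hole_mask, ph, lmk)
    sum((r$restored$values > 0.5)[hm] != tru[hm])
  }
  few <- landmark_set(ph$landmarks$names[1:6], ph$landmarks$points[1:6, ])
  expect_lte(err_with(ph$landmarks), err_with(few))

  expect_error(restore_endocast(dm$damaged, dm$hole_mask, ph,
                                landmark_set(ph$landmarks$names[1:3],
                                             ph$landmarks$points[1:3, ])),
               "4 usable")

  # a second TPS iteration does not increase the hole-region error
  r1 <- restore_endocast(dm$damaged, dm$hole_mask, ph, ph$landmarks,
                         n_iter = 1)
  r2 <- restore_endocast(dm$damaged, dm$hole_mask, ph, ph$landmarks,
                         n_iter = 2)
  e1 <- sum((r1$restored$values > 0.5)[hm] != tru[hm])
  e2 <- sum((r2$restored$values > 0.5)[hm] != tru[hm])
  expect_lte(e2, e1)
})
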