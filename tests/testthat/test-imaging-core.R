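test_that("voxel grids validate their geometry", {
  g <- voxel_grid(c(8, 8, 8), diag(c(2, 2, 2, 1)))
  expect_equal(g$voxel_volume, 8)
  expect_error(voxel_grid(c(8, 8, 8), matrix(0, 4, 4)), "singular")
  expect_error(voxel_grid(c(1, 8, 8)), ">= 2")
  expect_error(scalar_volume(g, array(1, c(4, 4, 4))), "shape")
  expect_error(scalar_volume(g, array(NA_real_, c(8, 8, 8))), "finite")
})

test_that("NIfTI volume round-trips are lossless", {
  g <- voxel_grid(c(8, 8, 8), diag(c(2, 2, 2, 1)))
  vol <- scalar_volume(g, array(1, c(8, 8, 8)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$values, vol$values)
  expect_lt(max(abs(back$grid$affine - g$affine)), 1e-5)
  expect_equal(back$grid$voxel_volume, 8)

  set.seed(4)
  lab <- label_volume(voxel_grid(c(8, 8, 8)),
                      array(sample(c(0L, 1L, 7L), 512, TRUE), c(8, 8, 8)))
  write_volume(lab, f)
  lback <- read_volume(f)
  expect_s3_class(lback, "label_volume")
  expect_identical(lback$labels, lab$labels)

  expect_error(read_volume(file.path(tempdir(), "absent.nii")), "no such file")
})

test_that("trilinear sampling is exact on lattices, lines and affine fields", {
  arr <- array(0, c(10, 10, 10))
  for (i in 1:10) arr[i, , ] <- 3 * (i - 1) + 1
  vol <- scalar_volume(voxel_grid(c(10, 10, 10)), arr)
  # lattice identity
  expect_equal(trilinear_sample(vol, c(1, 2, 3)), arr[2, 3, 4])
  # midpoint linearity
  a2 <- array(0, c(4, 4, 4)); a2[2, , ] <- 10
  v2 <- scalar_volume(voxel_grid(c(4, 4, 4)), a2)
  expect_equal(trilinear_sample(v2, c(0.5, 1, 1)), 5)
  # a fully affine scalar field is reproduced exactly anywhere
  aff <- array(0, c(10, 10, 10))
  for (k in 1:10) for (j in 1:10)
    aff[, j, k] <- 2 * (0:9) - 3 * (j - 1) + 0.5 * (k - 1) + 7
  va <- scalar_volume(voxel_grid(c(10, 10, 10)), aff)
  set.seed(1)
  pts <- matrix(runif(300, 0.2, 8.8), ncol = 3)
  truth <- 2 * pts[, 1] - 3 * pts[, 2] + 0.5 * pts[, 3] + 7
  expect_lt(max(abs(trilinear_sample(va, pts) - truth)), 1e-12)
})

test_that("nearest-label sampling rounds per axis and returns background outside", {
  set.seed(9)
  lab <- label_volume(voxel_grid(c(6, 6, 6)),
                      array(sample(0:3, 216, TRUE), c(6, 6, 6)))
  expect_equal(nearest_sample(lab, c(0.4, 0.4, 0.4)), lab$labels[1, 1, 1])
  expect_equal(nearest_sample(lab, c(-2, 1, 1)), 0L)
  pts <- paleobrain:::grid_points(lab$grid)
  expect_equal(nearest_sample(lab, pts), as.vector(lab$labels))
})

test_that("isosurface of a smoothed sphere matches analytic area and volume", {
  sv <- sphere_volume(48, 10)
  mesh <- extract_isosurface(sv, 0.5)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_lt(abs(mesh_volume(mesh) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)
  # outward orientation: signed volume positive
  expect_gt(mesh_volume(mesh), 0)
  expect_error(
    extract_isosurface(scalar_volume(voxel_grid(c(8, 8, 8)),
                                     array(1, c(8, 8, 8))), 0.5),
    "range")
})

test_that("isosurface error decreases as the grid is refined", {
  err <- vapply(c(32, 64), function(n) {
    r <- n / 4.8
    m <- extract_isosurface(sphere_volume(n, r), 0.5)
    abs(mesh_area(m) - 4 * pi * r^2) / (4 * pi * r^2)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("mesh, landmark and table files round-trip", {
  mesh <- cached("rt_mesh", extract_isosurface(sphere_volume(16, 5), 0.5))
  f <- withr::local_tempfile(fileext = ".ply")
  write_mesh(mesh, f)
  back <- read_mesh(f)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
  expect_identical(back$faces, mesh$faces)

  lmk <- landmark_set(c("a", "b", "c", "d"),
                      matrix(rnorm(12), 4) * 10)
  fl <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lmk, fl)
  lback <- read_landmarks(fl)
  expect_equal(lback$names, lmk$names)
  expect_lt(max(abs(lback$points - lmk$points)), 1e-6)

  df <- data.frame(x = 1:3, y = c("u", "v", "w"))
  ft <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(df, ft)
  expect_equal(read_table_csv(ft), df)

  bad <- withr::local_tempfile(fileext = ".ply")
  writeLines("not a ply", bad)
  expect_error(read_mesh(bad), "line 1")
})
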