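# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# smoothed sphere indicator volume
sphere_volume <- function(n, r, sig = 1, ctr = NULL) {
  ax <- seq_len(n) - 1
  if (is.null(ctr)) ctr <- rep((n - 1) / 2, 3)
  d2 <- outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"), (ax - ctr[3])^2, "+")
  vals <- array(as.numeric(sqrt(d2) <= r), c(n, n, n))
  scalar_volume(voxel_grid(c(n, n, n)),
                paleobrain:::gaussian_smooth3(vals, sig))
}

# smooth white-noise velocity field (FWHM 8 voxels, like the cohort
# generator), scaled to a maximum absolute displacement
smooth_test_field <- function(d, seed, fwhm = 8, vmax = 1.5) {
  v <- paleobrain:::random_velocity(d, fwhm, 1, seed)
  v * (vmax / max(abs(v)))
}

# forward-Euler flow integration oracle for exp(v)
euler_flow <- function(v, n_steps = 256) {
  d <- dim(v)[1:3]
  g <- voxel_grid(d)
  pts <- paleobrain:::grid_points(g)
  x <- pts
  for (s in seq_len(n_steps)) {
    vx <- cbind(paleobrain:::interp_array3(v[, , , 1], x),
                paleobrain:::interp_array3(v[, , , 2], x),
                paleobrain:::interp_array3(v[, , , 3], x))
    x <- x + vx / n_steps
  }
  u <- array(0, c(d, 3))
  xd <- x - pts
  for (c in 1:3) u[, , , c] <- array(xd[, c], d)
  u
}

# interior mask (margin voxels from each face) for flow-invariant checks
# outside the boundary clamp zone
interior_idx <- function(d, margin = 3) {
  lapply(d, function(n) (margin + 1):(n - margin))
}

interior_max <- function(u, margin = 3) {
  d <- dim(u)[1:3]
  ii <- interior_idx(d, margin)
  max(abs(u[ii[[1]], ii[[2]], ii[[3]], ]))
}

# 6-connected components count of a binary array (BFS flood fill)
n_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      ijk <- arrayInd(q, d)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- ijk
        nb[, ax] <- nb[, ax] + dd
        ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
        new <- lin[mask[lin] & lab[lin] == 0L]
        lab[new] <- cur
        queue <- c(queue, new)
      }
      queue <- unique(queue)
    }
  }
  cur
}

canonical_48 <- function() cached("canon48", canonical_phantom(c(48, 48, 48)))
canonical_32 <- function() cached("canon32", canonical_phantom(c(32, 32, 32)))

# homologous sphere-mesh cohort: template sphere mesh plus per-specimen
# vertex noise; optional radial bump added to group A on `patch` vertices
sphere_mesh_set <- function(n_per_group = 10, noise_sd = 0.3, bump = 0,
                            seed = 3, n = 24, r = 8) {
  tpl <- cached(sprintf("spheremesh_%d_%d", n, r), {
    extract_isosurface(sphere_volume(n, r), 0.5)
  })
  ctr <- rep((n - 1) / 2, 3)
  V <- nrow(tpl$vertices)
  dirs <- sweep(tpl$vertices, 2, ctr)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  patch <- which(tpl$vertices[, 3] > ctr[3] + r - 2)
  set.seed(seed)
  S <- 2 * n_per_group
  verts <- array(0, c(S, V, 3))
  grp <- rep(c("A", "B"), each = n_per_group)
  for (s in seq_len(S)) {
    verts[s, , ] <- tpl$vertices + matrix(stats::rnorm(V * 3, 0, noise_sd), V)
    if (bump != 0 && grp[s] == "A")
      verts[s, patch, ] <- verts[s, patch, ] + bump * dirs[patch, ]
  }
  structure(list(template_mesh = tpl, vertices = verts,
                 ids = sprintf("s%02d", seq_len(S)), groups = grp,
                 patch = patch, dirs = dirs),
            class = "homologous_mesh_set")
}

# ground-truth laterality table (cerebellar L/R volumes) from a cohort
laterality_table <- function(cohort, regions = c("Ce_A", "Ce_P"),
                             variant = "sym") {
  do.call(rbind, lapply(cohort, function(s) {
    tv <- true_parcel_volumes(s)
    icv_v <- icv(s$tissue)
    do.call(rbind, lapply(regions, function(rg)
      data.frame(specimen = s$id, group = s$group, region = rg,
                 side = c("L", "R"),
                 volume = c(tv$volume_mm3[tv$lobe_group == rg &
                                            tv$hemisphere == "L"],
                            tv$volume_mm3[tv$lobe_group == rg &
                                            tv$hemisphere == "R"]),
                 icv = icv_v, variant = variant,
                 stringsAsFactors = FALSE)))
  }))
}
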