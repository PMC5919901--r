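#' Extract a level-set surface as a triangle mesh
#'
#' Isosurfaces a scalar volume by marching tetrahedra on the Kuhn 6-tetrahedra
#' subdivision of each grid cube. The uniform subdivision is conforming
#' across cube boundaries, so the result is a closed, consistently oriented
#' surface with outward normals (normals point away from the super-level
#' region, i.e. out of the object when the object carries the high values).
#' Vertices are welded and returned in world mm.
#'
#' @param volume a [scalar_volume].
#' @param level iso value; must lie strictly between the lattice min and max.
#' @return a [triangle_mesh].
#' @export
extract_isosurface <- function(volume, level) {
  stopifnot(inherits(volume, "scalar_volume"))
  vals <- volume$values
  rng <- range(vals)
  if (!(level > rng[1] && level < rng[2]))
    stop("extract_isosurface: level outside the value range (no crossing)")
  d <- dim(vals)

  # cube origins (0-based), all cubes
  nc <- (d[1] - 1L) * (d[2] - 1L) * (d[3] - 1L)
  ci <- rep.int(seq_len(d[1] - 1L) - 1L, (d[2] - 1L) * (d[3] - 1L))
  cj <- rep.int(rep(seq_len(d[2] - 1L) - 1L, each = d[1] - 1L), d[3] - 1L)
  ck <- rep(seq_len(d[3] - 1L) - 1L, each = (d[1] - 1L) * (d[2] - 1L))

  # local corner offsets, corner id 0..7 = (dx, dy, dz) bits
  off <- cbind(dx = bitwAnd(0:7, 1L),
               dy = bitwShiftR(bitwAnd(0:7, 2L), 1L),
               dz = bitwShiftR(bitwAnd(0:7, 4L), 2L))
  # linear index (1-based) of each cube corner
  corner_idx <- matrix(0L, nc, 8)
  for (c in 1:8) {
    corner_idx[, c] <- 1L + (ci + off[c, 1]) +
      d[1] * ((cj + off[c, 2]) + d[2] * (ck + off[c, 3]))
  }
  above <- matrix(vals[corner_idx] > level, nc, 8)

  # discard cubes with no crossing early
  ns <- rowSums(above)
  active <- ns > 0 & ns < 8
  if (!any(active)) stop("extract_isosurface: no crossing found")
  corner_idx <- corner_idx[active, , drop = FALSE]
  above <- above[active, , drop = FALSE]
  ci <- ci[active]; cj <- cj[active]; ck <- ck[active]

  # Kuhn subdivision: 6 tets sharing the main diagonal corner0-corner7
  tets <- rbind(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))

  tri_list <- vector("list", 6)
  for (t in 1:6) {
    tc <- tets[t, ]
    tv <- cbind(vals[corner_idx[, tc[1]]], vals[corner_idx[, tc[2]]],
                vals[corner_idx[, tc[3]]], vals[corner_idx[, tc[4]]])
    ta <- above[, tc, drop = FALSE]
    nab <- rowSums(ta)
    mixed <- which(nab > 0 & nab < 4)
    if (!length(mixed)) next
    # tet corner coordinates (voxel units), M x 4 x 3
    px <- ci[mixed]; py <- cj[mixed]; pz <- ck[mixed]
    P <- lapply(1:4, function(v) cbind(px + off[tc[v], 1],
                                       py + off[tc[v], 2],
                                       pz + off[tc[v], 3]))
    tri_list[[t]] <- march_tet(tv[mixed, , drop = FALSE],
                               ta[mixed, , drop = FALSE], P, level)
  }
  soup <- do.call(rbind, tri_list)      # (3*T) x 3, triangles consecutive
  if (is.null(soup) || nrow(soup) == 0)
    stop("extract_isosurface: no crossing found")

  # weld vertices (round to 1e-6 voxel)
  key <- round(soup * 1e6)
  id <- match(
    paste(key[, 1], key[, 2], key[, 3]),
    paste(key[, 1], key[, 2], key[, 3])[!duplicated(key)]
  )
  verts_vox <- soup[!duplicated(key), , drop = FALSE]
  faces <- matrix(id, ncol = 3, byrow = TRUE)
  verts <- voxel_to_world(volume$grid, verts_vox)
  triangle_mesh(verts, faces)
}

# emit oriented triangles for a batch of mixed-sign tetrahedra.
# tv: M x 4 values; ta: M x 4 above-flags; P: list of 4 (M x 3) corner coords
march_tet <- function(tv, ta, P, level) {
  M <- nrow(tv)
  edge_pt <- function(a, b, rows) {
    va <- tv[rows, a]; vb <- tv[rows, b]
    w <- (level - va) / (vb - va)
    P[[a]][rows, , drop = FALSE] +
      w * (P[[b]][rows, , drop = FALSE] - P[[a]][rows, , drop = FALSE])
  }
  out <- vector("list", 8)
  oi <- 0L
  nab <- rowSums(ta)

  # one corner on its own side (above alone, or below alone)
  for (lone_above in c(TRUE, FALSE)) {
    target <- if (lone_above) 1L else 3L
    for (a in 1:4) {
      rows <- which(nab == target & ta[, a] == lone_above)
      if (!length(rows)) next
      others <- setdiff(1:4, a)
      q1 <- edge_pt(a, others[1], rows)
      q2 <- edge_pt(a, others[2], rows)
      q3 <- edge_pt(a, others[3], rows)
      # orient: normal away from the above side
      apex <- P[[a]][rows, , drop = FALSE]
      tris <- orient_tris(q1, q2, q3, apex, toward = !lone_above)
      oi <- oi + 1L; out[[oi]] <- tris
    }
  }

  # two-two split: quad -> two triangles
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in seq_len(nrow(pairs))) {
    a1 <- pairs[p, 1]; a2 <- pairs[p, 2]
    rows <- which(nab == 2L & ta[, a1] & ta[, a2])
    if (!length(rows)) next
    bb <- setdiff(1:4, c(a1, a2))
    p11 <- edge_pt(a1, bb[1], rows); p12 <- edge_pt(a1, bb[2], rows)
    p21 <- edge_pt(a2, bb[1], rows); p22 <- edge_pt(a2, bb[2], rows)
    above_mid <- (P[[a1]][rows, , drop = FALSE] +
                  P[[a2]][rows, , drop = FALSE]) / 2
    t1 <- orient_tris(p11, p12, p22, above_mid, toward = FALSE)
    t2 <- orient_tris(p11, p22, p21, above_mid, toward = FALSE)
    oi <- oi + 1L; out[[oi]] <- rbind(t1, t2)
  }
  do.call(rbind, out[seq_len(oi)])
}

# stack triangles (q1,q2,q3) so normals point toward/away from ref point
orient_tris <- function(q1, q2, q3, ref, toward) {
  n <- vec_cross(q2 - q1, q3 - q1)
  s <- rowSums(n * (ref - q1))
  flip <- if (toward) s < 0 else s > 0
  if (any(flip)) {
    tmp <- q2[flip, , drop = FALSE]
    q2[flip, ] <- q3[flip, , drop = FALSE]
    q3[flip, ] <- tmp
  }
  # interleave rows as consecutive triangles
  m <- nrow(q1)
  res <- matrix(0, 3 * m, 3)
  res[seq(1, 3 * m, 3), ] <- q1
  res[seq(2, 3 * m, 3), ] <- q2
  res[seq(3, 3 * m, 3), ] <- q3
  res
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  0.5 * sqrt(rowSums(vec_cross(e1, e2)^2))
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [triangle_mesh].
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Enclosed volume of a closed, outward-oriented mesh (mm^3)
#'
#' Signed volume by the divergence theorem; positive for outward normals.
#' @param mesh a [triangle_mesh].
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * vec_cross(b, cc))) / 6
}

# area-weighted vertex normals, unit length
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- vec_cross(e1, e2)   # magnitude = 2*area
  n <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    for (ax in 1:3) {
      acc <- rowsum(fn[, ax], f[, c], reorder = FALSE)
      n[as.integer(rownames(acc)), ax] <- n[as.integer(rownames(acc)), ax] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}
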