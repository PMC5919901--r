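#' Voxel grid geometry
#'
#' A `voxel_grid` couples an integer lattice shape with a 4x4 affine matrix
#' mapping homogeneous 0-based voxel indices `(i, j, k, 1)` to world
#' coordinates in mm (RAS+ orientation; +x is the left-right axis used for
#' midsagittal flips). All volumes, deformations and meshes in the package
#' live on such grids.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 2).
#' @param affine 4x4 numeric matrix, voxel-to-world map; must be invertible.
#' @return An object of class `voxel_grid` with fields `shape`, `affine`
#'   and `voxel_volume` (mm^3, the absolute determinant of the spatial
#'   3x3 block).
#' @export
voxel_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  affine <- unname(as.matrix(affine))
  stopifnot(identical(dim(affine), c(4L, 4L)), all(is.finite(affine)))
  d <- det(affine[1:3, 1:3])
  if (abs(d) < .Machine$double.eps * 100)
    stop("voxel_grid: affine is singular")
  structure(
    list(shape = shape, affine = affine, voxel_volume = abs(d)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s, voxel %.4g mm^3>\n",
              paste(x$shape, collapse = "x"), x$voxel_volume))
  invisible(x)
}

grids_compatible <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_compatible(a, b))
    stop(sprintf("grid mismatch between %s", what))
  invisible(TRUE)
}

#' Scalar image volume
#'
#' @param grid a [voxel_grid].
#' @param values numeric 3-D array matching `grid$shape`; all finite.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(grid, values) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("scalar_volume: lattice shape does not match grid shape")
  if (!all(is.finite(values)))
    stop("scalar_volume: non-finite values")
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' Integer label volume (0 = background)
#'
#' @param grid a [voxel_grid].
#' @param labels non-negative integer 3-D array matching `grid$shape`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, labels) {
  stopifnot(inherits(grid, "voxel_grid"))
  labels <- as.array(labels)
  if (!identical(dim(labels), as.integer(grid$shape)))
    stop("label_volume: lattice shape does not match grid shape")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("label_volume: negative labels")
  structure(list(grid = grid, labels = labels), class = "label_volume")
}

#' Tissue fraction maps (GM/WM/CSF) on one grid
#'
#' @param gm,wm,csf `scalar_volume` fraction maps in \[0, 1\] on a shared
#'   grid; the three fractions may not sum above 1 anywhere (tolerance 1e-6).
#' @return An object of class `tissue_volume_set`.
#' @export
tissue_volume_set <- function(gm, wm, csf) {
  stopifnot(inherits(gm, "scalar_volume"), inherits(wm, "scalar_volume"),
            inherits(csf, "scalar_volume"))
  stop_if_grid_mismatch(gm$grid, wm$grid, "gm/wm")
  stop_if_grid_mismatch(gm$grid, csf$grid, "gm/csf")
  rng <- range(gm$values, wm$values, csf$values)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("tissue_volume_set: fractions outside [0, 1]")
  if (max(gm$values + wm$values + csf$values) > 1 + 1e-6)
    stop("tissue_volume_set: fractions sum above 1")
  structure(list(gm = gm, wm = wm, csf = csf, grid = gm$grid),
            class = "tissue_volume_set")
}

#' Triangular surface mesh in world mm
#'
#' @param vertices V x 3 numeric matrix of world coordinates.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param drop_degenerate drop zero-area faces (default TRUE).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L,
            all(is.finite(vertices)))
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("triangle_mesh: face index out of range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  if (drop_degenerate && nrow(faces) > 0) {
    a <- triangle_areas(m)
    m$faces <- faces[a > .Machine$double.eps, , drop = FALSE]
  }
  m
}

#' Named 3-D landmark set
#'
#' @param names character vector of unique landmark identifiers.
#' @param points L x 3 numeric matrix of world-mm coordinates.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(names, points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  names <- as.character(names)
  stopifnot(ncol(points) == 3L, length(names) == nrow(points))
  if (anyDuplicated(names)) stop("landmark_set: duplicate names")
  structure(list(names = names, points = points), class = "landmark_set")
}

# world <-> voxel coordinate transforms (points are N x 3, voxel 0-based)
voxel_to_world <- function(grid, pts) {
  pts <- rbind_points(pts)
  h <- cbind(pts, 1)
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

world_to_voxel <- function(grid, pts) {
  pts <- rbind_points(pts)
  h <- cbind(pts, 1)
  out <- h %*% t(solve(grid$affine))
  out[, 1:3, drop = FALSE]
}

rbind_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  as.matrix(pts)
}

# all voxel index triples of a grid as an N x 3 matrix (0-based)
grid_points <- function(grid) {
  d <- grid$shape
  cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
}
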