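#' Read / write volumes as NIfTI-1
#'
#' `read_volume()` reads a 3-D NIfTI-1 image. Integer-typed images are
#' returned as [label_volume], floating-point images as [scalar_volume].
#' `write_volume()` writes either class; label volumes are stored with an
#' integer datatype so labels round-trip bit-exactly.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param as one of `"auto"`, `"scalar"`, `"labels"`.
#' @return a [scalar_volume] or [label_volume].
#' @export
read_volume <- function(path, as = c("auto", "scalar", "labels")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop(sprintf("read_volume: no such file: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("read_volume: %s is not a 3-D image", path))
  # prefer the sform: it stores the affine exactly, while the quaternion
  # qform representation can lose non-unit scales
  aff <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                   class = NULL)
  arr <- array(as.vector(img), dim(img))
  grid <- voxel_grid(dim(img), aff)
  is_int <- RNifti::niftiHeader(img)$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L)
  if (as == "labels" || (as == "auto" && is_int))
    label_volume(grid, arr)
  else
    scalar_volume(grid, arr)
}

#' @rdname read_volume
#' @param volume a [scalar_volume] or [label_volume].
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "label_volume")) {
    arr <- volume$labels
    storage.mode(arr) <- "integer"
    dt <- "int32"
    grid <- volume$grid
  } else if (inherits(volume, "scalar_volume")) {
    arr <- volume$values
    dt <- "double"
    grid <- volume$grid
  } else stop("write_volume: need a scalar_volume or label_volume")
  img <- RNifti::asNifti(arr, datatype = dt)
  qform(img) <- structure(grid$affine, code = 2L)
  sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read / write triangle meshes as ASCII PLY
#'
#' Plain-text PLY with coordinates printed to 9 significant digits, giving
#' round-trips lossless to well under 1e-6 mm at cranial scale.
#'
#' @param path file path.
#' @return a [triangle_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_mesh: no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop(sprintf("read_mesh: %s: not a PLY file (line 1)", path))
  endh <- match("end_header", lines)
  if (is.na(endh)) stop(sprintf("read_mesh: %s: missing end_header", path))
  head <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", head, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", head, value = TRUE)))
  if (!length(nv) || !length(nf))
    stop(sprintf("read_mesh: %s: missing element declarations", path))
  vl <- lines[endh + seq_len(nv)]
  fl <- lines[endh + nv + seq_len(nf)]
  verts <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
  fparts <- matrix(as.integer(scan(text = fl, quiet = TRUE)), ncol = 4, byrow = TRUE)
  if (any(fparts[, 1] != 3L))
    stop(sprintf("read_mesh: %s: non-triangular face", path))
  triangle_mesh(verts, fparts[, 2:4] + 1L, drop_degenerate = FALSE)
}

#' @rdname read_mesh
#' @param mesh a [triangle_mesh].
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read / write landmark sets as CSV (columns name, x, y, z)
#' @param path file path.
#' @return a [landmark_set].
#' @export
read_landmarks <- function(path) {
  df <- read_table_csv(path)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop(sprintf("read_landmarks: %s: missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  landmark_set(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' @rdname read_landmarks
#' @param lmk a [landmark_set].
#' @export
write_landmarks <- function(lmk, path) {
  stopifnot(inherits(lmk, "landmark_set"))
  df <- data.frame(name = lmk$names, x = lmk$points[, 1],
                   y = lmk$points[, 2], z = lmk$points[, 3])
  write_table_csv(df, path)
}

#' Read / write data frames as comma-separated text with a header row
#' @param path file path.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_table_csv: no such file: %s", path))
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_table_csv
#' @param df a data frame.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
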