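#' Read a point cloud from disk
#'
#' Supported formats: PLY (ascii or binary little-endian), uncompressed
#' LAS 1.2-1.4 and whitespace-delimited XYZ text with optional
#' `semantic instance` (and `r g b`) columns. `format = "auto"` dispatches on
#' the file extension.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"ply"`, `"las"`, `"xyz"`.
#' @param class_map LAS classification map, see [las_class_map()].
#' @return a `forest_cloud`; semantic/instance are `-1` where the file carries
#'   no labels.
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "las", "xyz"),
                             class_map = las_class_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file '", path, "'")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", las = "las", laz = "las",
                     xyz = "xyz", txt = "xyz", csv = "xyz",
                     stop("cannot infer point-cloud format from extension '.", ext, "'"))
  }
  switch(format,
         ply = read_ply(path),
         las = read_las(path, class_map),
         xyz = read_xyz(path))
}

#' Write a point cloud to disk
#'
#' @param cloud a `forest_cloud`.
#' @param path output file path; parent directory must exist.
#' @param format one of `"auto"`, `"ply"`, `"las"`, `"xyz"`.
#' @param binary for PLY: write binary little-endian (default) or ascii.
#' @return the path, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "ply", "las", "xyz"),
                              binary = TRUE) {
  stopifnot(inherits(cloud, "forest_cloud"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", las = "las", xyz = "xyz", txt = "xyz",
                     stop("cannot infer point-cloud format from extension '.", ext, "'"))
  }
  switch(format,
         ply = write_ply(cloud, path, binary = binary),
         las = write_las(cloud, path),
         xyz = write_xyz(cloud, path))
  invisible(path)
}

#' Quantize a point cloud into a sparse voxel grid
#'
#' Voxel index is `floor((p - origin) / voxel_size)` with the origin at the
#' per-block minimum corner by default. Initial per-voxel features are the
#' mean offset of member points from the voxel center (in voxel units,
#' range (-0.5, 0.5)) followed by mean color when the cloud has color.
#'
#' @param cloud a `forest_cloud` with at least one point.
#' @param voxel_size voxel edge length in metres (default 0.15).
#' @param origin length-3 numeric or `NULL` for the minimum corner.
#' @return a `voxel_grid`: integer `voxel_coords` (V x 3, unique rows),
#'   `features` (V x C), `point_to_voxel` (length N, in 1..V), `voxel_size`,
#'   `origin`.
#' @export
voxelize <- function(cloud, voxel_size = 0.15, origin = NULL) {
  stopifnot(inherits(cloud, "forest_cloud"))
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a positive number")
  n <- n_points(cloud)
  if (n == 0L) stop("cannot voxelize an empty cloud")
  if (is.null(origin)) origin <- col_mins(cloud$coords)
  ijk <- floor(sweep(cloud$coords, 2L, origin) / voxel_size)
  storage.mode(ijk) <- "integer"
  key <- voxel_key(ijk)
  uk <- unique(key)
  p2v <- match(key, uk)
  V <- length(uk)
  first <- match(uk, key)
  vox <- ijk[first, , drop = FALSE]
  centers <- sweep((vox + 0.5) * voxel_size, 2L, origin, "+")
  mean_by <- function(x) rowsum(x, p2v, reorder = TRUE) / as.vector(table(p2v))
  moff <- (mean_by(cloud$coords) - centers) / voxel_size
  feats <- moff
  if (!is.null(cloud$color)) feats <- cbind(feats, mean_by(cloud$color))
  structure(list(voxel_coords = vox, features = feats, point_to_voxel = p2v,
                 voxel_size = voxel_size, origin = origin, n_points = n),
            class = "voxel_grid")
}

# Collision-free integer key for voxel coordinates: exact in a double
# mantissa for |ijk| < 32768 per axis (about 5 km of 0.15 m voxels), far
# beyond any block this package tiles.
voxel_key <- function(ijk) {
  (as.numeric(ijk[, 1]) + 32768) +
    (as.numeric(ijk[, 2]) + 32768) * 65536 +
    (as.numeric(ijk[, 3]) + 32768) * 4294967296
}

#' Broadcast per-voxel values back to points
#'
#' @param grid a `voxel_grid`.
#' @param voxel_values matrix or vector with one row/element per voxel.
#' @return an N x D matrix (or length-N vector) of per-point values.
#' @export
devoxelize <- function(grid, voxel_values) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(dim(voxel_values))) {
    if (length(voxel_values) != nrow(grid$voxel_coords))
      stop("voxel_values length (", length(voxel_values), ") != number of voxels (",
           nrow(grid$voxel_coords), ")")
    return(voxel_values[grid$point_to_voxel])
  }
  if (nrow(voxel_values) != nrow(grid$voxel_coords))
    stop("voxel_values rows (", nrow(voxel_values), ") != number of voxels (",
         nrow(grid$voxel_coords), ")")
  voxel_values[grid$point_to_voxel, , drop = FALSE]
}

#' Voxel centers in metres
#' @param grid a `voxel_grid`.
#' @return V x 3 matrix of voxel center coordinates.
#' @export
voxel_centers <- function(grid) {
  sweep((grid$voxel_coords + 0.5) * grid$voxel_size, 2L, grid$origin, "+")
}
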