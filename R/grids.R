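#' @useDynLib densiligand, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm quantile sd kmeans median rnorm runif setNames
#' @importFrom utils read.csv
NULL

#' Canonical voxel spacing of ligand blobs (Angstrom)
#'
#' All extracted ligand blobs are resampled onto an isotropic grid with this
#' spacing so that blobs from different deposits are directly comparable.
#' @export
CANONICAL_SPACING <- 0.2

#' Construct a density grid
#'
#' A `density_grid` is a 3D scalar field together with the world-space
#' position of its first voxel center (`origin`, Angstrom), the per-axis
#' voxel spacing (Angstrom per voxel) and a tag saying which kind of map the
#' values come from. Voxel `(i, j, k)` (1-based R indices) has world
#' coordinate `origin + (i - 1, j - 1, k - 1) * spacing`: the grid is a
#' lattice of voxel *centers*.
#'
#' @param values numeric 3D array of map values (e/A^3 for crystallographic
#'   difference maps, Volts for cryoEM potential maps).
#' @param origin numeric length-3, world coordinate of voxel (1,1,1) centers.
#' @param spacing numeric length-3 (or scalar), voxel edge lengths, all > 0.
#' @param map_kind `"xray_diff"` or `"cryoem"`.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(values, origin = c(0, 0, 0), spacing = CANONICAL_SPACING,
                         map_kind = c("xray_diff", "cryoem")) {
  map_kind <- match.arg(map_kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 1L)) stop("all array dimensions must be >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L)
    stop("`origin` and `spacing` must have length 3")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be strictly positive")
  structure(list(values = values, origin = origin, spacing = spacing,
                 map_kind = map_kind),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_grid> %d x %d x %d voxels (%s)\n", d[1], d[2], d[3], x$map_kind))
  cat(sprintf("  origin : %.3f %.3f %.3f A\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  spacing: %.3f %.3f %.3f A\n", x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  values : [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

is_density_grid <- function(x) inherits(x, "density_grid")

#' World coordinates of voxel centers
#'
#' @param grid a `density_grid`.
#' @param idx integer matrix of 1-based voxel indices (n x 3).
#' @return n x 3 matrix of world coordinates (Angstrom).
#' @export
voxel_centers <- function(grid, idx) {
  stopifnot(is_density_grid(grid))
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

#' Quality metadata for a ligand blob
#'
#' Holds the per-ligand quality descriptors used by the blob filters.
#' `resolution` is mandatory; every other field may be `NA` (its filter is
#' then skipped). RSCC is the real-space correlation coefficient; RSZO and
#' RSZD are real-space Z-scores of observed and difference density; Q-score
#' is the cryoEM map-model resolvability score; `volume` is blob volume in
#' cubic Angstrom.
#'
#' @param resolution map resolution in Angstrom (> 0).
#' @param rscc,rszo,rszd,r_factor,occupancy,q_score,volume optional metrics.
#' @return An object of class `quality_metadata`.
#' @export
quality_metadata <- function(resolution, rscc = NA_real_, rszo = NA_real_,
                             rszd = NA_real_, r_factor = NA_real_,
                             occupancy = NA_real_, q_score = NA_real_,
                             volume = NA_real_) {
  resolution <- as.numeric(resolution)
  if (!is.finite(resolution) || resolution <= 0)
    stop("`resolution` must be a positive number (Angstrom)")
  if (!is.na(volume) && volume < 0) stop("`volume` must be >= 0 when present")
  structure(list(resolution = resolution, rscc = as.numeric(rscc),
                 rszo = as.numeric(rszo), rszd = as.numeric(rszd),
                 r_factor = as.numeric(r_factor),
                 occupancy = as.numeric(occupancy),
                 q_score = as.numeric(q_score), volume = as.numeric(volume)),
            class = "quality_metadata")
}

#' Construct a ligand blob
#'
#' A blob is a cropped, thresholded density grid presumed to contain a single
#' ligand, plus its quality metadata, an optional ligand-group label and a
#' free-form source identifier (deposit/chain/residue).
#'
#' @param grid a thresholded `density_grid` (background exactly zero, at
#'   least one strictly positive voxel, no negative voxels).
#' @param meta a `quality_metadata` object or `NULL`.
#' @param label group label string or `NA` for unlabeled blobs.
#' @param source_id identifier string.
#' @return An object of class `ligand_blob`.
#' @export
ligand_blob <- function(grid, meta = NULL, label = NA_character_,
                        source_id = "") {
  stopifnot(is_density_grid(grid))
  v <- grid$values
  if (!any(v > 0)) stop("blob grid must contain at least one positive voxel")
  if (any(v < 0)) stop("blob grid must be thresholded: no negative voxels")
  if (!is.null(meta) && !inherits(meta, "quality_metadata"))
    stop("`meta` must be a quality_metadata object or NULL")
  structure(list(grid = grid, meta = meta, label = as.character(label),
                 source_id = as.character(source_id)),
            class = "ligand_blob")
}

#' Threshold a crystallographic difference map at a sigma level
#'
#' Keeps only voxels at or above `mean + n_sigma * SD` of the full map (the
#' conventional sigma-scale contour of difference density); everything below
#' the contour is set to zero. Statistics are the mean and population
#' standard deviation over *all* voxels of the supplied grid.
#'
#' @param grid a `density_grid` with `map_kind == "xray_diff"`.
#' @param n_sigma contour level in standard deviations (default 2.8).
#' @return A new `density_grid` with sub-threshold voxels zeroed.
#' @export
threshold_xray <- function(grid, n_sigma = 2.8) {
  stopifnot(is_density_grid(grid))
  if (grid$map_kind != "xray_diff")
    stop("threshold_xray applies to xray_diff maps; got ", grid$map_kind)
  v <- grid$values
  mu <- mean(v)
  sdev <- sqrt(mean((v - mu)^2))
  if (sdev == 0) stop("degenerate input: constant grid has zero SD")
  thr <- mu + n_sigma * sdev
  out <- grid
  out$values[v < thr] <- 0
  out
}

#' Resample a grid onto an isotropic lattice
#'
#' Trilinear interpolation of the source field at the voxel centers of a new
#' isotropic grid with the requested spacing. The new grid starts at the
#' source origin and covers the source bounding box (its far edge is within
#' one voxel of the source's). Query points outside the source box evaluate
#' to zero.
#'
#' @param grid a `density_grid`.
#' @param target_spacing isotropic spacing in Angstrom (default 0.2).
#' @return A resampled `density_grid`.
#' @export
resample_grid <- function(grid, target_spacing = CANONICAL_SPACING) {
  stopifnot(is_density_grid(grid))
  if (!is.finite(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be > 0")
  d <- dim(grid$values)
  extent <- (d - 1) * grid$spacing
  nd <- pmax(1L, as.integer(floor(extent / target_spacing + 1e-9)) + 1L)
  # fractional source index (0-based) of each target voxel center, per axis
  ax <- lapply(1:3, function(a) {
    ((seq_len(nd[a]) - 1) * target_spacing) / grid$spacing[a]
  })
  out <- array(0, dim = nd)
  v <- grid$values
  i0 <- lapply(1:3, function(a) pmin(pmax(floor(ax[[a]]), 0), d[a] - 1))
  fr <- lapply(1:3, function(a) ax[[a]] - i0[[a]])
  # clamp the upper corner so a query exactly on the far face stays in range
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1, d[a] - 1))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- if (cx == 0) i0[[1]] else i1[[1]]
    iy <- if (cy == 0) i0[[2]] else i1[[2]]
    iz <- if (cz == 0) i0[[3]] else i1[[3]]
    wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
    # corner weight is separable: accumulate as an outer product of axis terms
    block <- v[ix + 1L, iy + 1L, iz + 1L, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * array(block, dim = nd)
  }
  density_grid(out, origin = grid$origin, spacing = target_spacing,
               map_kind = grid$map_kind)
}

#' Convert a thresholded grid to a point cloud
#'
#' Emits one point per strictly positive voxel, at the voxel-center world
#' coordinate, carrying the voxel value as the point density. The source
#' lattice (origin, spacing, extents) is kept as attributes so that
#' voxel-aligned samplers can recover voxel indices.
#'
#' @param grid a thresholded `density_grid` (background zero).
#' @return A `point_cloud`: a data.frame with columns `x`, `y`, `z`,
#'   `density`, plus attributes `origin`, `spacing` and `grid_dim`.
#' @export
grid_to_pointcloud <- function(grid) {
  stopifnot(is_density_grid(grid))
  pos <- which(grid$values > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("empty blob: grid has no positive voxels")
  xyz <- voxel_centers(grid, pos)
  pc <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   density = grid$values[pos])
  attr(pc, "origin") <- grid$origin
  attr(pc, "spacing") <- grid$spacing
  attr(pc, "grid_dim") <- dim(grid$values)
  class(pc) <- c("point_cloud", "data.frame")
  pc
}

#' Re-voxelize a point cloud onto its source lattice
#'
#' Inverse of [grid_to_pointcloud()] for clouds whose points are voxel
#' centers of a known lattice.
#'
#' @param cloud a `point_cloud` carrying `origin`/`spacing`/`grid_dim`
#'   attributes.
#' @param map_kind map kind of the rebuilt grid.
#' @return A `density_grid` with the cloud's densities at the cloud's voxels
#'   and zero elsewhere.
#' @export
pointcloud_to_grid <- function(cloud, map_kind = "xray_diff") {
  org <- attr(cloud, "origin"); sp <- attr(cloud, "spacing")
  dm <- attr(cloud, "grid_dim")
  if (is.null(org) || is.null(sp) || is.null(dm))
    stop("cloud does not carry source-lattice attributes")
  idx <- cloud_voxel_indices(cloud)
  if (any(idx < 1L) || any(sweep(idx, 2L, dm, ">")))
    stop("cloud contains points outside the source lattice")
  v <- array(0, dim = dm)
  v[idx] <- cloud$density
  density_grid(v, origin = org, spacing = sp, map_kind = map_kind)
}

# 1-based voxel indices of a voxel-aligned cloud on its source lattice
cloud_voxel_indices <- function(cloud) {
  org <- attr(cloud, "origin"); sp <- attr(cloud, "spacing")
  if (is.null(org) || is.null(sp))
    stop("cloud does not carry source-lattice attributes")
  cbind(as.integer(round((cloud$x - org[1]) / sp[1])) + 1L,
        as.integer(round((cloud$y - org[2]) / sp[2])) + 1L,
        as.integer(round((cloud$z - org[3]) / sp[3])) + 1L)
}
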