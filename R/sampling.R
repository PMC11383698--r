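#' Point-sampling configuration
#'
#' Controls how a blob's point cloud is reduced to at most `max_p` points
#' before classification. Strategies: `"uniform"` (meta-voxel partition,
#' keep the maximum-density point per occupied meta-voxel; the default and
#' best-performing strategy), `"random"` (uniform subsample without
#' replacement), `"surface"` (uniform subsample of the blob's outer shell),
#' `"clustering"` (k-means centroids with `k = max_p`).
#'
#' @param strategy one of `"uniform"`, `"random"`, `"surface"`,
#'   `"clustering"`.
#' @param max_p maximum number of points to keep (default 2000).
#' @param seed integer RNG seed for the stochastic strategies.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(strategy = c("uniform", "random", "surface",
                                         "clustering"),
                            max_p = 2000L, seed = 1L) {
  strategy <- match.arg(strategy)
  max_p <- as.integer(max_p)
  if (is.na(max_p) || max_p < 1L) stop("`max_p` must be >= 1")
  structure(list(strategy = strategy, max_p = max_p, seed = as.integer(seed)),
            class = "sampling_config")
}

#' Partition a grid into N^3 meta-voxels
#'
#' Divides each face of the grid by the divisor `N`: the grid is zero-padded
#' (at the high-index corner, so original voxel indices are unchanged) to
#' the next multiple of `N` per axis, then cut into `N^3` equally sized
#' blocks. For a grid of shape `(20, 16, 10)` and `N = 2` this gives 8
#' meta-voxels of shape `(10, 8, 5)`.
#'
#' @param grid_shape integer length-3 grid extents.
#' @param occupancy integer n x 3 matrix of 1-based nonzero voxel indices.
#' @param N divisor (>= 1).
#' @return A `partition_plan`: list with `N`, `meta_shape`, `padded_shape`,
#'   `n_blocks` (`= N^3`) and `nonempty` (occupied meta-voxel count).
#' @export
partition_for_divisor <- function(grid_shape, occupancy, N) {
  grid_shape <- as.integer(grid_shape)
  N <- as.integer(N)
  stopifnot(length(grid_shape) == 3L, N >= 1L)
  occupancy <- matrix(as.integer(occupancy), ncol = 3L)
  meta_shape <- as.integer(ceiling(grid_shape / N))
  padded_shape <- meta_shape * N
  block <- block_index(occupancy, meta_shape)
  structure(list(N = N, meta_shape = meta_shape, padded_shape = padded_shape,
                 n_blocks = N^3, nonempty = length(unique(block))),
            class = "partition_plan")
}

# linearized meta-voxel index (block id) of each voxel index row
block_index <- function(idx, meta_shape) {
  b <- (idx - 1L) %/% rep(meta_shape, each = nrow(idx))
  b[, 1] + b[, 2] * 1000000 + b[, 3] * 1e12
}

#' Choose the meta-voxel divisor for uniform sampling
#'
#' Starting at `N = 1`, the divisor is incremented while the number of
#' occupied meta-voxels stays within `max_p`; the largest such `N` is kept
#' (if `N + 1` overshoots `max_p`, the search stops at `N`). This drives
#' the occupied-meta-voxel count as close to `max_p` as possible from
#' below.
#'
#' @inheritParams partition_for_divisor
#' @param max_p occupancy budget (>= 1).
#' @return The selected `partition_plan`.
#' @export
plan_uniform_partition <- function(grid_shape, occupancy, max_p = 2000L) {
  occupancy <- matrix(as.integer(occupancy), ncol = 3L)
  if (nrow(occupancy) == 0L) stop("occupancy must be non-empty")
  best <- partition_for_divisor(grid_shape, occupancy, 1L)
  n_max <- max(grid_shape)
  N <- 1L
  while (N < n_max) {
    cand <- partition_for_divisor(grid_shape, occupancy, N + 1L)
    if (cand$nonempty > max_p) break
    best <- cand
    N <- N + 1L
  }
  best
}

#' Uniform sampling: maximum-density point per meta-voxel
#'
#' Partitions the cloud's source lattice with [plan_uniform_partition()] and
#' keeps, from every occupied meta-voxel, the single point of maximum
#' density (ties resolved to the lowest linear voxel index, for
#' determinism). Sampled points keep their original coordinates and density
#' values.
#'
#' @param cloud a voxel-aligned `point_cloud`.
#' @param cfg a [sampling_config()].
#' @return A `point_cloud` with at most `max_p` points, a subset of the
#'   input.
#' @export
sample_uniform_max <- function(cloud, cfg = sampling_config()) {
  if (nrow(cloud) == 0L) stop("cloud is empty")
  dm <- attr(cloud, "grid_dim")
  if (is.null(dm)) stop("uniform sampling needs a voxel-aligned cloud")
  idx <- cloud_voxel_indices(cloud)
  plan <- plan_uniform_partition(dm, idx, cfg$max_p)
  block <- block_index(idx, plan$meta_shape)
  lin <- (idx[, 1] - 1) + (idx[, 2] - 1) * dm[1] +
    (idx[, 3] - 1) * as.numeric(dm[1]) * dm[2]
  # within each block: highest density wins, ties to lowest linear index
  ord <- order(block, -cloud$density, lin)
  keep <- ord[!duplicated(block[ord])]
  out <- cloud[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  restore_cloud_attrs(out, cloud)
}

restore_cloud_attrs <- function(out, cloud) {
  attr(out, "origin") <- attr(cloud, "origin")
  attr(out, "spacing") <- attr(cloud, "spacing")
  attr(out, "grid_dim") <- attr(cloud, "grid_dim")
  class(out) <- c("point_cloud", "data.frame")
  out
}

#' Random sampling of a point cloud
#'
#' Draws `min(max_p, n)` distinct points uniformly without replacement,
#' reproducibly under `cfg$seed`.
#'
#' @inheritParams sample_uniform_max
#' @return A `point_cloud`, a subset of the input.
#' @export
sample_random <- function(cloud, cfg = sampling_config(strategy = "random")) {
  n <- nrow(cloud)
  if (n == 0L) stop("cloud is empty")
  if (n <= cfg$max_p) return(cloud)
  keep <- local_seed(cfg$seed, sample.int(n, cfg$max_p))
  out <- cloud[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  restore_cloud_attrs(out, cloud)
}

# evaluate `expr` under a private RNG state, restoring the caller's stream
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Surface sampling of a point cloud
#'
#' The blob's outer shell is the set of points whose voxel has at least one
#' empty 6-neighbor (face-adjacent voxel not in the cloud). Returns
#' `min(max_p, |shell|)` shell points sampled uniformly without
#' replacement.
#'
#' @inheritParams sample_uniform_max
#' @return A `point_cloud` of shell points.
#' @export
sample_surface <- function(cloud, cfg = sampling_config(strategy = "surface")) {
  if (nrow(cloud) == 0L) stop("cloud is empty")
  idx <- cloud_voxel_indices(cloud)
  key <- idx[, 1] + idx[, 2] * 1e5 + idx[, 3] * 1e10
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  on_shell <- rep(FALSE, nrow(idx))
  for (o in seq_len(6L)) {
    nb <- key + offs[o, 1] + offs[o, 2] * 1e5 + offs[o, 3] * 1e10
    on_shell <- on_shell | !(nb %in% key)
  }
  shell_ids <- which(on_shell)
  if (length(shell_ids) > cfg$max_p)
    shell_ids <- sort(local_seed(cfg$seed,
                                 sample(shell_ids, cfg$max_p)))
  out <- cloud[shell_ids, , drop = FALSE]
  rownames(out) <- NULL
  restore_cloud_attrs(out, cloud)
}

#' Clustering sampling: k-means centroids
#'
#' Runs k-means with `k = min(max_p, n)` on the point coordinates and
#' returns the centroids as the sampled points. Centroids are synthetic
#' points, so each centroid's density is the mean density of its cluster's
#' members. Initialization is seeded, making the result reproducible.
#'
#' @inheritParams sample_uniform_max
#' @return A `point_cloud` of centroids (not a subset of the input).
#' @export
sample_cluster <- function(cloud, cfg = sampling_config(strategy = "clustering")) {
  n <- nrow(cloud)
  if (n == 0L) stop("cloud is empty")
  k <- min(cfg$max_p, n)
  if (k == n) return(cloud)
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  km <- local_seed(cfg$seed,
                   kmeans(xyz, centers = k, iter.max = 50L, nstart = 1L))
  dens <- as.numeric(tapply(cloud$density, km$cluster, mean))
  out <- data.frame(x = km$centers[, 1], y = km$centers[, 2],
                    z = km$centers[, 3], density = dens)
  rownames(out) <- NULL
  restore_cloud_attrs(out, cloud)
}

#' Sample a point cloud with the configured strategy
#'
#' Dispatches to [sample_uniform_max()], [sample_random()],
#' [sample_surface()] or [sample_cluster()].
#'
#' @inheritParams sample_uniform_max
#' @return A `point_cloud` with at most `cfg$max_p` points.
#' @export
sample_points <- function(cloud, cfg = sampling_config()) {
  switch(cfg$strategy,
         uniform = sample_uniform_max(cloud, cfg),
         random = sample_random(cloud, cfg),
         surface = sample_surface(cloud, cfg),
         clustering = sample_cluster(cloud, cfg))
}
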