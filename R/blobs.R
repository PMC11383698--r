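#' X-ray ligand quality-filter configuration
#'
#' Rejection thresholds for crystallographic ligand blobs. A blob is
#' rejected if *any* criterion triggers: resolution worse than
#' `max_resolution`, RSCC below `min_rscc`, RSZO below `min_rszo`, RSZD at
#' or above `max_rszd` (inclusive bound), R factor above `max_r_factor`, or
#' occupancy below `min_occupancy`.
#'
#' @param max_resolution reject if resolution > this (default 4.0 A).
#' @param min_rscc reject if RSCC < this (default 0.6).
#' @param min_rszo reject if RSZO < this (default 1.0).
#' @param max_rszd reject if RSZD >= this (default 6.0; inclusive).
#' @param max_r_factor reject if R factor > this (default 0.3).
#' @param min_occupancy reject if occupancy < this (default 0.3).
#' @return An object of class `xray_filter_config`.
#' @export
xray_filter_config <- function(max_resolution = 4.0, min_rscc = 0.6,
                               min_rszo = 1.0, max_rszd = 6.0,
                               max_r_factor = 0.3, min_occupancy = 0.3) {
  cfg <- list(max_resolution = max_resolution, min_rscc = min_rscc,
              min_rszo = min_rszo, max_rszd = max_rszd,
              max_r_factor = max_r_factor, min_occupancy = min_occupancy)
  if (any(!vapply(cfg, is.finite, logical(1))))
    stop("all filter thresholds must be finite")
  structure(cfg, class = "xray_filter_config")
}

#' CryoEM ligand quality-filter configuration
#'
#' A cryoEM blob passes only if its Q-score is at least `min_q_score`
#' (inclusive) and its volume strictly exceeds `min_volume`.
#'
#' @param min_q_score inclusive lower bound on the Q-score (default 0.6).
#' @param min_volume exclusive lower bound on blob volume in cubic Angstrom
#'   (default 2.14).
#' @return An object of class `cryo_filter_config`.
#' @export
cryo_filter_config <- function(min_q_score = 0.6, min_volume = 2.14) {
  structure(list(min_q_score = min_q_score, min_volume = min_volume),
            class = "cryo_filter_config")
}

#' Extract connected density blobs from a thresholded map
#'
#' Labels connected components of strictly positive voxels using
#' 26-connectivity (face, edge and corner neighbors all connect, since
#' density blobs commonly touch diagonally) and returns one cropped grid per
#' component, sorted by descending voxel count. Each cropped grid keeps its
#' world origin, so blob voxel centers stay at their original coordinates.
#'
#' @param grid a thresholded `density_grid`.
#' @return A list of `density_grid` objects (possibly empty).
#' @export
extract_blobs <- function(grid) {
  stopifnot(is_density_grid(grid))
  mask <- grid$values > 0
  if (!any(mask)) return(list())
  d <- dim(grid$values)
  labels <- label_components26(as.logical(mask), as.integer(d))
  labels <- array(labels, dim = d)
  sizes <- tabulate(labels[labels > 0L])
  out <- lapply(order(sizes, decreasing = TRUE), function(lab) {
    idx <- which(labels == lab, arr.ind = TRUE)
    lo <- apply(idx, 2L, min)
    hi <- apply(idx, 2L, max)
    vals <- array(0, dim = hi - lo + 1L)
    sel <- sweep(idx, 2L, lo - 1L)
    vals[sel] <- grid$values[idx]
    density_grid(vals,
                 origin = grid$origin + (lo - 1L) * grid$spacing,
                 spacing = grid$spacing, map_kind = grid$map_kind)
  })
  out
}

# evaluate one rejection rule, skipping absent (NA) optional metrics
check_rule <- function(value, triggered, reason, reasons) {
  if (!is.na(value) && triggered) c(reasons, reason) else reasons
}

#' Apply the X-ray ligand quality filters
#'
#' Evaluates the rejection criteria of [xray_filter_config()]. Resolution
#' must be present; any other metric that is absent (`NA`) simply skips its
#' test, since e.g. cryoEM-derived blobs lack crystallographic metrics.
#'
#' @param meta a [quality_metadata()].
#' @param cfg an [xray_filter_config()].
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   triggered criteria, empty when passing).
#' @export
passes_xray_filters <- function(meta, cfg = xray_filter_config()) {
  stopifnot(inherits(meta, "quality_metadata"))
  r <- character(0)
  r <- check_rule(meta$resolution, meta$resolution > cfg$max_resolution,
                  "resolution", r)
  r <- check_rule(meta$rscc, meta$rscc < cfg$min_rscc, "rscc", r)
  r <- check_rule(meta$rszo, meta$rszo < cfg$min_rszo, "rszo", r)
  r <- check_rule(meta$rszd, meta$rszd >= cfg$max_rszd, "rszd", r)
  r <- check_rule(meta$r_factor, meta$r_factor > cfg$max_r_factor,
                  "r_factor", r)
  r <- check_rule(meta$occupancy, meta$occupancy < cfg$min_occupancy,
                  "occupancy", r)
  list(pass = length(r) == 0L, reasons = r)
}

#' Apply the cryoEM ligand quality filters
#'
#' A blob passes iff its Q-score is `>= min_q_score` (the bound is
#' inclusive: a score of exactly 0.6 passes) and its volume is strictly
#' greater than `min_volume` (a volume of exactly 2.14 cubic Angstrom is
#' rejected).
#'
#' @param meta a [quality_metadata()] with `q_score` and `volume` present.
#' @param cfg a [cryo_filter_config()].
#' @return List with `pass` (logical) and `reasons` (character vector).
#' @export
passes_cryoem_filters <- function(meta, cfg = cryo_filter_config()) {
  stopifnot(inherits(meta, "quality_metadata"))
  if (is.na(meta$q_score) || is.na(meta$volume))
    stop("cryoEM filters require q_score and volume")
  r <- character(0)
  if (meta$q_score < cfg$min_q_score) r <- c(r, "q_score")
  if (meta$volume <= cfg$min_volume) r <- c(r, "volume")
  list(pass = length(r) == 0L, reasons = r)
}
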