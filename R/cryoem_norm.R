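#' Threshold configuration for cryoEM map normalization
#'
#' Parameters of the three-step cryoEM normalization. `median_window_sd` is
#' the half-width (in map standard deviations) of the band around the median
#' that is discarded when estimating the contour threshold, which suppresses
#' the zero-value spike that masking introduces into cryoEM histograms.
#' `quantile` is the cumulative probability at which the contour is placed;
#' the default is the standard normal CDF at `sigma_equivalent = 2.8`, i.e.
#' the quantile that reproduces the conventional 2.8-sigma crystallographic
#' contour on a normally distributed map.
#'
#' @param median_window_sd half-width of the discarded band, in SD units
#'   (default 0.5, >= 0).
#' @param sigma_equivalent sigma level the quantile mirrors (default 2.8).
#' @param quantile cumulative probability in (0, 1); defaults to
#'   `sigma_to_quantile(sigma_equivalent)`.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(median_window_sd = 0.5, sigma_equivalent = 2.8,
                             quantile = sigma_to_quantile(sigma_equivalent)) {
  if (!is.finite(quantile) || quantile <= 0 || quantile >= 1)
    stop("`quantile` must lie strictly inside (0, 1)")
  if (!is.finite(median_window_sd) || median_window_sd < 0)
    stop("`median_window_sd` must be >= 0")
  structure(list(median_window_sd = median_window_sd,
                 quantile = quantile,
                 sigma_equivalent = sigma_equivalent),
            class = "threshold_config")
}

#' Convert a sigma level to a cumulative probability
#'
#' The standard normal CDF at `n_sigma`; used to translate the
#' crystallographic sigma-contour convention into a quantile that can be
#' applied to non-normal cryoEM map histograms. `sigma_to_quantile(2.8)`
#' is approximately 0.9974.
#'
#' @param n_sigma finite sigma level.
#' @return Cumulative probability in (0, 1).
#' @export
sigma_to_quantile <- function(n_sigma) {
  if (any(!is.finite(n_sigma))) stop("`n_sigma` must be finite")
  pnorm(n_sigma)
}

# population SD (divide by n, not n-1): the map is the whole population of
# voxels, matching the crystallographic sigma-scale convention
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Remove the central band of a zero-inflated value distribution
#'
#' Drops every value within `median_window_sd` population standard
#' deviations of the median, leaving the tails. On masked cryoEM maps the
#' discarded band contains the zero spike, so quantiles of the remainder are
#' no longer dragged down by masking. Order of the surviving values is
#' preserved.
#'
#' @param values numeric vector of map values (length >= 2, SD > 0).
#' @param cfg a [threshold_config()].
#' @return The values outside the band, in input order.
#' @export
reduce_zero_inflation <- function(values, cfg = threshold_config()) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- median(values)
  s <- pop_sd(values)
  if (s == 0) stop("degenerate input: zero standard deviation")
  values[abs(values - m) > cfg$median_window_sd * s]
}

#' Empirical quantile threshold of a value collection
#'
#' The empirical quantile at `cfg$quantile`, using linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param values non-empty numeric vector.
#' @param cfg a [threshold_config()].
#' @return The threshold, in map units.
#' @export
compute_quantile_threshold <- function(values, cfg = threshold_config()) {
  if (length(values) == 0L) stop("degenerate input: no values left to threshold")
  unname(quantile(values, probs = cfg$quantile, type = 7, names = FALSE))
}

#' Resolution-keyed voxel rescale table
#'
#' Maps a resolution bin to the reference value that the lowest non-zero
#' voxel of a normalized cryoEM blob should take: the average lowest
#' non-zero value of thresholded X-ray blobs at that resolution. Bins are
#' left-closed, right-open (`[e_i, e_{i+1})`), except the last bin which
#' includes its right edge.
#'
#' The packaged default ([default_rescale_table()]) is computed from the
#' synthetic X-ray blob generator; for production use, build a table from
#' real X-ray blobs with [build_rescale_table()].
#'
#' @param edges strictly increasing numeric vector of bin edges (Angstrom),
#'   length m + 1 for m bins.
#' @param reference strictly positive numeric vector of length m.
#' @return An object of class `rescale_table`.
#' @export
rescale_table <- function(edges, reference) {
  edges <- as.numeric(edges); reference <- as.numeric(reference)
  if (length(edges) != length(reference) + 1L)
    stop("need one more edge than reference value")
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference values must be strictly positive")
  structure(list(edges = edges, reference = reference),
            class = "rescale_table")
}

#' Look up the reference value for a resolution
#'
#' @param table a [rescale_table()].
#' @param resolution resolution in Angstrom.
#' @return The reference map value for the bin containing `resolution`.
#' @export
rescale_reference <- function(table, resolution) {
  stopifnot(inherits(table, "rescale_table"))
  e <- table$edges
  if (resolution < e[1] || resolution > e[length(e)])
    stop(sprintf("resolution %.3f A outside table range [%.3f, %.3f]",
                 resolution, e[1], e[length(e)]))
  bin <- findInterval(resolution, e, rightmost.closed = TRUE)
  table$reference[bin]
}

#' Default synthetic rescale table
#'
#' Reference values for resolution bins 1.0--4.0 Angstrom in 0.5 Angstrom
#' steps, computed as the mean lowest non-zero voxel value of thresholded
#' synthetic X-ray blobs rendered at resolutions in each bin (see
#' [build_rescale_table()]; the constants here are frozen from
#' `build_rescale_table(seed = 20240101)`). They stand in for reference
#' values derived from real X-ray ligand blobs, which users should supply
#' for production work.
#'
#' @return A `rescale_table`.
#' @export
default_rescale_table <- function() {
  rescale_table(edges = seq(1.0, 4.0, by = 0.5),
                reference = DEFAULT_RESCALE_REFERENCE)
}

#' Build a rescale table from synthetic X-ray blobs
#'
#' For each resolution bin, renders `n_per_bin` synthetic X-ray blobs at
#' resolutions spread across the bin, thresholds them at the 2.8-sigma
#' contour, and averages their lowest non-zero voxel values.
#'
#' @param edges bin edges (Angstrom), default `seq(1, 4, by = 0.5)`.
#' @param n_per_bin blobs rendered per bin (default 8).
#' @param seed RNG seed.
#' @return A `rescale_table`.
#' @export
build_rescale_table <- function(edges = seq(1.0, 4.0, by = 0.5),
                                n_per_bin = 8L, seed = 20240101L) {
  templates <- ligand_templates()
  reference <- vapply(seq_len(length(edges) - 1L), function(b) {
    lows <- vapply(seq_len(n_per_bin), function(i) {
      res <- edges[b] + (i - 0.5) / n_per_bin * (edges[b + 1L] - edges[b])
      tpl <- templates[[(i - 1L) %% length(templates) + 1L]]
      spec <- synthetic_spec(atoms = tpl, resolution = res,
                             map_kind = "xray_diff",
                             seed = seed + 1000L * b + i)
      g <- render_blob(spec)
      thr <- threshold_xray(g)
      min(thr$values[thr$values > 0])
    }, numeric(1))
    mean(lows)
  }, numeric(1))
  rescale_table(edges, reference)
}

#' Multiplicatively rescale a thresholded grid to a reference level
#'
#' Multiplies every voxel by `reference / min(positive values)` so the
#' lowest non-zero value equals the table's reference for the blob's
#' resolution, putting cryoEM voxel values on the scale of X-ray blobs.
#'
#' @param grid thresholded `density_grid` with >= 1 positive voxel.
#' @param resolution resolution in Angstrom.
#' @param table a [rescale_table()].
#' @return List with elements `grid` (rescaled) and `factor`.
#' @export
rescale_voxels <- function(grid, resolution, table = default_rescale_table()) {
  stopifnot(is_density_grid(grid))
  pos <- grid$values[grid$values > 0]
  if (length(pos) == 0L) stop("grid has no positive voxels to rescale")
  ref <- rescale_reference(table, resolution)
  low <- min(pos)
  factor <- ref / low
  out <- grid
  if (factor != 1) {
    # divide first so the lowest positive voxel lands on the reference exactly
    out$values <- (grid$values / low) * ref
  }
  list(grid = out, factor = factor)
}

#' Normalize a cryoEM difference map onto the X-ray blob scale
#'
#' The three-step cryoEM normalization: (1) *zero-inflation reduction* —
#' values within `median_window_sd` SD of the median are set aside, for
#' threshold selection only; (2) *quantile thresholding* — the empirical
#' quantile of the remaining values at the 2.8-sigma-equivalent level
#' becomes the contour, and voxels of the **original** map below it are
#' zeroed; (3) *voxel value rescaling* — surviving values are multiplied so
#' the lowest non-zero value matches the X-ray reference for the map's
#' resolution.
#'
#' @param grid a `density_grid` with `map_kind == "cryoem"`.
#' @param resolution map resolution in Angstrom.
#' @param cfg a [threshold_config()].
#' @param table a [rescale_table()].
#' @return List with elements `grid` (normalized `density_grid`) and
#'   `report` (a `normalization_report` recording the median, SD, retained
#'   fraction after the contour, the naive threshold computed without zero
#'   removal, the final threshold, and the rescale factor).
#' @export
normalize_cryoem_map <- function(grid, resolution, cfg = threshold_config(),
                                 table = default_rescale_table()) {
  stopifnot(is_density_grid(grid))
  if (grid$map_kind != "cryoem")
    stop("normalize_cryoem_map applies to cryoem maps; got ", grid$map_kind)
  v <- as.numeric(grid$values)
  naive_threshold <- compute_quantile_threshold(v, cfg)
  reduced <- reduce_zero_inflation(v, cfg)
  threshold <- compute_quantile_threshold(reduced, cfg)
  thr_grid <- grid
  thr_grid$values[thr_grid$values < threshold] <- 0
  if (!any(thr_grid$values > 0))
    stop("threshold removed every voxel; map has no density above the contour")
  res <- rescale_voxels(thr_grid, resolution, table)
  report <- structure(list(
    median = median(v),
    sd = pop_sd(v),
    retained_fraction = mean(grid$values >= threshold),
    naive_threshold = naive_threshold,
    threshold = threshold,
    rescale_factor = res$factor
  ), class = "normalization_report")
  list(grid = res$grid, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("<normalization_report>\n")
  cat(sprintf("  median           : %.6g\n", x$median))
  cat(sprintf("  sd               : %.6g\n", x$sd))
  cat(sprintf("  naive threshold  : %.6g\n", x$naive_threshold))
  cat(sprintf("  final threshold  : %.6g\n", x$threshold))
  cat(sprintf("  retained fraction: %.4f\n", x$retained_fraction))
  cat(sprintf("  rescale factor   : %.6g\n", x$rescale_factor))
  invisible(x)
}
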