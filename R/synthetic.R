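#' Specification of a synthetic density blob or map
#'
#' Describes a pseudo-ligand rendered as a sum of atom-centered Gaussians
#' whose width grows with resolution (peaks of bonded atoms merge at poor
#' resolution), on the canonical 0.2 Angstrom lattice, plus i.i.d. Gaussian
#' background noise. `map_kind = "cryoem"` additionally emulates masking by
#' forcing a fraction of map voxels to exactly zero, reproducing the
#' zero-inflated histograms of deposited cryoEM maps; X-ray-kind maps have
#' near-normal value histograms.
#'
#' @param atoms numeric n x 4 matrix: columns x, y, z (Angstrom) and pseudo
#'   atomic number (peak amplitude is proportional to it, mimicking
#'   heavier-atom brightness).
#' @param resolution nominal resolution in Angstrom (> 0).
#' @param peak_width_rule Gaussian sigma per Angstrom of resolution
#'   (default 0.4, so a 2 Angstrom-resolution atom has sigma 0.8 Angstrom).
#' @param noise_sd background noise SD in map units (default 0.1).
#' @param map_kind `"xray_diff"` or `"cryoem"`.
#' @param zero_inflation fraction of voxels forced to exactly zero in
#'   [render_map()] (cryoem kind only; in `[0, 1)`).
#' @param box_padding empty margin around the atoms, Angstrom (default 3).
#' @param spacing voxel spacing (default the canonical 0.2 Angstrom).
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(atoms, resolution = 2.0, peak_width_rule = 0.4,
                           noise_sd = 0.1,
                           map_kind = c("xray_diff", "cryoem"),
                           zero_inflation = 0, box_padding = 3.0,
                           spacing = CANONICAL_SPACING, seed = 1L) {
  map_kind <- match.arg(map_kind)
  atoms <- matrix(as.numeric(atoms), ncol = 4L)
  if (nrow(atoms) < 1L) stop("need at least one template atom")
  if (!is.finite(resolution) || resolution <= 0)
    stop("`resolution` must be > 0")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("`zero_inflation` must be in [0, 1)")
  if (zero_inflation > 0 && map_kind != "cryoem")
    stop("zero inflation applies only to cryoem-kind maps")
  structure(list(atoms = atoms, resolution = resolution,
                 peak_width_rule = peak_width_rule, noise_sd = noise_sd,
                 map_kind = map_kind, zero_inflation = zero_inflation,
                 box_padding = box_padding, spacing = spacing,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# accumulate atom Gaussians onto a grid with given axis coordinate vectors.
# The Gaussian is separable, so each atom is an outer product of axis terms.
render_atoms <- function(xs, ys, zs, atoms, sigma) {
  field <- array(0, dim = c(length(xs), length(ys), length(zs)))
  for (a in seq_len(nrow(atoms))) {
    gx <- exp(-(xs - atoms[a, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - atoms[a, 2])^2 / (2 * sigma^2))
    gz <- exp(-(zs - atoms[a, 3])^2 / (2 * sigma^2))
    field <- field + atoms[a, 4] * outer(outer(gx, gy), gz)
  }
  field
}

#' Render a synthetic ligand blob
#'
#' Samples the sum of atom-centered Gaussians (sigma =
#' `peak_width_rule * resolution`, amplitude proportional to the pseudo
#' atomic number) on a grid covering the atoms plus `box_padding`, and adds
#' seeded Gaussian noise of SD `noise_sd`. Deterministic for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A `density_grid`.
#' @export
render_blob <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sigma <- spec$peak_width_rule * spec$resolution
  lo <- apply(spec$atoms[, 1:3, drop = FALSE], 2L, min) - spec$box_padding
  hi <- apply(spec$atoms[, 1:3, drop = FALSE], 2L, max) + spec$box_padding
  n <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(n[a]) - 1) * spec$spacing)
  field <- render_atoms(ax[[1]], ax[[2]], ax[[3]], spec$atoms, sigma)
  if (spec$noise_sd > 0)
    field <- field + local_seed(spec$seed,
                                array(rnorm(prod(n), sd = spec$noise_sd),
                                      dim = n))
  density_grid(field, origin = lo, spacing = spec$spacing,
               map_kind = spec$map_kind)
}

#' Render a synthetic whole map with decoy blobs
#'
#' Builds a background-noise map, optionally zero-inflates it (cryoem kind:
#' a seeded random fraction of voxels is set to exactly zero, emulating
#' masking), and places the spec's ligand plus `n_decoys` copies at
#' non-overlapping random positions. Placement that cannot avoid overlap
#' after 200 attempts raises an error.
#'
#' @param spec a [synthetic_spec()].
#' @param n_decoys number of additional decoy blobs (default 0).
#' @param box_size map edge length in Angstrom (default 24).
#' @return A `density_grid`.
#' @export
render_map <- function(spec, n_decoys = 0L, box_size = 24) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sigma <- spec$peak_width_rule * spec$resolution
  n <- as.integer(ceiling(box_size / spec$spacing)) + 1L
  ax <- (seq_len(n) - 1) * spec$spacing
  local_seed(spec$seed, {
    field <- array(rnorm(n^3, sd = spec$noise_sd), dim = c(n, n, n))
    centered <- sweep(spec$atoms[, 1:3, drop = FALSE], 2L,
                      colMeans(spec$atoms[, 1:3, drop = FALSE]))
    r_blob <- max(sqrt(rowSums(centered^2))) + 3 * sigma
    if (2 * r_blob * (n_decoys + 1)^(1 / 3) > box_size)
      stop("placement error: box too small for ", n_decoys + 1, " blobs")
    centers <- matrix(numeric(0), ncol = 3L)
    for (b in seq_len(n_decoys + 1L)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        cand <- runif(3, min = r_blob, max = box_size - r_blob)
        if (nrow(centers) == 0L ||
            all(sqrt(rowSums(sweep(centers, 2L, cand)^2)) > 2 * r_blob)) {
          centers <- rbind(centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("placement error: could not place blob ", b,
                        " without overlap")
      at <- cbind(sweep(centered, 2L, cand, "+"), spec$atoms[, 4])
      field <- field + render_atoms(ax, ax, ax, at, sigma)
    }
    if (spec$map_kind == "cryoem" && spec$zero_inflation > 0) {
      nz <- round(spec$zero_inflation * length(field))
      field[sample.int(length(field), nz)] <- 0
    }
    density_grid(field, origin = c(0, 0, 0), spacing = spec$spacing,
                 map_kind = spec$map_kind)
  })
}

#' Shape templates for synthetic ligand classes
#'
#' Geometrically distinct pseudo-ligand atom templates (n x 4 matrices of
#' x, y, z, pseudo atomic number): a phosphate-like tetrahedron (5 atoms), a
#' linear chain (6 atoms), a hexagonal ring (6 atoms), a planar cross
#' (7 atoms), and a cube (8 atoms). Used as class prototypes by
#' [make_classification_dataset()] and as generic fixtures elsewhere.
#'
#' @return Named list of atom-template matrices.
#' @export
ligand_templates <- function() {
  b <- 1.6  # bond length, Angstrom
  tetra_xyz <- rbind(c(0, 0, 0),
                     b * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                               c(-1, -1, 1)) / sqrt(3))
  tetra <- cbind(tetra_xyz, c(15, 8, 8, 8, 8))
  chain <- cbind((0:5) * 1.5, 0, 0, 6)
  ang <- seq(0, 2 * pi, length.out = 7L)[1:6]
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0, 6)
  cross <- rbind(c(0, 0, 0, 7),
                 cbind(c(1.5, -1.5, 0, 0, 0, 0), c(0, 0, 1.5, -1.5, 0, 0),
                       c(0, 0, 0, 0, 1.5, -1.5), 6))
  cube <- cbind(expand.grid(c(0, 1.55), c(0, 1.55), c(0, 1.55)), 6)
  lapply(list(tetrahedron = tetra, chain = chain, ring = ring,
              cross = cross, cube = as.matrix(cube)),
         function(m) {
           m <- as.matrix(m); dimnames(m) <- NULL; m
         })
}

# a uniformly random 3D rotation matrix (QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3L))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a labeled synthetic classification dataset
#'
#' Renders `n_per_class` blobs for each of `n_classes` template shapes
#' (see [ligand_templates()]), each with a random rigid rotation, per-atom
#' coordinate jitter and background noise, then thresholds at the
#' 2.8-sigma contour and samples the resulting cloud with the uniform
#' maximum-density strategy. Classes are geometrically well separated, so a
#' capable classifier should recover the labels from held-out blobs.
#'
#' @param n_classes number of classes (2 to 5).
#' @param n_per_class blobs per class.
#' @param seed integer RNG seed.
#' @param max_p point budget per blob (default 512).
#' @param resolution rendering resolution in Angstrom (default 1.5).
#' @param jitter_sd per-atom positional jitter SD in Angstrom (default 0.1).
#' @return List with `clouds` (list of `point_cloud`) and `labels`
#'   (character vector of template names).
#' @export
make_classification_dataset <- function(n_classes = 3L, n_per_class = 30L,
                                        seed = 1L, max_p = 512L,
                                        resolution = 1.5, jitter_sd = 0.1) {
  templates <- ligand_templates()
  if (n_classes < 2L || n_classes > length(templates))
    stop("`n_classes` must be between 2 and ", length(templates))
  templates <- templates[seq_len(n_classes)]
  cfg <- sampling_config(strategy = "uniform", max_p = max_p)
  clouds <- list()
  labels <- character(0)
  k <- 0L
  for (cls in names(templates)) {
    tpl <- templates[[cls]]
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sample_seed <- seed * 10000L + k
      xyz <- local_seed(sample_seed, {
        rot <- random_rotation()
        t(rot %*% t(tpl[, 1:3])) +
          matrix(rnorm(3L * nrow(tpl), sd = jitter_sd), ncol = 3L)
      })
      spec <- synthetic_spec(atoms = cbind(xyz, tpl[, 4]),
                             resolution = resolution,
                             map_kind = "xray_diff", seed = sample_seed)
      thr <- threshold_xray(render_blob(spec))
      clouds[[k]] <- sample_uniform_max(grid_to_pointcloud(thr), cfg)
      labels[k] <- cls
    }
  }
  list(clouds = clouds, labels = labels)
}
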