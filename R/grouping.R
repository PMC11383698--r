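#' Construct a molecular graph
#'
#' A hydrogen-free molecular graph: atoms carry an atomic number and an
#' optional chirality flag; bonds are unordered pairs of atom indices.
#' This is the input to ligand-group signature computation.
#'
#' @param z integer vector of atomic numbers (>= 1), one per atom.
#' @param bonds two-column matrix of 1-based atom index pairs (may have zero
#'   rows).
#' @param chirality character vector of per-atom flags (`"none"`, `"R"` or
#'   `"S"`); recycled if length 1.
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(z, bonds = matrix(integer(0), ncol = 2L),
                            chirality = "none") {
  z <- as.integer(z)
  if (length(z) < 1L) stop("graph must have at least one atom")
  if (any(is.na(z)) || any(z < 1L)) stop("atomic numbers must be integers >= 1")
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) > 0L) {
    if (any(is.na(bonds)) || any(bonds < 1L) || any(bonds > length(z)))
      stop("bond endpoints must index atoms")
    if (any(bonds[, 1] == bonds[, 2])) stop("bond endpoints must be distinct")
  }
  chirality <- rep_len(as.character(chirality), length(z))
  if (!all(chirality %in% c("none", "R", "S")))
    stop("chirality flags must be 'none', 'R' or 'S'")
  structure(list(z = z, bonds = bonds, chirality = chirality),
            class = "molecular_graph")
}

#' Compute a ligand-group signature
#'
#' A graph-invariant fingerprint of the features that make ligands
#' indistinguishable by density alone: heavy-atom count, ring count (cycle
#' rank: bonds - atoms + connected components), connectivity (the multiset
#' of degree-annotated atomic numbers together with the multiset of bonded
#' atomic-number pairs), and the multiset of chirality flags. Identical for
#' any relabeling of the same graph; it is a necessary-but-not-sufficient
#' isomorphism invariant (weaker than full canonization), which suffices to
#' merge density-equivalent ligands into groups.
#'
#' @param graph a [molecular_graph()].
#' @return An object of class `group_signature` with fields `n_atoms`,
#'   `n_rings`, `connectivity`, `chirality` and a canonical `key` string.
#' @export
group_signature <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- length(graph$z)
  nb <- nrow(graph$bonds)
  if (nb > 0L) {
    g <- igraph::graph_from_edgelist(graph$bonds, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    comp <- igraph::components(g)$no
    degree <- igraph::degree(g)
  } else {
    comp <- n
    degree <- rep(0L, n)
  }
  n_rings <- nb - n + comp
  atom_ms <- paste(sort(paste0(graph$z, "d", degree)), collapse = ",")
  if (nb > 0L) {
    ez <- cbind(graph$z[graph$bonds[, 1]], graph$z[graph$bonds[, 2]])
    ez <- t(apply(ez, 1L, sort))
    edge_ms <- paste(sort(paste0(ez[, 1], "-", ez[, 2])), collapse = ",")
  } else edge_ms <- ""
  chi <- paste(sort(graph$chirality[graph$chirality != "none"]), collapse = ",")
  key <- paste(n, n_rings, atom_ms, edge_ms, chi, sep = "|")
  structure(list(n_atoms = n, n_rings = n_rings,
                 connectivity = paste(atom_ms, edge_ms, sep = ";"),
                 chirality = chi, key = key),
            class = "group_signature")
}

#' @export
print.group_signature <- function(x, ...) {
  cat(sprintf("<group_signature> %d heavy atoms, %d rings\n",
              x$n_atoms, x$n_rings))
  cat("  key:", x$key, "\n")
  invisible(x)
}

#' Build a ligand-group catalog
#'
#' Signatures observed in at least `min_instances` blobs become named
#' groups; every other signature maps to the collective `rare` class. Named
#' groups are ordered by descending instance count (ties alphabetically by
#' label), with the rare label appended last.
#'
#' @param labels character vector of group labels, one per signature.
#' @param signatures character vector of signature keys (or a list of
#'   `group_signature` objects).
#' @param counts integer vector of blob instance counts (>= 0).
#' @param min_instances minimum count for a named group (default 100,
#'   inclusive).
#' @param rare_label label of the collective class (default `"rare"`).
#' @return An object of class `group_catalog` with fields `labels` (ordered
#'   label vector including the rare label), `map` (named character vector:
#'   signature key -> label) and the cutoff parameters.
#' @export
build_catalog <- function(labels, signatures, counts, min_instances = 100L,
                          rare_label = "rare") {
  if (is.list(signatures))
    signatures <- vapply(signatures, function(s) s$key, character(1))
  stopifnot(length(labels) == length(signatures),
            length(labels) == length(counts))
  if (any(counts < 0)) stop("counts must be >= 0")
  if (anyDuplicated(signatures)) stop("signatures must be unique")
  named <- counts >= min_instances
  ord <- order(-counts[named], labels[named])
  catalog_labels <- c(labels[named][ord], rare_label)
  if (anyDuplicated(catalog_labels)) stop("group labels must be unique")
  map <- ifelse(named, labels, rare_label)
  names(map) <- signatures
  structure(list(labels = catalog_labels, map = map,
                 min_instances = as.integer(min_instances),
                 rare_label = rare_label),
            class = "group_catalog")
}

#' @export
print.group_catalog <- function(x, ...) {
  cat(sprintf("<group_catalog> %d groups (incl. '%s'), cutoff >= %d instances\n",
              length(x$labels), x$rare_label, x$min_instances))
  invisible(x)
}

#' Look up the catalog label for a signature
#'
#' @param catalog a [build_catalog()] result.
#' @param signature a `group_signature` or signature key string.
#' @return The group label; unknown signatures map to the rare label.
#' @export
catalog_label <- function(catalog, signature) {
  stopifnot(inherits(catalog, "group_catalog"))
  key <- if (inherits(signature, "group_signature")) signature$key
         else as.character(signature)
  lbl <- unname(catalog$map[key])
  ifelse(is.na(lbl), catalog$rare_label, lbl)
}

#' Provisional 219-label catalog
#'
#' The published classifier distinguishes 218 named ligand groups plus the
#' collective `rare` class (219 labels). The group definitions themselves
#' are not published, so this catalog carries synthetic placeholder label
#' names (`group_001` ... `group_218`, then `rare`) purely to fix the size
#' and ordering of the output head; replace it with a catalog built from
#' real data via [build_catalog()] for interoperable predictions.
#'
#' @return A `group_catalog` with 219 labels and an empty signature map.
#' @export
provisional_catalog_219 <- function() {
  labels <- c(sprintf("group_%03d", 1:218), "rare")
  structure(list(labels = labels, map = setNames(character(0), character(0)),
                 min_instances = 100L, rare_label = "rare"),
            class = "group_catalog")
}

#' Read a molecular graph from JSON
#'
#' Schema: `{"atoms": [{"z": 8, "chirality": "none"}, ...],
#' "bonds": [[0, 1], ...]}` with 0-based bond indices.
#'
#' @param path JSON file path.
#' @return A `molecular_graph`.
#' @export
read_molecular_graph_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyMatrix = TRUE)
  atoms <- obj$atoms
  z <- as.integer(atoms$z)
  chir <- if (!is.null(atoms$chirality)) atoms$chirality else "none"
  chir[is.na(chir)] <- "none"
  bonds <- if (length(obj$bonds)) matrix(as.integer(obj$bonds), ncol = 2L) + 1L
           else matrix(integer(0), ncol = 2L)
  molecular_graph(z, bonds, chir)
}

#' Read a molecular graph from an SDF/MOL V2000 connection table
#'
#' Parses the first molecule of an SDF (or a bare MOL file), dropping
#' hydrogens and any bonds to them. Chirality flags are not read from SDF
#' (they require 3D perception) and default to `"none"`.
#'
#' @param path SDF/MOL file path.
#' @return A `molecular_graph`.
#' @export
read_molecular_graph_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("format error: SDF too short")
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n_atoms) || n_atoms < 1L)
    stop("format error: bad counts line in SDF")
  atom_lines <- lines[5:(4L + n_atoms)]
  sym <- toupper(trimws(substr(atom_lines, 32L, 34L)))
  z <- ELEMENT_Z[sym]
  if (any(is.na(z))) stop("unknown element symbol in SDF: ",
                          paste(unique(sym[is.na(z)]), collapse = ", "))
  bonds <- matrix(integer(0), ncol = 2L)
  if (n_bonds > 0L) {
    bl <- lines[(5L + n_atoms):(4L + n_atoms + n_bonds)]
    bonds <- cbind(as.integer(substr(bl, 1L, 3L)),
                   as.integer(substr(bl, 4L, 6L)))
  }
  heavy <- which(z != 1L)
  remap <- match(seq_along(z), heavy)
  keep <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
  bonds <- matrix(remap[bonds[keep, , drop = FALSE]], ncol = 2L)
  molecular_graph(unname(z[heavy]), bonds)
}

ELEMENT_Z <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, NA. = 11L, MG = 12L,
               P = 15L, S = 16L, CL = 17L, K = 19L, CA = 20L, MN = 25L,
               FE = 26L, CO = 27L, NI = 28L, CU = 29L, ZN = 30L, SE = 34L,
               BR = 35L, I = 53L)
names(ELEMENT_Z)[names(ELEMENT_Z) == "NA."] <- "NA"
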