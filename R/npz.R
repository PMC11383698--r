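# Minimal NPY v1.0 + uncompressed ZIP (NPZ) serialization for blob archives.
# Supports the dtypes the blob format needs: little-endian float64/float32,
# int32/int64, and fixed-width unicode ('<U*') scalars for the tag fields.

npy_serialize <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    cp <- utf8ToInt(enc2utf8(x))
    width <- max(length(cp), 1L)
    descr <- sprintf("<U%d", width)
    shape <- "()"
    payload <- raw(4L * width)
    if (length(cp) > 0) {
      u32 <- writeBin(as.integer(cp), raw(), size = 4L, endian = "little")
      payload[seq_along(u32)] <- u32
    }
  } else {
    xs <- as.numeric(x)
    descr <- "<f8"
    dm <- dim(x)
    if (is.null(dm)) {
      shape <- sprintf("(%d,)", length(xs))
    } else {
      shape <- paste0("(", paste(dm, collapse = ", "), ")")
    }
    payload <- writeBin(xs, raw(), size = 8L, endian = "little")
  }
  header <- sprintf("{'descr': '%s', 'fortran_order': True, 'shape': %s, }",
                    descr, shape)
  # total header block (magic..newline) padded to a multiple of 64 bytes
  base_len <- 10L + nchar(header, type = "bytes") + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  hlen <- nchar(header, type = "bytes")
  c(as.raw(c(0x93)), charToRaw("NUMPY"), as.raw(c(1L, 0L)),
    writeBin(hlen, raw(), size = 2L, endian = "little"),
    charToRaw(header), payload)
}

npy_parse <- function(bytes) {
  if (length(bytes) < 10L || bytes[1] != as.raw(0x93) ||
      rawToChar(bytes[2:6]) != "NUMPY")
    stop("format error: not an NPY payload")
  hlen <- readBin(bytes[9:10], "integer", size = 2L, signed = FALSE,
                  endian = "little")
  header <- rawToChar(bytes[11:(10L + hlen)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s|,$", "", shape_str), ",")[[1]])
  if (length(shape) == 1L && is.na(shape[1])) shape <- integer(0)
  data <- bytes[(10L + hlen + 1L):length(bytes)]
  n <- if (length(shape)) prod(shape) else 1L
  if (grepl("^[<|=]?U", descr)) {
    width <- as.integer(sub("^[<|=]?U", "", descr))
    cp <- readBin(data, "integer", n = n * width, size = 4L, endian = "little")
    return(vapply(seq_len(n), function(i) {
      s <- cp[((i - 1L) * width + 1L):(i * width)]
      intToUtf8(s[s != 0L])
    }, character(1)))
  }
  x <- switch(sub("^[<|=]", "", descr),
    "f8" = readBin(data, "double", n = n, size = 8L, endian = "little"),
    "f4" = readBin(data, "double", n = n, size = 4L, endian = "little"),
    "i8" = readBin(data, "double", n = n, size = 8L, endian = "little"),
    "i4" = readBin(data, "integer", n = n, size = 4L, endian = "little"),
    stop("format error: unsupported NPY dtype ", descr)
  )
  if (length(shape) > 1L) {
    x <- if (fortran) array(x, dim = shape)
         else aperm(array(x, dim = rev(shape)), rev(seq_along(shape)))
  }
  x
}

# --- stored (method 0) ZIP container ----------------------------------------

# reinterpret an unsigned 32-bit quantity (held in a double) as signed int
u32_int <- function(x) as.integer(ifelse(x >= 2^31, x - 2^32, x))

zip_write_stored <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  names_raw <- lapply(names(entries), charToRaw)
  crcs <- numeric(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    crcs[i] <- crc32_raw(data)
    offsets[i] <- pos
    nm <- names_raw[[i]]
    writeBin(as.raw(c(0x50, 0x4b, 0x03, 0x04)), con)
    writeBin(c(20L, 0L, 0L, 0L, 0L), con, size = 2L, endian = "little")
    writeBin(c(u32_int(crcs[i]), length(data), length(data)), con, size = 4L,
             endian = "little")
    writeBin(c(length(nm), 0L), con, size = 2L, endian = "little")
    writeBin(nm, con)
    writeBin(data, con)
    pos <- pos + 30L + length(nm) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    nm <- names_raw[[i]]
    data <- entries[[i]]
    writeBin(as.raw(c(0x50, 0x4b, 0x01, 0x02)), con)
    writeBin(c(20L, 20L, 0L, 0L, 0L, 0L), con, size = 2L, endian = "little")
    writeBin(c(u32_int(crcs[i]), length(data), length(data)), con, size = 4L,
             endian = "little")
    writeBin(c(length(nm), 0L, 0L, 0L, 0L), con, size = 2L, endian = "little")
    writeBin(c(0L, as.integer(offsets[i])), con, size = 4L, endian = "little")
    writeBin(nm, con)
    pos <- pos + 46L + length(nm)
  }
  writeBin(as.raw(c(0x50, 0x4b, 0x05, 0x06)), con)
  writeBin(c(0L, 0L, length(entries), length(entries)), con, size = 2L,
           endian = "little")
  writeBin(as.integer(c(pos - cd_start, cd_start)), con, size = 4L,
           endian = "little")
  writeBin(c(0L), con, size = 2L, endian = "little")
  invisible(path)
}

zip_read_stored <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  entries <- list()
  pos <- 1L
  while (pos + 3L <= length(bytes) &&
         identical(bytes[pos:(pos + 3L)], as.raw(c(0x50, 0x4b, 0x03, 0x04)))) {
    method <- readBin(bytes[(pos + 8L):(pos + 9L)], "integer", size = 2L,
                      endian = "little")
    csize <- readBin(bytes[(pos + 18L):(pos + 21L)], "integer", size = 4L,
                     endian = "little")
    nlen <- readBin(bytes[(pos + 26L):(pos + 27L)], "integer", size = 2L,
                    endian = "little")
    elen <- readBin(bytes[(pos + 28L):(pos + 29L)], "integer", size = 2L,
                    endian = "little")
    name <- rawToChar(bytes[(pos + 30L):(pos + 29L + nlen)])
    if (csize == -1L && elen > 0L) {
      # zip64: sizes live in the 0x0001 extra record (8-byte LE each)
      extra <- bytes[(pos + 30L + nlen):(pos + 29L + nlen + elen)]
      ep <- 1L
      while (ep + 3L <= length(extra)) {
        id <- readBin(extra[ep:(ep + 1L)], "integer", size = 2L,
                      endian = "little")
        sz <- readBin(extra[(ep + 2L):(ep + 3L)], "integer", size = 2L,
                      endian = "little")
        if (id == 1L) {
          csize <- readBin(extra[(ep + 12L):(ep + 15L)], "integer",
                           size = 4L, endian = "little")
          break
        }
        ep <- ep + 4L + sz
      }
    }
    data_start <- pos + 30L + nlen + elen
    data <- bytes[data_start:(data_start + csize - 1L)]
    if (method == 8L) data <- memDecompress(data, type = "gzip")
    else if (method != 0L) stop("format error: unsupported ZIP method ", method)
    entries[[name]] <- data
    pos <- data_start + csize
  }
  entries
}

#' Write a ligand blob as an NPZ-style archive
#'
#' Serializes a blob to a `numpy.savez`-compatible archive with keys
#' `values` (3D float64 array), `origin`, `spacing` (length-3 float64),
#' `map_kind` and `source_id` (unicode scalars) — the layout of publicly
#' deposited ligand-blob archives.
#'
#' @param blob a `ligand_blob` or `density_grid`.
#' @param path output `.npz` path.
#' @return `path`, invisibly.
#' @export
write_blob_npz <- function(blob, path) {
  if (inherits(blob, "ligand_blob")) {
    grid <- blob$grid; source_id <- blob$source_id
  } else {
    stopifnot(is_density_grid(blob))
    grid <- blob; source_id <- ""
  }
  entries <- list(
    "values.npy" = npy_serialize(grid$values),
    "origin.npy" = npy_serialize(grid$origin),
    "spacing.npy" = npy_serialize(grid$spacing),
    "map_kind.npy" = npy_serialize(grid$map_kind),
    "source_id.npy" = npy_serialize(if (nzchar(source_id)) source_id else " ")
  )
  zip_write_stored(path, entries)
}

#' Read a ligand blob from an NPZ-style archive
#'
#' @param path path to an archive written by [write_blob_npz()] or
#'   `numpy.savez` with the same keys.
#' @return A `ligand_blob` (metadata absent).
#' @export
read_blob_npz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  entries <- zip_read_stored(path)
  need <- c("values.npy", "origin.npy", "spacing.npy", "map_kind.npy")
  if (!all(need %in% names(entries)))
    stop("format error: archive missing keys: ",
         paste(setdiff(need, names(entries)), collapse = ", "))
  values <- npy_parse(entries[["values.npy"]])
  if (length(dim(values)) != 3L) stop("format error: `values` is not 3D")
  grid <- density_grid(values,
                       origin = npy_parse(entries[["origin.npy"]]),
                       spacing = npy_parse(entries[["spacing.npy"]]),
                       map_kind = npy_parse(entries[["map_kind.npy"]]))
  sid <- if ("source_id.npy" %in% names(entries))
    trimws(npy_parse(entries[["source_id.npy"]])) else ""
  ligand_blob(grid, source_id = sid)
}

#' Read a blob metadata table
#'
#' Reads a CSV with one row per blob and columns
#' `resolution,rscc,rszo,rszd,r_factor,occupancy,q_score,volume,label,source_id`.
#'
#' @param path CSV path.
#' @return A data.frame with exactly those columns.
#' @export
read_blob_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("resolution", "rscc", "rszo", "rszd", "r_factor", "occupancy",
            "q_score", "volume", "label", "source_id")
  if (!all(need %in% names(df)))
    stop("metadata CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df[, need]
}
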