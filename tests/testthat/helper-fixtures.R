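# Shared fixture builders and independent oracles (pure R, no package
# internals) used across the suite.

# random sparse non-negative grid: background 0, `n_pos` positive voxels
random_sparse_grid <- function(dims = c(8L, 8L, 8L), n_pos = 30L,
                               seed = 1L, map_kind = "xray_diff",
                               spacing = 0.2, origin = c(0, 0, 0)) {
  set.seed(seed)
  v <- array(0, dim = dims)
  pick <- sample(prod(dims), n_pos)
  v[pick] <- runif(n_pos, 0.5, 5)
  density_grid(v, origin = origin, spacing = spacing, map_kind = map_kind)
}

# independent flood-fill labeling oracle, 26-connectivity, pure R BFS
oracle_label26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nxt <- 0L
  idx_all <- which(mask, arr.ind = TRUE)
  occ <- array(FALSE, dim = d)
  occ[idx_all] <- TRUE
  for (r in seq_len(nrow(idx_all))) {
    start <- idx_all[r, ]
    if (lab[start[1], start[2], start[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(start)
    lab[start[1], start[2], start[3]] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        p <- cur + c(di, dj, dk)
        if (any(p < 1L) || any(p > d)) next
        if (occ[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nxt
          queue[[length(queue) + 1L]] <- p
        }
      }
    }
  }
  lab
}

# brute-force per-meta-voxel argmax oracle for uniform sampling
oracle_block_argmax <- function(cloud, N) {
  org <- attr(cloud, "origin"); sp <- attr(cloud, "spacing")
  dm <- attr(cloud, "grid_dim")
  idx <- cbind(round((cloud$x - org[1]) / sp[1]),
               round((cloud$y - org[2]) / sp[2]),
               round((cloud$z - org[3]) / sp[3])) + 1
  meta <- ceiling(dm / N)
  bid <- paste(floor((idx[, 1] - 1) / meta[1]),
               floor((idx[, 2] - 1) / meta[2]),
               floor((idx[, 3] - 1) / meta[3]))
  lin <- (idx[, 1] - 1) + (idx[, 2] - 1) * dm[1] + (idx[, 3] - 1) * dm[1] * dm[2]
  keep <- unlist(lapply(split(seq_len(nrow(idx)), bid), function(rows) {
    best <- rows[cloud$density[rows] == max(cloud$density[rows])]
    best[which.min(lin[best])]
  }))
  sort(unname(keep))
}

# a small random labeled grouped dataset for split tests
random_split_fixture <- function(n_items = 200L, n_groups = 40L,
                                 n_classes = 5L, seed = 1L) {
  set.seed(seed)
  list(labels = sample(LETTERS[seq_len(n_classes)], n_items, replace = TRUE),
       groups = sample(sprintf("dep%02d", seq_len(n_groups)), n_items,
                       replace = TRUE))
}

expect_same_points <- function(a, b) {
  key <- function(p) paste(round(p$x, 9), round(p$y, 9), round(p$z, 9),
                           signif(p$density, 9))
  expect_setequal(key(a), key(b))
}
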