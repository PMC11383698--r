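test_that("density_grid validates its invariants", {
  expect_error(density_grid(array(1, c(2, 2, 2)), spacing = c(0.2, 0, 0.2)),
               "positive")
  expect_error(density_grid(matrix(1, 2, 2)), "3D")
  g <- density_grid(array(1:8, c(2, 2, 2)), origin = c(1, 2, 3),
                    spacing = 0.5)
  expect_equal(voxel_centers(g, cbind(1, 1, 1))[1, ], c(1, 2, 3))
  expect_equal(voxel_centers(g, cbind(2, 2, 2))[1, ], c(1.5, 2.5, 3.5))
})

test_that("MRC files round-trip values, origin and spacing", {
  set.seed(11)
  # values on a float32-representable lattice so the round trip is exact
  v <- array(round(rnorm(2 * 2 * 2), 3), c(2, 2, 2))
  g <- density_grid(v, origin = c(1.5, -2.25, 0.5), spacing = c(0.25, 0.5, 1))
  f <- tempfile(fileext = ".mrc")
  write_map(g, f)
  r1 <- read_map(f)
  expect_equal(dim(r1$values), c(2L, 2L, 2L))
  expect_equal(r1$values, v, tolerance = 1e-7)
  expect_equal(r1$origin, g$origin)
  expect_equal(r1$spacing, g$spacing)
  # write-read a second time: exact identity once values are float32
  f2 <- tempfile(fileext = ".mrc")
  write_map(r1, f2)
  r2 <- read_map(f2)
  expect_identical(r2$values, r1$values)
  expect_identical(r2$origin, r1$origin)
  expect_identical(r2$spacing, r1$spacing)
})

test_that("non-mode-2 maps are rejected naming the header field", {
  g <- density_grid(array(1:8 / 8, c(2, 2, 2)))
  f <- tempfile(fileext = ".mrc")
  write_map(g, f)
  raw <- readBin(f, "raw", file.size(f))
  raw[13:16] <- writeBin(1L, raw(), size = 4L, endian = "little")  # MODE = 1
  writeBin(raw, f)
  expect_error(read_map(f), "MODE")
})

test_that("permuted MAPC/MAPR/MAPS headers give the same world grid", {
  set.seed(7)
  dims <- c(3L, 4L, 5L)
  v <- array(round(runif(prod(dims)), 3), dims)
  spacing <- c(0.2, 0.3, 0.4)
  maporder <- c(2L, 3L, 1L)   # cols = y, rows = z, sections = x
  # write a permuted-axis MRC by hand
  d <- aperm(v, maporder)
  f <- tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  writeBin(as.integer(dim(d)), con, size = 4L, endian = "little")  # NX NY NZ
  writeBin(2L, con, size = 4L, endian = "little")                  # MODE
  writeBin(c(0L, 0L, 0L), con, size = 4L, endian = "little")       # NSTART
  writeBin(as.integer(dims), con, size = 4L, endian = "little")    # MX MY MZ
  writeBin(dims * spacing, con, size = 4L, endian = "little")      # CELLA
  writeBin(c(90, 90, 90), con, size = 4L, endian = "little")       # CELLB
  writeBin(maporder, con, size = 4L, endian = "little")            # MAPC/R/S
  for (w in 20:49) writeBin(0L, con, size = 4L, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4L, endian = "little")          # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)
  writeBin(0, con, size = 4L, endian = "little")                   # RMS
  writeBin(0L, con, size = 4L, endian = "little")                  # NLABL
  writeBin(raw(800), con)
  writeBin(as.numeric(d), con, size = 4L, endian = "little")
  close(con)
  g <- read_map(f)
  # brute-force remapping oracle: place every stored element at its crystal
  # index one by one
  oracle <- array(NA_real_, dims)
  dd <- dim(d)
  for (c_ in 1:dd[1]) for (r_ in 1:dd[2]) for (s_ in 1:dd[3]) {
    ix <- integer(3)
    ix[maporder[1]] <- c_; ix[maporder[2]] <- r_; ix[maporder[3]] <- s_
    oracle[ix[1], ix[2], ix[3]] <- d[c_, r_, s_]
  }
  expect_equal(g$values, oracle, tolerance = 1e-7)
  expect_equal(g$spacing, spacing, tolerance = 1e-6)
})

test_that("sigma thresholding keeps the expected normal tail fraction", {
  set.seed(42)
  g <- density_grid(array(rnorm(1e6), c(100, 100, 100)))
  thr <- threshold_xray(g, n_sigma = 2.8)
  frac <- mean(thr$values > 0)
  expect_lt(abs(frac - (1 - pnorm(2.8))), 3.5e-4)
})

test_that("sigma thresholding matches a brute-force voxel scan", {
  set.seed(5)
  v <- array(rnorm(27), c(3, 3, 3))
  g <- density_grid(v)
  thr <- threshold_xray(g, n_sigma = 0.5)
  mu <- mean(v); sdev <- sqrt(mean((v - mu)^2))
  keep <- array(FALSE, dim(v))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    keep[i, j, k] <- v[i, j, k] >= mu + 0.5 * sdev
  expect_identical(thr$values > 0, keep)
  expect_equal(thr$values[keep], v[keep])
})

test_that("sigma thresholding degenerate and no-op bounds behave", {
  expect_error(threshold_xray(density_grid(array(1, c(2, 2, 2)))),
               "degenerate")
  g <- random_sparse_grid(seed = 3)
  expect_equal(threshold_xray(g, n_sigma = -1e9)$values, g$values)
  expect_error(threshold_xray(density_grid(array(rnorm(8), c(2, 2, 2)),
                                           map_kind = "cryoem")),
               "xray_diff")
})

test_that("thresholding is idempotent under frozen statistics", {
  g <- random_sparse_grid(dims = c(6, 6, 6), n_pos = 40, seed = 9)
  mu <- mean(g$values); sdev <- sqrt(mean((g$values - mu)^2))
  thr_level <- mu + 1.0 * sdev
  t1 <- g; t1$values[t1$values < thr_level] <- 0
  t2 <- t1; t2$values[t2$values < thr_level] <- 0
  expect_identical(t2$values, t1$values)
})

test_that("resampling is the identity at the target spacing", {
  g <- random_sparse_grid(dims = c(5, 5, 5), seed = 2, spacing = 0.2)
  r <- resample_grid(g, 0.2)
  expect_equal(dim(r$values), dim(g$values))
  expect_equal(r$values, g$values, tolerance = 1e-9)
})

test_that("resampling a constant grid stays constant", {
  g <- density_grid(array(3.5, c(4, 3, 5)), spacing = c(0.7, 0.9, 0.4))
  r <- resample_grid(g, 0.2)
  expect_equal(r$spacing, rep(0.2, 3))
  expect_true(all(abs(r$values - 3.5) < 1e-12))
})

test_that("resampling a linear ramp is exact at machine precision", {
  # f(x, y, z) = x on a 0.4 A grid; trilinear interpolation of a linear
  # field reproduces it exactly at the new 0.2 A centers
  n <- c(6L, 4L, 4L)
  xs <- (seq_len(n[1]) - 1) * 0.4
  v <- array(rep(xs, times = prod(n[2:3])), dim = n)
  g <- density_grid(v, spacing = 0.4)
  r <- resample_grid(g, 0.2)
  expected_x <- (seq_len(dim(r$values)[1]) - 1) * 0.2
  for (k in seq_len(dim(r$values)[3]))
    for (j in seq_len(dim(r$values)[2]))
      expect_equal(r$values[, j, k], expected_x, tolerance = 1e-12)
  expect_error(resample_grid(g, -0.1), "target_spacing")
})

test_that("point clouds enumerate exactly the positive voxels", {
  v <- array(0, c(2, 2, 2)); v[1, 1, 1] <- 4.5
  g <- density_grid(v, origin = c(1, 1, 1), spacing = 0.2)
  pc <- grid_to_pointcloud(g)
  expect_equal(nrow(pc), 1L)
  expect_equal(unlist(pc[1, ]), c(x = 1, y = 1, z = 1, density = 4.5))

  for (seed in 1:5) {
    g <- random_sparse_grid(dims = c(7, 6, 5), n_pos = 25, seed = seed)
    pc <- grid_to_pointcloud(g)
    expect_equal(nrow(pc), sum(g$values > 0))
    # exhaustive scan oracle
    pos <- which(g$values > 0, arr.ind = TRUE)
    oracle <- data.frame(
      x = g$origin[1] + (pos[, 1] - 1) * g$spacing[1],
      y = g$origin[2] + (pos[, 2] - 1) * g$spacing[2],
      z = g$origin[3] + (pos[, 3] - 1) * g$spacing[3],
      density = g$values[pos])
    expect_same_points(pc, oracle)
  }
  expect_error(grid_to_pointcloud(density_grid(array(0, c(2, 2, 2)))),
               "empty")
})

test_that("re-voxelizing a cloud reproduces the positive voxels exactly", {
  g <- random_sparse_grid(dims = c(6, 7, 8), n_pos = 40, seed = 12,
                          origin = c(-1, 2, 0.4))
  pc <- grid_to_pointcloud(g)
  back <- pointcloud_to_grid(pc)
  expect_identical(back$values, g$values)
  expect_identical(back$origin, g$origin)
})
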