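test_that("the partition worked example divides (20,16,10) by N=2 into 8 blocks", {
  occ <- which(array(TRUE, c(20, 16, 10)), arr.ind = TRUE)
  plan <- partition_for_divisor(c(20L, 16L, 10L), occ, 2L)
  expect_equal(plan$n_blocks, 8)
  expect_equal(plan$meta_shape, c(10L, 8L, 5L))
  expect_equal(plan$padded_shape, c(20L, 16L, 10L))
  expect_equal(plan$nonempty, 8L)
})

test_that("non-divisible dimensions are zero-padded per axis", {
  occ <- cbind(1L, 1L, 1L)
  plan <- partition_for_divisor(c(5L, 4L, 3L), occ, 2L)
  expect_equal(plan$meta_shape, c(3L, 2L, 2L))
  expect_equal(plan$padded_shape, c(6L, 4L, 4L))
  expect_equal(plan$nonempty, 1L)
})

test_that("a single occupied voxel keeps nonempty = 1 for every divisor", {
  for (N in 1:6) {
    plan <- partition_for_divisor(c(9L, 9L, 9L), cbind(4L, 5L, 6L), N)
    expect_equal(plan$nonempty, 1L)
  }
  plan <- plan_uniform_partition(c(9L, 9L, 9L), cbind(4L, 5L, 6L), max_p = 10)
  expect_lte(plan$nonempty, 10L)
})

test_that("the divisor search matches a brute-force sweep", {
  for (seed in 1:8) {
    set.seed(seed)
    dims <- sample(6:20, 3, replace = TRUE)
    n_occ <- sample(20:80, 1)
    occ <- unique(cbind(sample(dims[1], n_occ, TRUE),
                        sample(dims[2], n_occ, TRUE),
                        sample(dims[3], n_occ, TRUE)))
    max_p <- 50L
    plan <- plan_uniform_partition(dims, occ, max_p)
    # oracle: nonempty counts for every N, pick the largest N reachable by
    # unit increments whose count stays within max_p
    counts <- vapply(1:max(dims), function(N)
      partition_for_divisor(dims, occ, N)$nonempty, integer(1))
    n_best <- 1L
    while (n_best < max(dims) && counts[n_best + 1L] <= max_p)
      n_best <- n_best + 1L
    expect_equal(plan$N, n_best)
    expect_lte(plan$nonempty, max_p)
    # per-N padding makes the count non-monotone in N in general, so the
    # search walks N upward one step at a time; sanity-bound the counts
    expect_true(all(counts <= pmin((1:max(dims))^3, nrow(occ))))
  }
})

make_cloud <- function(dims, n_pos, seed, distinct = FALSE) {
  g <- random_sparse_grid(dims = dims, n_pos = n_pos, seed = seed)
  if (distinct) {
    pos <- g$values > 0
    set.seed(seed + 999)
    g$values[pos] <- sample(seq_len(sum(pos))) + runif(sum(pos), 0, 0.4)
  }
  grid_to_pointcloud(g)
}

test_that("uniform-max keeps the maximum-density point per meta-voxel", {
  # two points in one meta-voxel: the density-5 one survives
  v <- array(0, c(4, 4, 4))
  v[1, 1, 1] <- 3; v[2, 2, 2] <- 5
  pc <- grid_to_pointcloud(density_grid(v))
  out <- sample_uniform_max(pc, sampling_config(max_p = 1))
  expect_equal(nrow(out), 1L)
  expect_equal(out$density, 5)

  # all points in distinct meta-voxels: identity
  pc <- make_cloud(c(6, 6, 6), 20, seed = 3)
  out <- sample_uniform_max(pc, sampling_config(max_p = 2000))
  expect_same_points(out, pc)
})

test_that("uniform-max equals the brute-force block-argmax oracle", {
  for (seed in 1:10) {
    pc <- make_cloud(c(10, 9, 8), 60, seed = seed, distinct = TRUE)
    cfg <- sampling_config(max_p = 20)
    out <- sample_uniform_max(pc, cfg)
    plan <- plan_uniform_partition(attr(pc, "grid_dim"),
                                   densiligand:::cloud_voxel_indices(pc),
                                   cfg$max_p)
    oracle_rows <- oracle_block_argmax(pc, plan$N)
    expect_same_points(out, pc[oracle_rows, ])
    expect_lte(nrow(out), cfg$max_p)
  }
})

test_that("random sampling is a seeded subset of the requested size", {
  pc <- make_cloud(c(8, 8, 8), 50, seed = 5)
  cfg <- sampling_config(strategy = "random", max_p = 100, seed = 3)
  expect_same_points(sample_random(pc, cfg), pc)  # undersized input

  cfg <- sampling_config(strategy = "random", max_p = 12, seed = 3)
  a <- sample_random(pc, cfg)
  b <- sample_random(pc, cfg)
  expect_equal(nrow(a), 12L)
  expect_identical(a, b)
  key <- function(p) paste(p$x, p$y, p$z)
  expect_true(all(key(a) %in% key(pc)))
})

test_that("single-point draws are uniform over the cloud", {
  v <- array(0, c(4, 1, 1)); v[] <- c(1, 2, 3, 4)
  pc <- grid_to_pointcloud(density_grid(v))
  draws <- vapply(1:10000, function(s) {
    sample_random(pc, sampling_config(strategy = "random", max_p = 1,
                                      seed = s))$density
  }, numeric(1))
  counts <- table(factor(draws, levels = 1:4))
  chi2 <- sum((counts - 2500)^2 / 2500)
  expect_lt(chi2, qchisq(0.999, df = 3))
})

test_that("surface sampling returns the 6-neighborhood shell", {
  # an isolated voxel is its own shell
  v <- array(0, c(3, 3, 3)); v[2, 2, 2] <- 1
  pc <- grid_to_pointcloud(density_grid(v))
  out <- sample_surface(pc, sampling_config(strategy = "surface"))
  expect_equal(nrow(out), 1L)

  # solid 3x3x3 cube: everything but the center is on the shell
  v <- array(1, c(3, 3, 3))
  pc <- grid_to_pointcloud(density_grid(v, origin = c(0, 0, 0)))
  out <- sample_surface(pc, sampling_config(strategy = "surface",
                                            max_p = 2000))
  expect_equal(nrow(out), 26L)
  expect_false(any(out$x == 0.2 & out$y == 0.2 & out$z == 0.2))

  # max_p below the shell size: seeded subset of the shell
  out5 <- sample_surface(pc, sampling_config(strategy = "surface",
                                             max_p = 5, seed = 2))
  expect_equal(nrow(out5), 5L)
  key <- function(p) paste(p$x, p$y, p$z)
  expect_true(all(key(out5) %in% key(out)))
})

test_that("cluster sampling returns seeded k-means centroids", {
  pc <- make_cloud(c(6, 6, 6), 30, seed = 9)
  # k = n: the points themselves
  out <- sample_cluster(pc, sampling_config(strategy = "clustering",
                                            max_p = 2000))
  expect_same_points(out, pc)

  # two tight, well-separated clusters with k = 2: centroids = the means
  v <- array(0, c(30, 2, 2))
  v[1:2, 1, 1] <- c(1, 1.5); v[29:30, 2, 2] <- c(2, 2.5)
  pc2 <- grid_to_pointcloud(density_grid(v))
  out2 <- sample_cluster(pc2, sampling_config(strategy = "clustering",
                                              max_p = 2, seed = 4))
  got <- out2[order(out2$x), ]
  expect_equal(got$x, c(mean(pc2$x[1:2]), mean(pc2$x[3:4])))
  expect_equal(got$density, c(mean(c(1, 1.5)), mean(c(2, 2.5))))

  cfgc <- sampling_config(strategy = "clustering", max_p = 7, seed = 11)
  expect_identical(sample_cluster(pc, cfgc), sample_cluster(pc, cfgc))
})

test_that("every strategy respects the point budget and subset contracts", {
  for (strategy in c("uniform", "random", "surface", "clustering")) {
    pc <- make_cloud(c(9, 9, 9), 70, seed = 13, distinct = TRUE)
    cfg <- sampling_config(strategy = strategy, max_p = 25, seed = 6)
    out <- sample_points(pc, cfg)
    expect_lte(nrow(out), 25L)
    expect_identical(sample_points(pc, cfg), out)
    if (strategy != "clustering") {
      key <- function(p) paste(p$x, p$y, p$z, p$density)
      expect_true(all(key(out) %in% key(pc)))
    }
  }
})

# rotate a cubic grid by 90 degrees about the z axis (voxel lattice map:
# (i, j, k) -> (j, n+1-i, k), 1-based)
rotate_grid_z <- function(g) {
  n <- dim(g$values)[1]
  v <- array(0, dim(g$values))
  for (i in seq_len(n)) for (j in seq_len(n))
    v[j, n + 1 - i, ] <- g$values[i, j, ]
  density_grid(v, origin = g$origin, spacing = g$spacing,
               map_kind = g$map_kind)
}

test_that("uniform sampling is equivariant under lattice rotations", {
  g <- random_sparse_grid(dims = c(12, 12, 12), n_pos = 200, seed = 19)
  pos <- g$values > 0
  set.seed(20)
  g$values[pos] <- sample(seq_len(sum(pos))) + 0.1   # tie-free densities
  gr <- rotate_grid_z(g)
  cfg <- sampling_config(max_p = 27)
  out <- sample_uniform_max(grid_to_pointcloud(g), cfg)
  out_r <- sample_uniform_max(grid_to_pointcloud(gr), cfg)
  # map the original sample through the rotation and compare as sets
  n <- 12
  i <- round(out$x / 0.2) + 1; j <- round(out$y / 0.2) + 1
  k <- round(out$z / 0.2) + 1
  mapped <- data.frame(x = (j - 1) * 0.2, y = (n + 1 - i - 1) * 0.2,
                       z = (k - 1) * 0.2, density = out$density)
  expect_same_points(out_r, mapped)
})
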