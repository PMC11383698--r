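tiny_cfg <- function(num_classes = 3L, seed = 7L) {
  model_config(num_classes = num_classes, channels = c(4L, 6L, 8L),
               descriptor_channels = 6L, vlad_clusters = 4L, hidden = 8L,
               seed = seed)
}

random_cloud <- function(n = 40L, seed = 1L, scale = 2) {
  set.seed(seed)
  cl <- data.frame(x = runif(n, 0, scale), y = runif(n, 0, scale),
                   z = runif(n, 0, scale), density = runif(n, 0.5, 2))
  class(cl) <- c("point_cloud", "data.frame")
  cl
}

tiny_model <- function(cloud_labels = c("a", "b", "c"), seed = 7L) {
  cfg <- tiny_cfg(num_classes = length(cloud_labels), seed = seed)
  list(weights = densiligand:::init_weights(cfg), cfg = cfg,
       labels = cloud_labels)
}

test_that("quantization floors, merges by max density and canonicalizes", {
  cfg <- tiny_cfg()
  # lattice-aligned points: one cell each, features preserved
  cl <- data.frame(x = c(0, 0.2, 0.4), y = 0, z = 0, density = c(1, 2, 3))
  class(cl) <- c("point_cloud", "data.frame")
  sp <- quantize(cl, cfg)
  expect_equal(nrow(sp$coords), 3L)
  expect_equal(sort(sp$feats[, 1]), c(1, 2, 3))

  # two points in one cell: max density wins
  cl2 <- data.frame(x = c(0.01, 0.05), y = 0, z = 0, density = c(1, 2))
  class(cl2) <- c("point_cloud", "data.frame")
  sp2 <- quantize(cl2, cfg)
  expect_equal(nrow(sp2$coords), 1L)
  expect_equal(sp2$feats[1, 1], 2)

  # brute-force floor-division oracle on a random cloud
  cl3 <- random_cloud(60, seed = 5)
  sp3 <- quantize(cl3, cfg)
  cells <- unique(cbind(floor(cl3$x / cfg$cell), floor(cl3$y / cfg$cell),
                        floor(cl3$z / cfg$cell)))
  cells <- sweep(cells, 2, apply(cells, 2, min))
  expect_equal(nrow(sp3$coords), nrow(cells))
  expect_setequal(paste(sp3$coords[, 1], sp3$coords[, 2], sp3$coords[, 3]),
                  paste(cells[, 1], cells[, 2], cells[, 3]))
})

test_that("forward output is a probability simplex with consistent ranking", {
  m <- tiny_model()
  pred <- forward(quantize(random_cloud(50, seed = 2), m$cfg), m)
  expect_equal(sum(pred$probabilities), 1, tolerance = 1e-6)
  expect_true(all(pred$probabilities >= 0))
  expect_equal(sort(pred$ranking), sort(m$labels))
  expect_equal(pred$ranking[1], names(which.max(pred$probabilities)))
  expect_error(forward(list(coords = matrix(integer(0), 0, 3)), m), "empty")
})

test_that("forward is invariant to point order and whole-cell translation", {
  m <- tiny_model()
  cl <- random_cloud(45, seed = 9)
  p0 <- forward(quantize(cl, m$cfg), m)
  set.seed(1)
  cl_perm <- cl[sample(nrow(cl)), ]
  class(cl_perm) <- c("point_cloud", "data.frame")
  expect_identical(forward(quantize(cl_perm, m$cfg), m)$probabilities,
                   p0$probabilities)
  cl_shift <- cl
  cl_shift$x <- cl$x + 7 * m$cfg$cell
  cl_shift$y <- cl$y - 13 * m$cfg$cell
  cl_shift$z <- cl$z + 1 * m$cfg$cell
  expect_identical(forward(quantize(cl_shift, m$cfg), m)$probabilities,
                   p0$probabilities)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_cfg(seed = 11)
  sp <- quantize(random_cloud(35, seed = 3), cfg)
  pp <- densiligand:::preprocess_sparse(sp)
  w <- densiligand:::init_weights(cfg)
  lossfun <- function(w) {
    fw <- densiligand:::net_forward(pp, w, cfg)
    -log(fw$probs[2])
  }
  fw <- densiligand:::net_forward(pp, w, cfg, keep_cache = TRUE)
  g <- densiligand:::net_backward(pp, w, cfg, fw, 2L)
  set.seed(12)
  for (nm in names(g)) {
    idx <- sample(length(w[[nm]]), min(3, length(w[[nm]])))
    for (i in idx) {
      eps <- 1e-6
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (lossfun(wp) - lossfun(wm)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]),
                1e-4 + 1e-3 * (abs(num) + abs(g[[nm]][i])))
    }
  }
})

test_that("the untrained loss of a balanced problem is about ln(C)", {
  for (C in c(3L, 7L)) {
    m <- tiny_model(sprintf("c%d", seq_len(C)), seed = 5)
    losses <- vapply(1:6, function(s) {
      p <- forward(quantize(random_cloud(40, seed = s), m$cfg), m)
      -log(p$probabilities[sample(C, 1)])
    }, numeric(1))
    expect_equal(mean(losses), log(C), tolerance = 0.05)
  }
})

test_that("a tiny training set is memorized to accuracy 1", {
  ds <- make_classification_dataset(n_classes = 2L, n_per_class = 6L,
                                    seed = 77, max_p = 256L)
  m <- train_model(ds$clouds, ds$labels,
                   cfg = model_config(num_classes = 2L,
                                      channels = c(8L, 12L, 16L),
                                      descriptor_channels = 12L,
                                      vlad_clusters = 4L, hidden = 16L,
                                      seed = 3L),
                   schedule = training_schedule(epochs = 25L, lr = 3e-3,
                                                grad_accum = 4L))
  expect_equal(m$log$accuracy[nrow(m$log)], 1.0)
  expect_true(all(diff(tapply(m$log$loss, (m$log$epoch - 1) %/% 5, mean)) < 0))
  # same seed: bit-reproducible log
  m2 <- train_model(ds$clouds, ds$labels,
                    cfg = model_config(num_classes = 2L,
                                       channels = c(8L, 12L, 16L),
                                       descriptor_channels = 12L,
                                       vlad_clusters = 4L, hidden = 16L,
                                       seed = 3L),
                    schedule = training_schedule(epochs = 25L, lr = 3e-3,
                                                 grad_accum = 4L))
  expect_identical(m$log, m2$log)
  expect_error(train_model(ds$clouds, rep("a", length(ds$clouds))),
               "two classes")
})

test_that("top-k prediction lists follow the ranking", {
  m <- tiny_model()
  pred <- forward(quantize(random_cloud(30, seed = 4), m$cfg), m)
  expect_equal(predict_topk(pred, 1), pred$ranking[1])
  expect_equal(predict_topk(pred, 3), pred$ranking)
  expect_setequal(predict_topk(pred, 3), m$labels)
  expect_error(predict_topk(pred, 0), "between")
  expect_error(predict_topk(pred, 4), "between")
})

test_that("checkpoints round-trip and refuse mismatched catalogs", {
  ds <- make_classification_dataset(n_classes = 2L, n_per_class = 3L,
                                    seed = 5, max_p = 128L)
  m <- train_model(ds$clouds, ds$labels,
                   cfg = model_config(num_classes = 2L,
                                      channels = c(4L, 6L, 8L),
                                      descriptor_channels = 6L,
                                      vlad_clusters = 3L, hidden = 8L,
                                      seed = 2L),
                   schedule = training_schedule(epochs = 2L))
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  cl <- ds$clouds[[1]]
  expect_identical(predict_cloud(m2, cl)$probabilities,
                   predict_cloud(m, cl)$probabilities)
  expect_error(load_checkpoint(f, catalog = c("x", "y")), "disagrees")
  expect_silent(load_checkpoint(f, catalog = m$labels))
})
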