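#' Sparse-convolution classifier configuration
#'
#' Hyperparameters of the ligand classifier: a U-Net-like sparse 3D
#' convolutional network with a three-block bottom-up pathway of increasing
#' receptive field, Efficient Channel Attention (ECA) in each block, a
#' top-down transposed-convolution pathway that adds deep features back at
#' the mid-level resolution, NetVLAD aggregation of the fused per-point
#' features into a global descriptor, and a two-layer softmax head over the
#' ligand-group catalog.
#'
#' @param num_classes size of the output head (>= 2; 219 for the full
#'   ligand-group catalog).
#' @param in_channels input feature width (1: the point density).
#' @param cell quantization cell edge in Angstrom (default the canonical
#'   0.2 grid).
#' @param channels integer 3-vector of per-block channel widths
#'   (default `c(32, 64, 128)`).
#' @param descriptor_channels channel width of the fused top-down features
#'   fed to NetVLAD (default `channels[2]`).
#' @param vlad_clusters NetVLAD cluster count (default 16).
#' @param hidden width of the first fully connected layer (default 64).
#' @param seed integer seed for weight initialization and epoch shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(num_classes = 219L, in_channels = 1L,
                         cell = CANONICAL_SPACING,
                         channels = c(32L, 64L, 128L),
                         descriptor_channels = channels[2],
                         vlad_clusters = 16L, hidden = 64L, seed = 1L) {
  if (num_classes < 2L) stop("`num_classes` must be >= 2")
  if (cell <= 0) stop("`cell` must be > 0")
  if (length(channels) != 3L || any(channels < 1L))
    stop("`channels` must be three positive widths")
  structure(list(num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels), cell = cell,
                 channels = as.integer(channels),
                 descriptor_channels = as.integer(descriptor_channels),
                 vlad_clusters = as.integer(vlad_clusters),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "model_config")
}

#' Quantize a point cloud to a sparse occupancy structure
#'
#' Maps each point to the integer cell `floor(coordinate / cell)`, merges
#' duplicate cells by keeping the maximum density, shifts coordinates so
#' the minimum cell is at the origin (which makes the network exactly
#' invariant to translations by whole cells), and sorts cells into a
#' canonical order (which makes it exactly invariant to input point order).
#'
#' @param cloud a `point_cloud`.
#' @param cfg a [model_config()].
#' @return List with `coords` (n x 3 integer matrix, min 0 per axis) and
#'   `feats` (n x in_channels numeric matrix of densities).
#' @export
quantize <- function(cloud, cfg = model_config()) {
  if (nrow(cloud) == 0L) stop("cannot quantize an empty cloud")
  co <- cbind(floor(cloud$x / cfg$cell), floor(cloud$y / cfg$cell),
              floor(cloud$z / cfg$cell))
  key <- coord_key(co)
  ord <- order(key, -cloud$density)
  keep <- ord[!duplicated(key[ord])]
  keep <- keep[order(key[keep])]
  co <- co[keep, , drop = FALSE]
  co <- sweep(co, 2L, apply(co, 2L, min))
  storage.mode(co) <- "integer"
  list(coords = co, feats = matrix(cloud$density[keep], ncol = 1L))
}

# collision-free scalar key for small non-negative integer coordinates
coord_key <- function(co) {
  co[, 1] + 4096 * (co[, 2] + 4096 * co[, 3])
}

# kernel offset tables
offsets_k3 <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
offsets_k2 <- as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))

# neighbor maps of a stride-1 kernel-3 conv on one coordinate set
build_maps_s1 <- function(coords) {
  key <- coord_key(coords)
  lapply(seq_len(nrow(offsets_k3)), function(o) {
    nb <- sweep(coords, 2L, offsets_k3[o, ], "+")
    inn <- match(coord_key(nb), key)
    ok <- !is.na(inn)
    list(inn = inn[ok], out = which(ok))
  })
}

# stride-2 kernel-2 downsampling: output coords and per-offset maps
build_maps_down <- function(coords) {
  parent <- coords %/% 2L
  pkey <- coord_key(parent)
  out_key <- sort(unique(pkey))
  out_coords <- cbind(out_key %% 4096, (out_key %/% 4096) %% 4096,
                      out_key %/% 4096^2)
  storage.mode(out_coords) <- "integer"
  key_in <- coord_key(coords)
  maps <- lapply(seq_len(nrow(offsets_k2)), function(o) {
    probe <- sweep(out_coords * 2L, 2L, offsets_k2[o, ], "+")
    inn <- match(coord_key(probe), key_in)
    ok <- !is.na(inn)
    list(inn = inn[ok], out = which(ok))
  })
  list(coords = out_coords, maps = maps)
}

# transposed stride-2 kernel-2 conv maps: coarse -> fine coordinate pairs
build_maps_up <- function(fine_coords, coarse_coords) {
  parent <- fine_coords %/% 2L
  off <- fine_coords - 2L * parent
  o_id <- off[, 1] + 2L * off[, 2] + 4L * off[, 3] + 1L
  src <- match(coord_key(parent), coord_key(coarse_coords))
  lapply(seq_len(8L), function(o) {
    sel <- which(o_id == o)
    list(inn = src[sel], out = sel)
  })
}

conv_forward <- function(feats, W, b, maps, n_out) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  out <- matrix(rep(b, each = n_out), n_out, cout)
  for (o in seq_along(maps)) {
    m <- maps[[o]]
    if (length(m$inn) == 0L) next
    Wo <- matrix(W[o, , ], cin, cout)
    out[m$out, ] <- out[m$out, , drop = FALSE] +
      feats[m$inn, , drop = FALSE] %*% Wo
  }
  out
}

conv_backward <- function(dout, feats, W, maps, n_in) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  dW <- array(0, dim = dim(W))
  dfeats <- matrix(0, n_in, cin)
  for (o in seq_along(maps)) {
    m <- maps[[o]]
    if (length(m$inn) == 0L) next
    Wo <- matrix(W[o, , ], cin, cout)
    dO <- dout[m$out, , drop = FALSE]
    dW[o, , ] <- crossprod(feats[m$inn, , drop = FALSE], dO)
    dfeats[m$inn, ] <- dfeats[m$inn, , drop = FALSE] + tcrossprod(dO, Wo)
  }
  list(dW = dW, db = colSums(dout), dfeats = dfeats)
}

# Efficient Channel Attention: gate channels by a sigmoid of a 1D conv over
# the channel-mean descriptor (shared kernel, no channel reduction)
eca_forward <- function(x, k) {
  s <- colMeans(x)
  z <- conv1d(s, k)
  g <- 1 / (1 + exp(-z))
  list(y = x * rep(g, each = nrow(x)), s = s, g = g)
}

eca_backward <- function(dy, x, k, cache) {
  g <- cache$g; s <- cache$s
  n <- nrow(x)
  dg <- colSums(dy * x)
  dz <- dg * g * (1 - g)
  dk <- conv1d_grad_k(s, dz, length(k))
  ds <- conv1d_transpose(dz, k)
  dx <- dy * rep(g, each = n) + matrix(ds / n, n, length(s), byrow = TRUE)
  list(dx = dx, dk = dk)
}

conv1d <- function(s, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(s)
  z <- numeric(n)
  for (j in seq_along(k)) {
    shift <- j - 1L - half
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    z[ok] <- z[ok] + k[j] * s[src[ok]]
  }
  z
}

conv1d_transpose <- function(dz, k) {
  half <- (length(k) - 1L) %/% 2L
  n <- length(dz)
  ds <- numeric(n)
  for (j in seq_along(k)) {
    shift <- j - 1L - half
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    ds[src[ok]] <- ds[src[ok]] + k[j] * dz[ok]
  }
  ds
}

conv1d_grad_k <- function(s, dz, klen) {
  half <- (klen - 1L) %/% 2L
  n <- length(s)
  vapply(seq_len(klen), function(j) {
    shift <- j - 1L - half
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    sum(dz[ok] * s[src[ok]])
  }, numeric(1))
}

l2_normalize <- function(v) {
  s <- sqrt(sum(v^2) + 1e-10)
  list(y = v / s, s = s)
}

l2_normalize_backward <- function(dy, v, s) {
  dy / s - v * (sum(v * dy) / s^3)
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

netvlad_forward <- function(f, A, b, C) {
  logits <- sweep(f %*% A, 2L, b, "+")
  asn <- softmax_rows(logits)
  V <- crossprod(asn, f) - colSums(asn) * C
  rn <- sqrt(rowSums(V^2) + 1e-10)
  Vn <- V / rn
  v <- as.vector(t(Vn))
  gl <- l2_normalize(v)
  list(desc = gl$y, asn = asn, V = V, rn = rn, Vn = Vn, v = v, gs = gl$s)
}

netvlad_backward <- function(ddesc, f, A, b, C, cache) {
  K <- nrow(C)
  dv <- l2_normalize_backward(ddesc, cache$v, cache$gs)
  dVn <- matrix(dv, K, ncol(C), byrow = TRUE)
  V <- cache$V; rn <- cache$rn
  dV <- dVn / rn - V * (rowSums(V * dVn) / rn^3)
  asn <- cache$asn
  df <- asn %*% dV
  dC <- -colSums(asn) * dV
  dasn <- f %*% t(dV) -
    matrix(rowSums(dV * C), nrow(f), K, byrow = TRUE)
  dlog <- asn * (dasn - rowSums(dasn * asn))
  list(df = df + dlog %*% t(A),
       dA = crossprod(f, dlog), db = colSums(dlog), dC = dC)
}

# --- network assembly -------------------------------------------------------

init_weights <- function(cfg) {
  c1 <- cfg$channels[1]; c2 <- cfg$channels[2]; c3 <- cfg$channels[3]
  cd <- cfg$descriptor_channels; K <- cfg$vlad_clusters
  D <- K * cd; h <- cfg$hidden; nc <- cfg$num_classes
  gauss <- function(...) {
    d <- c(...)
    array(rnorm(prod(d), sd = sqrt(2 / (prod(d[-length(d)]) + 1))), dim = d)
  }
  local_seed(cfg$seed, list(
    W_in = gauss(27, cfg$in_channels, c1), b_in = numeric(c1),
    k_eca1 = c(0, 1, 0),
    W_d1 = gauss(8, c1, c2), b_d1 = numeric(c2),
    W_c1 = gauss(27, c2, c2), b_c1 = numeric(c2),
    k_eca2 = c(0, 1, 0),
    W_d2 = gauss(8, c2, c3), b_d2 = numeric(c3),
    W_c2 = gauss(27, c3, c3), b_c2 = numeric(c3),
    k_eca3 = c(0, 1, 0),
    W_lat = matrix(rnorm(c2 * cd, sd = sqrt(2 / c2)), c2, cd),
    b_lat = numeric(cd),
    W_t = gauss(8, c3, cd), b_t = numeric(cd),
    A_vlad = matrix(rnorm(cd * K, sd = 1 / sqrt(cd)), cd, K),
    b_vlad = numeric(K),
    C_vlad = matrix(rnorm(K * cd, sd = 0.5), K, cd),
    W_f1 = matrix(rnorm(D * h, sd = sqrt(2 / D)), D, h),
    b_f1 = numeric(h),
    W_f2 = matrix(rnorm(h * nc, sd = 0.01), h, nc),
    b_f2 = numeric(nc)
  ))
}

# precompute per-sample coordinate maps for all levels
preprocess_sparse <- function(sp) {
  n0 <- nrow(sp$coords)
  maps0 <- build_maps_s1(sp$coords)
  d1 <- build_maps_down(sp$coords)
  maps1 <- build_maps_s1(d1$coords)
  d2 <- build_maps_down(d1$coords)
  maps2 <- build_maps_s1(d2$coords)
  up <- build_maps_up(d1$coords, d2$coords)
  list(feats = sp$feats, n0 = n0, n1 = nrow(d1$coords), n2 = nrow(d2$coords),
       maps0 = maps0, dmaps1 = d1$maps, maps1 = maps1, dmaps2 = d2$maps,
       maps2 = maps2, up = up)
}

net_forward <- function(pp, w, cfg, keep_cache = FALSE) {
  relu <- function(x) x * (x > 0)
  a0 <- conv_forward(pp$feats, w$W_in, w$b_in, pp$maps0, pp$n0)
  r0 <- relu(a0)
  e1 <- eca_forward(r0, w$k_eca1)
  a1 <- conv_forward(e1$y, w$W_d1, w$b_d1, pp$dmaps1, pp$n1)
  r1 <- relu(a1)
  a1b <- conv_forward(r1, w$W_c1, w$b_c1, pp$maps1, pp$n1)
  r1b <- relu(a1b)
  e2 <- eca_forward(r1b, w$k_eca2)
  a2 <- conv_forward(e2$y, w$W_d2, w$b_d2, pp$dmaps2, pp$n2)
  r2 <- relu(a2)
  a2b <- conv_forward(r2, w$W_c2, w$b_c2, pp$maps2, pp$n2)
  r2b <- relu(a2b)
  e3 <- eca_forward(r2b, w$k_eca3)
  lat <- sweep(e2$y %*% w$W_lat, 2L, w$b_lat, "+")
  td <- conv_forward(e3$y, w$W_t, w$b_t, pp$up, pp$n1)
  fuse <- lat + td
  fr <- relu(fuse)
  nv <- netvlad_forward(fr, w$A_vlad, w$b_vlad, w$C_vlad)
  h_pre <- as.numeric(nv$desc %*% w$W_f1) + w$b_f1
  h <- pmax(h_pre, 0)
  logits <- as.numeric(h %*% w$W_f2) + w$b_f2
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  out <- list(probs = p)
  if (keep_cache)
    out$cache <- list(a0 = a0, r0 = r0, e1 = e1, a1 = a1, r1 = r1,
                      a1b = a1b, r1b = r1b, e2 = e2, a2 = a2, r2 = r2,
                      a2b = a2b, r2b = r2b, e3 = e3, fuse = fuse, fr = fr,
                      nv = nv, h_pre = h_pre, h = h)
  out
}

net_backward <- function(pp, w, cfg, fw, y_idx) {
  cc <- fw$cache
  g <- list()
  dlogits <- fw$probs
  dlogits[y_idx] <- dlogits[y_idx] - 1
  g$W_f2 <- outer(cc$h, dlogits)
  g$b_f2 <- dlogits
  dh <- as.numeric(w$W_f2 %*% dlogits) * (cc$h_pre > 0)
  g$W_f1 <- outer(cc$nv$desc, dh)
  g$b_f1 <- dh
  ddesc <- as.numeric(w$W_f1 %*% dh)
  nb <- netvlad_backward(ddesc, cc$fr, w$A_vlad, w$b_vlad, w$C_vlad, cc$nv)
  g$A_vlad <- nb$dA; g$b_vlad <- nb$db; g$C_vlad <- nb$dC
  dfuse <- nb$df * (cc$fuse > 0)
  g$W_lat <- crossprod(cc$e2$y, dfuse)
  g$b_lat <- colSums(dfuse)
  de2_from_lat <- dfuse %*% t(w$W_lat)
  tb <- conv_backward(dfuse, cc$e3$y, w$W_t, pp$up, pp$n2)
  g$W_t <- tb$dW; g$b_t <- tb$db
  e3b <- eca_backward(tb$dfeats, cc$r2b, w$k_eca3, cc$e3)
  g$k_eca3 <- e3b$dk
  dr2b <- e3b$dx * (cc$a2b > 0)
  c2b <- conv_backward(dr2b, cc$r2, w$W_c2, pp$maps2, pp$n2)
  g$W_c2 <- c2b$dW; g$b_c2 <- c2b$db
  dr2 <- c2b$dfeats * (cc$a2 > 0)
  d2b <- conv_backward(dr2, cc$e2$y, w$W_d2, pp$dmaps2, pp$n1)
  g$W_d2 <- d2b$dW; g$b_d2 <- d2b$db
  de2 <- de2_from_lat + d2b$dfeats
  e2b <- eca_backward(de2, cc$r1b, w$k_eca2, cc$e2)
  g$k_eca2 <- e2b$dk
  dr1b <- e2b$dx * (cc$a1b > 0)
  c1b <- conv_backward(dr1b, cc$r1, w$W_c1, pp$maps1, pp$n1)
  g$W_c1 <- c1b$dW; g$b_c1 <- c1b$db
  dr1 <- c1b$dfeats * (cc$a1 > 0)
  d1b <- conv_backward(dr1, cc$e1$y, w$W_d1, pp$dmaps1, pp$n0)
  g$W_d1 <- d1b$dW; g$b_d1 <- d1b$db
  e1b <- eca_backward(d1b$dfeats, cc$r0, w$k_eca1, cc$e1)
  g$k_eca1 <- e1b$dk
  dr0 <- e1b$dx * (cc$a0 > 0)
  c0b <- conv_backward(dr0, pp$feats, w$W_in, pp$maps0, pp$n0)
  g$W_in <- c0b$dW; g$b_in <- c0b$db
  g
}

#' Forward pass of the ligand classifier
#'
#' Runs the network on a quantized sparse input and returns the class
#' probability vector and ranking. Deterministic given `(input, weights)`,
#' invariant to input point order and to translations of the input by whole
#' quantization cells (coordinates are canonicalized in [quantize()]); it
#' is *not* rotation invariant.
#'
#' @param sparse result of [quantize()] (must be non-empty).
#' @param model a trained model from [train_model()] (or a list with
#'   `weights`, `cfg`, `labels`).
#' @return A [prediction_result()] over the model's labels.
#' @export
forward <- function(sparse, model) {
  if (is.null(sparse$coords) || nrow(sparse$coords) == 0L)
    stop("empty sparse input")
  pp <- preprocess_sparse(sparse)
  fw <- net_forward(pp, model$weights, model$cfg)
  prediction_result(fw$probs, model$labels)
}

adam_step <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

#' Training schedule
#'
#' @param epochs number of passes over the training set (default 30).
#' @param lr Adam learning rate (default 1e-3).
#' @param grad_accum number of samples whose gradients are accumulated
#'   (averaged) per optimizer step (default 8).
#' @param oversample optional named numeric vector of per-class replication
#'   factors (>= 1) applied to the training list each epoch, to counter
#'   class imbalance.
#' @return A list with the schedule fields.
#' @export
training_schedule <- function(epochs = 30L, lr = 1e-3, grad_accum = 8L,
                              oversample = NULL) {
  list(epochs = as.integer(epochs), lr = lr,
       grad_accum = as.integer(grad_accum), oversample = oversample)
}

#' Train the sparse-convolution ligand classifier
#'
#' Minimizes the cross-entropy of the softmax head with Adam, shuffling the
#' training list each epoch and averaging gradients over `grad_accum`
#' samples per step. With a fixed `cfg$seed` the run (initialization,
#' shuffling, log) is bit-reproducible on one machine.
#'
#' @param clouds list of `point_cloud` training samples.
#' @param labels character vector of class labels (>= 2 distinct).
#' @param cfg a [model_config()]; `num_classes` must equal the number of
#'   catalog labels (defaulted from the observed labels when
#'   `catalog = NULL`).
#' @param schedule a [training_schedule()].
#' @param catalog optional `group_catalog` (or label vector) fixing the
#'   output head order; defaults to the sorted observed labels.
#' @param verbose print per-epoch loss/accuracy.
#' @return An object of class `densiligand_model`: list with `weights`,
#'   `cfg`, `labels` and `log` (data.frame epoch/loss/accuracy).
#' @export
train_model <- function(clouds, labels, cfg = NULL,
                        schedule = training_schedule(), catalog = NULL,
                        verbose = FALSE) {
  labels <- as.character(labels)
  stopifnot(length(clouds) == length(labels))
  cat_labels <- if (is.null(catalog)) sort(unique(labels))
                else if (inherits(catalog, "group_catalog")) catalog$labels
                else as.character(catalog)
  if (length(unique(labels)) < 2L)
    stop("training requires at least two classes")
  if (!all(labels %in% cat_labels)) stop("labels outside the catalog")
  if (is.null(cfg))
    cfg <- model_config(num_classes = length(cat_labels),
                        channels = c(16L, 32L, 64L),
                        descriptor_channels = 32L, vlad_clusters = 8L,
                        hidden = 32L)
  if (cfg$num_classes != length(cat_labels))
    stop("cfg$num_classes (", cfg$num_classes,
         ") must equal the catalog size (", length(cat_labels), ")")
  y <- match(labels, cat_labels)
  pps <- lapply(clouds, function(cl) preprocess_sparse(quantize(cl, cfg)))
  w <- init_weights(cfg)
  state <- list(t = 0L,
                m = lapply(w, function(x) x * 0),
                v = lapply(w, function(x) x * 0))
  base_idx <- seq_along(pps)
  if (!is.null(schedule$oversample)) {
    reps <- schedule$oversample[labels]
    reps[is.na(reps)] <- 1
    base_idx <- rep(base_idx, times = pmax(1L, round(reps)))
  }
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    accuracy = numeric(0))
  local_seed(cfg$seed + 1L, {
    for (ep in seq_len(schedule$epochs)) {
      ord <- sample(base_idx)
      losses <- numeric(length(ord))
      hits <- logical(length(ord))
      acc_g <- NULL
      n_acc <- 0L
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        fw <- net_forward(pps[[i]], w, cfg, keep_cache = TRUE)
        losses[ii] <- -log(max(fw$probs[y[i]], 1e-12))
        hits[ii] <- which.max(fw$probs) == y[i]
        g <- net_backward(pps[[i]], w, cfg, fw, y[i])
        if (is.null(acc_g)) acc_g <- g
        else for (nm in names(g)) acc_g[[nm]] <- acc_g[[nm]] + g[[nm]]
        n_acc <- n_acc + 1L
        if (n_acc == schedule$grad_accum || ii == length(ord)) {
          for (nm in names(acc_g)) acc_g[[nm]] <- acc_g[[nm]] / n_acc
          upd <- adam_step(w, acc_g, state, schedule$lr)
          w <- upd$w; state <- upd$state
          acc_g <- NULL; n_acc <- 0L
        }
      }
      log <- rbind(log, data.frame(epoch = ep, loss = mean(losses),
                                   accuracy = mean(hits)))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, mean(losses),
                        mean(hits)))
    }
  })
  structure(list(weights = w, cfg = cfg, labels = cat_labels, log = log),
            class = "densiligand_model")
}

#' @export
print.densiligand_model <- function(x, ...) {
  cat(sprintf("<densiligand_model> %d classes, channels (%s), %d VLAD clusters\n",
              x$cfg$num_classes, paste(x$cfg$channels, collapse = ", "),
              x$cfg$vlad_clusters))
  if (nrow(x$log))
    cat(sprintf("  trained %d epochs; final loss %.4f, accuracy %.3f\n",
                max(x$log$epoch), x$log$loss[nrow(x$log)],
                x$log$accuracy[nrow(x$log)]))
  invisible(x)
}

#' Predict the ligand group of a point cloud
#'
#' @param model a `densiligand_model`.
#' @param cloud a `point_cloud`.
#' @return A [prediction_result()].
#' @export
predict_cloud <- function(model, cloud) {
  forward(quantize(cloud, model$cfg), model)
}

#' Top-k labels of a prediction
#'
#' The first `k` entries of the prediction's ranking (labels ordered by
#' descending probability, ties broken by catalog order).
#'
#' @param result a `prediction_result`.
#' @param k integer in `[1, catalog size]` (default 10).
#' @return Character vector of `k` labels.
#' @export
predict_topk <- function(result, k = 10L) {
  stopifnot(inherits(result, "prediction_result"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(result$ranking))
    stop("`k` must be between 1 and the catalog size")
  result$ranking[seq_len(k)]
}

catalog_hash <- function(labels) {
  crc32_raw(charToRaw(paste(labels, collapse = "\x1f")))
}

#' Save a model checkpoint
#'
#' Writes a single-file checkpoint containing the weights, the model
#' configuration, the label catalog and a catalog hash. [load_checkpoint()]
#' verifies the hash so a checkpoint cannot silently be used with a
#' mismatched catalog/head.
#'
#' @param model a `densiligand_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "densiligand_model"))
  obj <- list(weights = model$weights, cfg = model$cfg,
              labels = model$labels, log = model$log,
              catalog_hash = catalog_hash(model$labels))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @param catalog optional catalog (or label vector) the checkpoint must
#'   match; mismatches are refused.
#' @return A `densiligand_model`.
#' @export
load_checkpoint <- function(path, catalog = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$catalog_hash, catalog_hash(obj$labels)))
    stop("checkpoint corrupt: catalog hash mismatch")
  if (!is.null(catalog)) {
    labels <- if (inherits(catalog, "group_catalog")) catalog$labels
              else as.character(catalog)
    if (!identical(labels, obj$labels))
      stop("checkpoint catalog disagrees with the supplied catalog; refusing")
  }
  if (obj$cfg$num_classes != length(obj$labels))
    stop("checkpoint head size disagrees with its catalog; refusing")
  structure(list(weights = obj$weights, cfg = obj$cfg, labels = obj$labels,
                 log = obj$log),
            class = "densiligand_model")
}
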