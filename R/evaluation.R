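#' Wrap a probability vector as a prediction result
#'
#' @param probabilities numeric vector over the catalog's labels
#'   (non-negative, summing to 1 within 1e-6; renormalized exactly).
#' @param catalog a `group_catalog` (or character vector of labels).
#' @return An object of class `prediction_result` with the probability
#'   vector (named by label) and the derived `ranking`: labels by
#'   descending probability, ties broken by catalog order.
#' @export
prediction_result <- function(probabilities, catalog) {
  labels <- if (inherits(catalog, "group_catalog")) catalog$labels
            else as.character(catalog)
  p <- as.numeric(probabilities)
  if (length(p) != length(labels))
    stop("probability vector length must equal catalog size")
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6)
    stop("probabilities must be a simplex vector (>= 0, sum 1)")
  p <- pmax(p, 0); p <- p / sum(p)
  names(p) <- labels
  ord <- order(-p, seq_along(p))
  structure(list(probabilities = p, ranking = labels[ord]),
            class = "prediction_result")
}

# rank of the true label: 1 + number of labels with strictly greater
# probability, ties broken by catalog order
rank_of_truth <- function(pred, truth) {
  p <- pred$probabilities
  i <- match(truth, names(p))
  if (is.na(i)) stop("unknown label: ", truth)
  sum(p > p[i]) + sum(p[seq_len(i - 1L)] == p[i]) + 1L
}

#' Score predictions against true labels
#'
#' Computes the five evaluation metrics: classification accuracy (top-1),
#' top-10 accuracy (true label among the ten highest-ranked), mean correct
#' prediction rank, Brier score (mean over cases of `(1 - p_truth)^2`, the
#' squared probability error of the correct class), and macro-averaged
#' recall (unweighted mean of per-class recognition rates over the classes
#' present in the truth set).
#'
#' @param predictions list of `prediction_result` objects.
#' @param truths character vector of true labels (same length).
#' @param catalog a `group_catalog` or character label vector.
#' @param top_k rank cutoff of the top-k accuracy (default 10).
#' @return An object of class `evaluation_report` with fields `accuracy`,
#'   `top10_accuracy`, `mean_rank`, `brier`, `macro_recall` and
#'   `per_class_recall` (named numeric vector).
#' @export
score_predictions <- function(predictions, truths, catalog, top_k = 10L) {
  labels <- if (inherits(catalog, "group_catalog")) catalog$labels
            else as.character(catalog)
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  if (!all(truths %in% labels))
    stop("unknown label(s): ",
         paste(unique(setdiff(truths, labels)), collapse = ", "))
  ranks <- mapply(rank_of_truth, predictions, truths)
  p_truth <- mapply(function(pr, tr) pr$probabilities[[tr]],
                    predictions, truths)
  top1 <- vapply(predictions, function(pr) pr$ranking[1], character(1))
  present <- sort(unique(truths))
  per_class <- vapply(present, function(cl) {
    mean(top1[truths == cl] == cl)
  }, numeric(1))
  structure(list(
    accuracy = mean(ranks == 1L),
    top10_accuracy = mean(ranks <= top_k),
    mean_rank = mean(ranks),
    brier = mean((1 - p_truth)^2),
    macro_recall = mean(per_class),
    per_class_recall = per_class,
    n = length(truths)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$n, "cases\n")
  cat(sprintf("  accuracy       : %.4f\n", x$accuracy))
  cat(sprintf("  top-10 accuracy: %.4f\n", x$top10_accuracy))
  cat(sprintf("  mean rank      : %.4f\n", x$mean_rank))
  cat(sprintf("  Brier score    : %.4f\n", x$brier))
  cat(sprintf("  macro recall   : %.4f\n", x$macro_recall))
  invisible(x)
}

#' Split configuration for evaluation protocols
#'
#' @param train_fraction fraction of items in the training side (default
#'   0.70).
#' @param validation_fraction fraction *of the training set* held out for
#'   validation (default 0.25).
#' @param n_folds folds of the cross-validation protocol (default 3).
#' @param seed integer RNG seed for tie shuffling.
#' @return An object of class `split_config`.
#' @export
split_config <- function(train_fraction = 0.70, validation_fraction = 0.25,
                         n_folds = 3L, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("`validation_fraction` must be in (0, 1)")
  if (n_folds < 2L) stop("`n_folds` must be >= 2")
  structure(list(train_fraction = train_fraction,
                 validation_fraction = validation_fraction,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "split_config")
}

#' Deposit-grouped stratified train/test split
#'
#' Splits items into train and test sides such that no group (e.g. all
#' ligands from one PDB deposit) is divided across sides, while per-class
#' proportions track `train_fraction` as closely as the grouping constraint
#' allows. Assignment is greedy: classes are visited from most to least
#' frequent, and within a class the groups richest in that class are
#' assigned first, each to the side with the larger remaining deficit for
#' that class. The group/side disjointness is re-asserted on every call.
#'
#' @param labels character vector of class labels, one per item.
#' @param groups vector of group keys, one per item.
#' @param cfg a [split_config()].
#' @return List with integer item indices `train` and `test`.
#' @export
grouped_stratified_split <- function(labels, groups, cfg = split_config()) {
  stopifnot(length(labels) == length(groups))
  labels <- as.character(labels); groups <- as.character(groups)
  ugroups <- unique(groups)
  if (length(ugroups) < 2L)
    stop("cannot split: a single group contains all items")
  if (length(ugroups) == 2L)
    warning("only two groups: one group per side regardless of fractions")
  tab <- table(groups, labels)   # group x class counts
  class_sizes <- sort(colSums(tab), decreasing = TRUE)
  side <- setNames(rep(NA_character_, length(ugroups)), ugroups)
  # remaining per-class deficits for each side
  train_target <- cfg$train_fraction * class_sizes
  test_target <- (1 - cfg$train_fraction) * class_sizes
  train_have <- test_have <- setNames(numeric(length(class_sizes)),
                                      names(class_sizes))
  for (cl in names(class_sizes)) {
    cand <- rownames(tab)[is.na(side[rownames(tab)]) & tab[, cl] > 0]
    if (length(cand) == 0L) next
    cand <- local_seed(cfg$seed, sample(cand))      # shuffle before ordering
    cand <- cand[order(-tab[cand, cl])]             # richest in class first
    for (g in cand) {
      d_train <- train_target[cl] - train_have[cl]
      d_test <- test_target[cl] - test_have[cl]
      pick <- if (d_train / cfg$train_fraction >=
                  d_test / (1 - cfg$train_fraction)) "train" else "test"
      side[g] <- pick
      counts <- tab[g, ]
      if (pick == "train") train_have <- train_have + counts[names(train_have)]
      else test_have <- test_have + counts[names(test_have)]
    }
  }
  # any group with no labeled items left: balance overall fraction
  for (g in names(side)[is.na(side)]) {
    side[g] <- if (sum(train_have) / max(1, sum(train_have) + sum(test_have)) <
                   cfg$train_fraction) "train" else "test"
  }
  if (all(side == "train")) side[names(side)[length(side)]] <- "test"
  if (all(side == "test")) side[names(side)[1]] <- "train"
  train_ids <- which(side[groups] == "train")
  test_ids <- which(side[groups] == "test")
  # hard integrity assertion: a group must never leak across sides
  stopifnot(length(intersect(groups[train_ids], groups[test_ids])) == 0L)
  list(train = unname(train_ids), test = unname(test_ids))
}

#' Grouped stratified k-fold partition
#'
#' Assigns whole groups to folds so that every item appears in exactly one
#' test fold and per-fold class proportions are approximately preserved.
#' Greedy: groups are visited from largest to smallest and placed in the
#' fold currently poorest in the group's dominant class (ties: smallest
#' fold, then lowest fold index).
#'
#' @inheritParams grouped_stratified_split
#' @return List of `cfg$n_folds` elements, each a list with item indices
#'   `train` and `test`.
#' @export
stratified_kfold <- function(labels, groups, cfg = split_config()) {
  stopifnot(length(labels) == length(groups))
  labels <- as.character(labels); groups <- as.character(groups)
  ugroups <- unique(groups)
  k <- cfg$n_folds
  if (length(ugroups) < k)
    stop("fewer groups (", length(ugroups), ") than folds (", k, ")")
  tab <- table(groups, labels)
  gsize <- rowSums(tab)
  ord <- local_seed(cfg$seed, sample(rownames(tab)))
  ord <- ord[order(-gsize[ord])]
  fold_of <- setNames(integer(length(ugroups)), rownames(tab))
  fold_class <- matrix(0, nrow = k, ncol = ncol(tab),
                       dimnames = list(NULL, colnames(tab)))
  fold_total <- numeric(k)
  for (g in ord) {
    dom <- colnames(tab)[which.max(tab[g, ])]
    f <- order(fold_class[, dom], fold_total, seq_len(k))[1]
    fold_of[g] <- f
    fold_class[f, ] <- fold_class[f, ] + tab[g, ]
    fold_total[f] <- fold_total[f] + gsize[g]
  }
  lapply(seq_len(k), function(f) {
    test_ids <- which(fold_of[groups] == f)
    list(train = which(fold_of[groups] != f), test = test_ids)
  })
}

#' Calibration curve of a classifier
#'
#' Bins cases by their top-1 confidence (maximum predicted probability)
#' into `n_bins` equal-width bins over [0, 1] and reports, per bin, the
#' mean confidence, the empirical top-1 accuracy and the case count. A
#' well-calibrated classifier's accuracy tracks its confidence linearly.
#'
#' @param predictions list of `prediction_result` objects.
#' @param truths character vector of true labels.
#' @param n_bins number of bins (>= 2, default 10).
#' @return A data.frame with columns `bin_lo`, `bin_hi`, `mean_confidence`,
#'   `accuracy`, `count` and `empty` (flagging zero-count bins, where the
#'   confidence/accuracy columns are `NA`).
#' @export
calibration_curve <- function(predictions, truths, n_bins = 10L) {
  if (n_bins < 2L) stop("`n_bins` must be >= 2")
  conf <- vapply(predictions, function(p) max(p$probabilities), numeric(1))
  correct <- vapply(predictions, function(p) p$ranking[1], character(1)) ==
    truths
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  out <- data.frame(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L])
  out$count <- tabulate(bin, nbins = n_bins)
  out$mean_confidence <- NA_real_
  out$accuracy <- NA_real_
  for (b in which(out$count > 0L)) {
    out$mean_confidence[b] <- mean(conf[bin == b])
    out$accuracy[b] <- mean(correct[bin == b])
  }
  out$empty <- out$count == 0L
  out[, c("bin_lo", "bin_hi", "mean_confidence", "accuracy", "count", "empty")]
}
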