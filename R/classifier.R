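# k-nearest-neighbors behavior classifier in (nPM, nCM, nCD) space, with
# cross-validated choice of k and the 12/15 temporal pruning filter.

BEHAVIOR_CLASSES <- c("grooming", "locomotion", "rest")

feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("nPM", "nCM", "nCD") %in% names(x)))
    x <- as.matrix(x[, c("nPM", "nCM", "nCD")])
  }
  storage.mode(x) <- "double"
  x
}

#' Fit a kNN behavior classifier
#'
#' Stores the training samples and builds a k-d tree for nearest-neighbor
#' search under Euclidean distance in the normalized feature space (the
#' axes are constructed to be commensurate, so no re-standardization is
#' applied). Tree queries return exactly the exhaustive-search neighbor
#' lists; distance ties are broken toward the lower training-sample
#' index.
#'
#' @param x feature matrix or data.frame with columns `nPM`, `nCM`, `nCD`.
#' @param labels behavior label per sample, from
#'   `c("grooming", "locomotion", "rest")`.
#' @param k number of neighbors used by [classify()].
#' @return object of class `groom_knn`.
#' @export
fit_knn <- function(x, labels, k = 10) {
  x <- feature_matrix(x)
  labels <- as.character(labels)
  if (nrow(x) == 0L) stop("training set is empty", call. = FALSE)
  if (length(labels) != nrow(x)) {
    stop("one label per training sample is required", call. = FALSE)
  }
  bad <- !(labels %in% BEHAVIOR_CLASSES)
  if (any(bad)) {
    stop(sprintf("labels outside the three-class alphabet: %s",
                 paste(unique(labels[bad]), collapse = ", ")), call. = FALSE)
  }
  if (k > nrow(x)) stop("`k` cannot exceed the number of training samples",
                        call. = FALSE)
  model <- structure(
    list(x = x, labels = labels, k = as.integer(k),
         n = nrow(x), cache = new.env(parent = emptyenv())),
    class = "groom_knn"
  )
  model$cache$tree <- .kdtree_build(x)
  model
}

knn_tree <- function(model) {
  tr <- model$cache$tree
  if (is.null(tr) || !.kdtree_valid(tr)) {
    tr <- .kdtree_build(model$x)
    model$cache$tree <- tr
  }
  tr
}

#' Nearest neighbors of query points
#'
#' @param model a `groom_knn`.
#' @param queries feature matrix or data.frame.
#' @param k neighbors per query (defaults to the model's k).
#' @return list with `index` (n x k matrix of 1-based training indices,
#'   ordered by increasing distance, ties by index) and `dist`.
#' @export
knn_neighbors <- function(model, queries, k = model$k) {
  q <- feature_matrix(queries)
  if (k > model$n) stop("`k` cannot exceed the number of training samples",
                        call. = FALSE)
  .kdtree_query(knn_tree(model), q, as.integer(k))
}

#' Classify feature vectors into grooming / locomotion / rest
#'
#' Each query is labeled by the most frequent label among its k nearest
#' training samples. Vote ties are broken by the label of the single
#' nearest neighbor; if that label is not among the tied leaders, the
#' first tied class in the fixed order grooming < locomotion < rest
#' wins. Feature rows that are `NA` (frames before the fly was ever
#' detected) are labeled `rest`, consistent with the stationary-fly
#' reading of a missing detection.
#'
#' @param model a `groom_knn`.
#' @param features feature matrix or `groom_features` data.frame.
#' @return character vector of raw labels, one per feature row.
#' @export
classify <- function(model, features) {
  q <- feature_matrix(features)
  out <- rep("rest", nrow(q))
  ok <- stats::complete.cases(q)
  if (!any(ok)) return(out)
  nn <- knn_neighbors(model, q[ok, , drop = FALSE], k = model$k)
  lab <- matrix(model$labels[nn$index], nrow = sum(ok))
  out[ok] <- majority_vote(lab)
  out
}

# majority label per row of a neighbor-label matrix (column 1 = nearest);
# ties resolved by the nearest neighbor's label, then fixed class order
majority_vote <- function(lab) {
  counts <- vapply(BEHAVIOR_CLASSES, function(cl) rowSums(lab == cl),
                   numeric(nrow(lab)))
  if (nrow(lab) == 1L) counts <- matrix(counts, nrow = 1)
  first <- max.col(counts, ties.method = "first")
  last <- max.col(counts, ties.method = "last")
  pred <- BEHAVIOR_CLASSES[first]
  tied <- which(first != last)
  for (i in tied) {
    lead <- BEHAVIOR_CLASSES[counts[i, ] == counts[i, first[i]]]
    pred[i] <- if (lab[i, 1L] %in% lead) lab[i, 1L] else lead[1L]
  }
  pred
}

#' Cross-validated accuracy over a range of k
#'
#' Stratified 10-fold cross-validation of the kNN classifier, reporting
#' mean held-out accuracy for each candidate k. Supports re-choosing k;
#' the pipeline default of k = 10 balances accuracy and computing time.
#'
#' @param x,labels training data as in [fit_knn()].
#' @param k_range candidate neighbor counts.
#' @param folds number of folds (>= 2).
#' @param seed seed for the fold assignment.
#' @return data.frame with columns `k` and `accuracy`.
#' @export
cross_validate <- function(x, labels, k_range = 1:50, folds = 10,
                           seed = NULL) {
  x <- feature_matrix(x)
  labels <- as.character(labels)
  if (folds < 2) stop("`folds` must be at least 2", call. = FALSE)
  if (min(table(labels)) < folds) {
    stop("a class would be absent from some fold; use fewer folds",
         call. = FALSE)
  }
  kmax <- max(k_range)
  with_seed(seed, {
    fold <- integer(nrow(x))
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    correct <- matrix(0, folds, length(k_range))
    n_test <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- fit_knn(x[tr, , drop = FALSE], labels[tr],
                       k = min(kmax, sum(tr)))
      nn <- knn_neighbors(model, x[!tr, , drop = FALSE],
                          k = min(kmax, sum(tr)))
      lab <- matrix(model$labels[nn$index], nrow = sum(!tr))
      truth <- labels[!tr]
      n_test[f] <- length(truth)
      for (j in seq_along(k_range)) {
        k <- min(k_range[j], ncol(lab))
        pred <- majority_vote(lab[, seq_len(k), drop = FALSE])
        correct[f, j] <- sum(pred == truth)
      }
    }
    data.frame(k = k_range, accuracy = colSums(correct) / sum(n_test))
  })
}

#' Temporal pruning of grooming labels (12-of-15 filter)
#'
#' A raw grooming frame keeps its label only if it lies inside at least
#' one contiguous window of `window` frames containing `min_grooming` or
#' more raw grooming frames (the window slides one frame at a time).
#' Grooming frames failing the rule are relabeled as locomotion; other
#' labels pass through unchanged. The default 12/15 at 5 Hz removes
#' short grooming-like behavior such as stretching.
#'
#' @param labels character vector of raw per-analyzed-frame labels.
#' @param window filter length in analyzed frames.
#' @param min_grooming minimum grooming frames within the window.
#' @param strict for streams shorter than `window`: if `TRUE` relabel
#'   all grooming, otherwise treat the whole stream as a single window
#'   of its own length.
#' @return pruned label vector.
#' @export
prune_labels <- function(labels, window = 15, min_grooming = 12,
                         strict = FALSE) {
  if (!(window >= min_grooming && min_grooming >= 1)) {
    stop("need window >= min_grooming >= 1", call. = FALSE)
  }
  n <- length(labels)
  g <- labels == "grooming"
  if (!any(g)) return(labels)
  if (n < window) {
    keep <- if (strict) rep(FALSE, n) else sum(g) >= min_grooming
    labels[g & !keep] <- "locomotion"
    return(labels)
  }
  nw <- n - window + 1L
  cs <- c(0L, cumsum(g))
  ok <- (cs[(window + 1L):(n + 1L)] - cs[1L:nw]) >= min_grooming
  ok_cs <- c(0L, cumsum(ok))
  i <- seq_len(n)
  lo <- pmax(1L, i - window + 1L)
  hi <- pmin(i, nw)
  covered <- (ok_cs[hi + 1L] - ok_cs[lo]) > 0L
  labels[g & !covered] <- "locomotion"
  labels
}

#' Frame-level grooming accuracy and sensitivity
#'
#' Accuracy is the ratio of correct grooming labels to all output
#' grooming labels (precision of the grooming class); sensitivity is the
#' ratio of grooming identified by the classifier to all ground-truth
#' grooming frames (recall). Either is `NA` when its denominator is
#' zero.
#'
#' @param pred,truth equal-length label vectors.
#' @param positive the class evaluated (grooming).
#' @return list with `accuracy`, `sensitivity`, `tp`, `fp`, `fn`.
#' @export
evaluate_labels <- function(pred, truth, positive = "grooming") {
  if (length(pred) != length(truth)) {
    stop("prediction and truth streams differ in length", call. = FALSE)
  }
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  list(
    accuracy = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn
  )
}
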