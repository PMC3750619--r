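#' Depth-based classifiers DS and TAD
#'
#' Multi-class classification of expression profiles using within-class
#' Modified Band Depth.
#'
#' `class_ds` ("distance to the deepest samples' mean") computes, for each
#' class of the learning set, the depth-trimmed mean with trimming
#' proportion `alpha`, and assigns each test row to the class whose trimmed
#' mean is nearest in Euclidean distance. With `alpha = 0` it reduces to
#' the ordinary nearest-centroid rule.
#'
#' `class_tad` ("trimmed average distance") keeps, in each class, the
#' `ceiling((1 - alpha) * n_g)` deepest members, weights each retained
#' member proportionally to its within-class depth (weights normalised to
#' sum 1), and scores a test row by the weighted average Euclidean distance
#' to those members; the class with the smallest score wins. Trimming the
#' most external members makes both rules resistant to contaminated
#' learning samples.
#'
#' Ties in the arg-min are broken in favour of the class appearing first in
#' `labels`, so predictions are deterministic. Predictions are invariant
#' under any consistent permutation of the variables and under adding a
#' constant vector to all learning and test rows.
#'
#' @param x numeric learning matrix, samples in rows.
#' @param labels class label for each row of `x` (>= 2 classes, each with
#'   at least 2 members).
#' @param newdata numeric matrix of samples to classify, same columns as
#'   `x`.
#' @param alpha trimming proportion in `[0, 1)`. Default 0.2.
#' @return character vector (or factor matching `labels`' type) of
#'   predicted class labels, one per row of `newdata`.
#' @examples
#' sim <- simulate_two_class(n_per_class = 25, d = 50, n_informative = 10,
#'                           shift = 3, seed = 7)
#' train <- c(1:20, 26:45); test <- setdiff(1:50, train)
#' mean(class_ds(sim$x[train, ], sim$labels[train],
#'               sim$x[test, ]) == sim$labels[test])
#' @export
class_ds <- function(x, labels, newdata, alpha = 0.2) {
  prep <- check_learning_set(x, labels, newdata)
  centers <- vapply(prep$classes, function(g) {
    tmean(prep$x[prep$labels == g, , drop = FALSE], alpha = alpha)$tm
  }, numeric(ncol(prep$x)))
  # scores: one column per class, rows follow newdata
  scores <- vapply(seq_along(prep$classes), function(j) {
    sqrt(rowSums(sweep(prep$newdata, 2L, centers[, j])^2))
  }, numeric(nrow(prep$newdata)))
  pick_class(scores, prep$classes, labels)
}

#' @rdname class_ds
#' @export
class_tad <- function(x, labels, newdata, alpha = 0.2) {
  prep <- check_learning_set(x, labels, newdata)
  scores <- vapply(prep$classes, function(g) {
    xg <- prep$x[prep$labels == g, , drop = FALSE]
    dp <- mbd(xg)
    keep <- dp$ordering[seq_len(ceiling((1 - alpha) * nrow(xg)))]
    w <- dp$depth[keep] / sum(dp$depth[keep])
    dist_to <- vapply(keep, function(i) {
      sqrt(rowSums(sweep(prep$newdata, 2L, xg[i, ])^2))
    }, numeric(nrow(prep$newdata)))
    as.numeric(dist_to %*% w)
  }, numeric(nrow(prep$newdata)))
  pick_class(scores, prep$classes, labels)
}

check_learning_set <- function(x, labels, newdata) {
  x <- as_depth_matrix(x, "samples")
  newdata <- as_depth_matrix(newdata, "samples", min_rows = 1L)
  check_same_d(x, newdata)
  if (length(labels) != nrow(x))
    stop("dimension mismatch: one label per learning row is required",
         call. = FALSE)
  labels_chr <- as.character(labels)
  classes <- unique(labels_chr)        # first-appearance order: tie-break
  if (length(classes) < 2L)
    stop("degenerate class: at least two classes are required",
         call. = FALSE)
  sizes <- table(labels_chr)
  if (any(sizes < 2L))
    stop(sprintf("degenerate class: class '%s' has fewer than 2 samples",
                 names(sizes)[which(sizes < 2L)[1L]]), call. = FALSE)
  list(x = x, labels = labels_chr, newdata = newdata, classes = classes)
}

pick_class <- function(scores, classes, original_labels) {
  scores <- matrix(scores, ncol = length(classes))
  pred <- classes[apply(scores, 1L, which.min)]  # which.min: first wins
  if (is.factor(original_labels)) factor(pred, levels = levels(original_labels))
  else pred
}
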