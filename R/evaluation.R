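#' Train/test split of a labelled dataset
#'
#' Seeded, deterministic 80/20 (by default) partition.  When stratified
#' (default), sampling is within class, so per-class proportions match the
#' requested fraction within one sample.
#'
#' @param labels integer class labels, or a `DatasetManifest` (its `ec`
#'   column is used and ids are returned).
#' @param train_fraction fraction assigned to the training partition.
#' @param stratified sample within class (requires >= 2 samples per class).
#' @param seed integer seed.
#' @return list with `train` and `test`: integer indices (or manifest ids).
#' @export
split_dataset <- function(labels, train_fraction = 0.8, stratified = TRUE,
                          seed = 1L) {
  ids <- NULL
  if (inherits(labels, "DatasetManifest") || is.data.frame(labels)) {
    ids <- labels$id
    labels <- labels$ec
  }
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(labels)
  train <- withr::with_seed(as.integer(seed), {
    if (stratified) {
      cls <- split(seq_len(n), labels)
      small <- names(cls)[lengths(cls) < 2L]
      if (length(small)) {
        stop("stratified split needs >= 2 samples per class; class(es) ",
             paste(small, collapse = ", "), " too small")
      }
      sort(unlist(lapply(cls, function(ix) {
        sample(ix, round(length(ix) * train_fraction))
      }), use.names = FALSE))
    } else {
      sort(sample.int(n, round(n * train_fraction)))
    }
  })
  test <- setdiff(seq_len(n), train)
  if (!is.null(ids)) list(train = ids[train], test = ids[test])
  else list(train = train, test = test)
}

#' Row-normalized confusion matrix, in percent
#'
#' Row = true class, column = predicted class; each row of a class that
#' occurs sums to 100, and the diagonal holds the per-class accuracies.
#' Rows of absent classes are zero.
#'
#' @param true,pred equal-length integer label vectors in 1..n_classes.
#' @param n_classes matrix dimension (default 6 EC classes).
#' @return `ConfusionMatrix`: n_classes x n_classes numeric matrix.
#' @export
confusion_matrix_percent <- function(true, pred, n_classes = 6L) {
  true <- as.integer(true); pred <- as.integer(pred)
  stopifnot(length(true) == length(pred))
  if (any(c(true, pred) < 1L) || any(c(true, pred) > n_classes)) {
    stop("labels must lie in 1..", n_classes)
  }
  cm <- matrix(0, n_classes, n_classes,
               dimnames = list(true = paste0("EC", 1:n_classes),
                               pred = paste0("EC", 1:n_classes)))
  for (i in seq_along(true)) cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1
  rs <- rowSums(cm)
  cm[rs > 0, ] <- 100 * cm[rs > 0, , drop = FALSE] / rs[rs > 0]
  class(cm) <- c("ConfusionMatrix", class(cm))
  cm
}

#' @export
print.ConfusionMatrix <- function(x, digits = 1, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Overall accuracy
#'
#' @param true,pred equal-length label vectors.
#' @return fraction of agreeing positions.
#' @export
overall_accuracy <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  mean(true == pred)
}

#' One-vs-rest ROC curves and AUC per class
#'
#' For each class, the decision scores of that class are swept over their
#' unique values; ties move the curve diagonally in one step, and the AUC
#' is the trapezoidal area.  A class absent from `true` yields `auc = NA`
#' with `defined = FALSE` (never 0).
#'
#' @param scores n x n_classes matrix of decision scores (e.g.
#'   [knn_predict()] scores).
#' @param true integer labels in 1..n_classes.
#' @return `ROCResult`: list per class with `curve` (data frame fpr, tpr),
#'   `auc`, `defined`; plus `macro_auc` (mean over defined classes).
#' @export
roc_auc_per_class <- function(scores, true) {
  scores <- as.matrix(scores)
  true <- as.integer(true)
  stopifnot(nrow(scores) == length(true))
  n_classes <- ncol(scores)
  per_class <- vector("list", n_classes)
  names(per_class) <- paste0("EC", seq_len(n_classes))
  for (cl in seq_len(n_classes)) {
    pos <- true == cl
    if (!any(pos) || all(pos)) {
      per_class[[cl]] <- list(curve = NULL, auc = NA_real_, defined = FALSE)
      next
    }
    s <- scores[, cl]
    np <- sum(pos); nn <- sum(!pos)
    # sweep thresholds downward over unique scores; ties step jointly
    ord <- order(s, decreasing = TRUE)
    sp <- s[ord]; yp <- pos[ord]
    tp <- cumsum(yp); fp <- cumsum(!yp)
    last <- c(diff(sp) != 0, TRUE)   # last index of each tie group
    tpr <- c(0, tp[last] / np)
    fpr <- c(0, fp[last] / nn)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    per_class[[cl]] <- list(curve = data.frame(fpr = fpr, tpr = tpr),
                            auc = auc, defined = TRUE)
  }
  aucs <- vapply(per_class, `[[`, numeric(1), "auc")
  structure(list(per_class = per_class, auc = aucs,
                 macro_auc = mean(aucs, na.rm = TRUE)),
            class = "ROCResult")
}
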