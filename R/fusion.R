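#' Late fusion of per-stream class probabilities
#'
#' `fuse_architecture1` concatenates the class-probability vectors produced
#' by the three whole-map CNNs in the fixed order (angle XA, distance XD,
#' mutation XL), giving a vector of length `3 * l` (18 for l = 6 classes).
#'
#' `fuse_architecture2` concatenates the probabilities of the per-channel
#' CNNs -- one per XA channel (23), XD bin-channel (8) and XL bin-channel
#' (25), in that order -- giving length `l * 56` (336 for l = 6).
#'
#' @param pA,pD,pL length-l probability vectors from the XA, XD and XL
#'   streams.
#' @return `FusedVector`: numeric vector with attributes `architecture` and
#'   `l`.
#' @export
fuse_architecture1 <- function(pA, pD, pL) {
  l <- length(pA)
  if (length(pD) != l || length(pL) != l) {
    stop("pA, pD, pL must have equal length (one probability per class)")
  }
  .check_prob_blocks(c(pA, pD, pL), l)
  structure(c(pA, pD, pL), architecture = 1L, l = l, class = "FusedVector")
}

#' @rdname fuse_architecture1
#' @param per_channel_probs list of length-l probability vectors, ordered
#'   (XA channels, XD channels, XL channels).
#' @param channel_counts channels per map; the default `c(23, 8, 25)`
#'   matches the XA/XD/XL tensor depths.
#' @export
fuse_architecture2 <- function(per_channel_probs,
                               channel_counts = c(m = 23L, hD = 8L, hL = 25L)) {
  n_ch <- sum(channel_counts)
  if (length(per_channel_probs) != n_ch) {
    stop(sprintf("expected %d per-channel probability vectors, got %d",
                 n_ch, length(per_channel_probs)))
  }
  l <- length(per_channel_probs[[1]])
  if (!all(lengths(per_channel_probs) == l)) {
    stop("all per-channel probability vectors must have equal length")
  }
  v <- unlist(per_channel_probs, use.names = FALSE)
  .check_prob_blocks(v, l)
  structure(v, architecture = 2L, l = l, class = "FusedVector")
}

.check_prob_blocks <- function(v, l) {
  if (any(v < -1e-9) || any(v > 1 + 1e-9)) {
    stop("probabilities must lie in [0, 1]")
  }
  sums <- colSums(matrix(v, nrow = l))
  if (any(abs(sums - 1) > 1e-6)) {
    stop("each length-l block must sum to 1 (softmax output expected)")
  }
  invisible(v)
}

#' Correlation distance between two fused vectors
#'
#' `1 - Pearson correlation(u, v)`, in \[0, 2\]; invariant to positive affine
#' rescaling of either argument.  If either vector is constant the
#' correlation is undefined and the distance falls back to 1 (the
#' uncorrelated convention).
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return non-negative scalar.
#' @export
correlation_distance <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("length mismatch")
  if (length(u) < 2L) stop("vectors must have length >= 2")
  su <- stats::sd(u); sv <- stats::sd(v)
  if (su == 0 || sv == 0) return(1)
  1 - stats::cor(u, v)
}

#' k-nearest-neighbour classifier with correlation distance
#'
#' The model is transparent: the stored training vectors, their labels and
#' k.  Prediction takes the k training vectors nearest to the query under
#' [correlation_distance()]; the label is the majority vote, with ties
#' broken by the smallest summed distance and then by the lowest class
#' index.  The per-class decision score (used for ROC curves) is the
#' inverse-distance-weighted vote share of each class among the k
#' neighbours.
#'
#' @param x numeric matrix, one training vector per row (e.g. fused
#'   vectors), or a list of `FusedVector`s.
#' @param labels integer class labels, 1..n_classes.
#' @param k number of neighbours (default 12).
#' @param n_classes number of classes scored (default `max(labels)`).
#' @return a `knn_model`.
#' @export
knn_fit <- function(x, labels, k = 12L, n_classes = max(labels)) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels), nrow(x) >= 1)
  if (k < 1L || k > nrow(x)) {
    stop(sprintf("k = %d must be in 1..%d (training-set size)", k, nrow(x)))
  }
  structure(list(x = x, labels = labels, k = as.integer(k),
                 n_classes = as.integer(n_classes)),
            class = "knn_model")
}

#' @rdname knn_fit
#' @param model a `knn_model`.
#' @param query numeric matrix of query vectors (rows), a single vector, or
#'   a list of `FusedVector`s.
#' @return `knn_predict`: list with `labels` (integer vector) and `scores`
#'   (n x n_classes matrix of inverse-distance-weighted vote shares).
#' @export
knn_predict <- function(model, query) {
  stopifnot(inherits(model, "knn_model"))
  if (is.list(query)) query <- do.call(rbind, lapply(query, as.numeric))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  if (ncol(query) != ncol(model$x)) stop("query length mismatch")
  n <- nrow(query)
  labels <- integer(n)
  scores <- matrix(0, n, model$n_classes)
  for (q in seq_len(n)) {
    d <- apply(model$x, 1, correlation_distance, v = query[q, ])
    nb <- order(d)[seq_len(model$k)]
    dl <- model$labels[nb]; dd <- d[nb]
    votes <- tabulate(dl, nbins = model$n_classes)
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      dsum <- vapply(top, function(cl) sum(dd[dl == cl]), numeric(1))
      top <- top[dsum == min(dsum)]
    }
    labels[q] <- min(top)
    w <- 1 / (dd + 1e-8)
    scores[q, ] <- vapply(seq_len(model$n_classes),
                          function(cl) sum(w[dl == cl]), numeric(1)) / sum(w)
  }
  list(labels = labels, scores = scores)
}
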