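#' Mutation-histogram specification
#'
#' PSI-BLAST log-odds scores fall in \[-12, 13\]; 25 unit-width bins cover
#' this range exactly, and each histogram is smoothed with a 1D Gaussian
#' kernel of sigma 0.5 bins.
#'
#' @param vmin,vmax score range covered by the histogram.
#' @param nbins number of equal bins; `(vmax - vmin) / nbins` must be 1.
#' @param sigma Gaussian smoothing bandwidth, in bins.
#' @return list with the four fields, class `MutationHistogramSpec`.
#' @export
mutation_histogram_spec <- function(vmin = -12, vmax = 13, nbins = 25L,
                                    sigma = 0.5) {
  stopifnot((vmax - vmin) / nbins == 1, sigma > 0)
  structure(list(vmin = vmin, vmax = vmax, nbins = as.integer(nbins),
                 sigma = sigma),
            class = "MutationHistogramSpec")
}

#' Build a PSSM from an alignment profile and a mutation matrix
#'
#' Computes `scores[i, j] = sum_k gamma[i, k] * w[k, j]`: the expected
#' mutability of position i toward residue type j, given the observed
#' residue-type frequencies `gamma` (L x 20, rows of a probe alignment
#' profile) and a Dayhoff-style substitution-rate matrix `w` (20 x 20).
#' Routine use parses PSI-BLAST output instead ([read_pssm()]); this
#' constructor exists for profiles that come from a custom alignment.
#'
#' @param gamma L x 20 matrix of per-position residue frequencies in \[0, 1\];
#'   rows sum to at most 1 (gaps allowed).
#' @param w 20 x 20 mutation-rate matrix in [standard20()] order.
#' @param sequence optional length-L residue vector for the resulting
#'   profile; defaults to the per-row argmax of `gamma`.
#' @return a `PSSMProfile`.
#' @export
compute_pssm_from_msa <- function(gamma, w, sequence = NULL) {
  gamma <- as.matrix(gamma); w <- as.matrix(w)
  if (ncol(gamma) != 20L || !identical(dim(w), c(20L, 20L))) {
    stop("shape mismatch: gamma must be L x 20 and w 20 x 20")
  }
  if (!all(is.finite(gamma)) || !all(is.finite(w))) {
    stop("non-finite values in gamma or w")
  }
  scores <- gamma %*% w
  colnames(scores) <- standard20()
  if (is.null(sequence)) {
    sequence <- aa_one_letter(standard20()[max.col(gamma, ties.method = "first")])
  }
  structure(list(sequence = sequence, scores = scores), class = "PSSMProfile")
}

#' Read a whitespace-delimited 20 x 20 mutation-rate matrix
#'
#' @param path text file with 20 rows of 20 numbers, rows/columns in
#'   [standard20()] order.
#' @return 20 x 20 numeric matrix.
#' @export
read_mutation_matrix <- function(path) {
  w <- as.matrix(utils::read.table(path, header = FALSE))
  if (!identical(dim(w), c(20L, 20L)) || !all(is.finite(w))) {
    stop("mutation matrix must be a finite 20 x 20 table")
  }
  dimnames(w) <- list(standard20(), standard20())
  w
}

#' Group PSSM rows by the residue type at each position
#'
#' Splits the L x 20 score matrix into per-type blocks `Y_n`: the rows of
#' the PSSM at positions carrying residue type n, original order preserved.
#' Positions with a nonstandard residue code are skipped with a warning
#' (the PSSM is strictly over the 20 native amino acids).
#'
#' @param pssm a `PSSMProfile`.
#' @return named list over occurring standard types; each element a
#'   count_n x 20 matrix.
#' @export
group_rows_by_residue_type <- function(pssm) {
  stopifnot(inherits(pssm, "PSSMProfile"))
  res3 <- aa_three_letter(pssm$sequence)
  std <- res3 %in% standard20()
  if (any(!std)) {
    warning(sprintf("%d position(s) with nonstandard residue codes skipped",
                    sum(!std)))
  }
  out <- list()
  for (n in unique(res3[std])) {
    out[[n]] <- pssm$scores[res3 == n & std, , drop = FALSE]
  }
  out
}

# bin index for score v on [vmin, vmax], unit bins, ends clipped, last closed
.score_bin <- function(v, spec) {
  pmin(pmax(floor(v - spec$vmin) + 1, 1), spec$nbins)
}

#' Per-column score histograms of a PSSM block
#'
#' Row j of the result is the `nbins`-bin histogram of column j of `Y` over
#' \[vmin, vmax\] (unit bins, left-closed, last bin closed, out-of-range
#' values clipped into the end bins), normalized to probability mass 1 when
#' `Y` has rows; an empty block gives a zero matrix.
#'
#' @param Y count_n x 20 matrix (one residue type's PSSM rows).
#' @param spec a [mutation_histogram_spec()].
#' @return 20 x nbins matrix.
#' @export
mutation_histogram <- function(Y, spec = mutation_histogram_spec()) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 20L) stop("Y must have 20 columns")
  H <- matrix(0, 20L, spec$nbins)
  if (nrow(Y) == 0L) return(H)
  for (j in 1:20) {
    H[j, ] <- tabulate(.score_bin(Y[, j], spec), nbins = spec$nbins) / nrow(Y)
  }
  H
}

# discrete Gaussian kernel on offsets -2..2 bins, renormalized to sum 1
.gauss_kernel <- function(sigma, half_width = 2L) {
  if (sigma <= 0) stop("sigma must be positive")
  k <- stats::dnorm(seq(-half_width, half_width), sd = sigma)
  k / sum(k)
}

#' Smooth a histogram with a 1D Gaussian kernel
#'
#' Convolution with a discrete Gaussian (default sigma 0.5 bins, truncated
#' at +/- 2 bins and renormalized) under symmetric boundary padding, which
#' conserves total mass exactly for a symmetric kernel.
#'
#' @param h non-negative histogram vector.
#' @param sigma kernel bandwidth in bins.
#' @return smoothed vector, same length and same sum as `h`.
#' @export
smooth_histogram_1d <- function(h, sigma = 0.5) {
  stopifnot(is.numeric(h), all(is.finite(h)), all(h >= 0))
  k <- .gauss_kernel(sigma)
  hw <- (length(k) - 1L) %/% 2L
  n <- length(h)
  if (n == 1L) return(h)
  pad_l <- h[pmin(hw:1, n)]
  pad_r <- h[pmax(n - seq_len(hw) + 1L, 1L)]
  hp <- c(pad_l, h, pad_r)
  out <- numeric(n)
  for (t in seq_along(k)) out <- out + k[t] * hp[(t - 1L) + seq_len(n)]
  out
}

#' Assemble the mutation feature map XL
#'
#' For every ordered pair (source type n, target type j), `XL[n, j, ]` is
#' the smoothed, mass-1 histogram of the PSSM scores toward type j at the
#' positions carrying type n.  Source types absent from the sequence give
#' all-zero slices, so the output shape is (20, 20, 25) regardless of
#' sequence length -- the point of the histogram standardization.
#'
#' @param pssm a `PSSMProfile`.
#' @param spec a [mutation_histogram_spec()].
#' @return `FeatureMapXL`: numeric array (20, 20, 25), axis order
#'   (source type, target type, bin).
#' @export
build_xl <- function(pssm, spec = mutation_histogram_spec()) {
  groups <- group_rows_by_residue_type(pssm)
  s20 <- standard20()
  xl <- array(0, dim = c(20L, 20L, spec$nbins),
              dimnames = list(s20, s20, NULL))
  for (n in names(groups)) {
    H <- mutation_histogram(groups[[n]], spec)
    for (j in 1:20) xl[n, j, ] <- smooth_histogram_1d(H[j, ], spec$sigma)
  }
  xl
}
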