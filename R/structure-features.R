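#' Histogram specifications for the structural feature maps
#'
#' The torsion-angle map uses 19 equal bins per axis on \[-180, 180\] degrees;
#' the Calpha-distance map uses 8 equal bins on \[5, 40\] Angstroms (bin width
#' 4.375 A).  Both are smoothed with a Gaussian kernel; the bandwidth is not
#' fixed by the underlying method description, so it defaults to 0.5 bins in
#' parallel with the mutation map.
#'
#' @param nbins bins per angle axis (19) / distance bins (8).
#' @param sigma Gaussian smoothing bandwidth in bins.
#' @param range distance range covered, in Angstroms.
#' @return spec list of class `AngleHistogramSpec` / `DistanceHistogramSpec`.
#' @export
angle_histogram_spec <- function(nbins = 19L, sigma = 0.5) {
  stopifnot(nbins >= 2, sigma > 0)
  structure(list(nbins = as.integer(nbins), width = 360 / nbins,
                 sigma = sigma),
            class = "AngleHistogramSpec")
}

#' @rdname angle_histogram_spec
#' @export
distance_histogram_spec <- function(range = c(5, 40), nbins = 8L,
                                    sigma = 0.5) {
  stopifnot(length(range) == 2, range[2] > range[1], nbins >= 2, sigma > 0)
  structure(list(dmin = range[1], dmax = range[2], nbins = as.integer(nbins),
                 width = diff(range) / nbins, sigma = sigma),
            class = "DistanceHistogramSpec")
}

# signed dihedral (degrees, [-180, 180)) of the p1-p2-p3-p4 chain, atan2 form
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(b2 / sqrt(sum(b2^2)), n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  ang
}

#' Backbone torsion angles phi/psi
#'
#' Signed dihedrals by the standard IUPAC convention, in degrees on
#' \[-180, 180): `phi[i]` from atoms C(i-1), N(i), CA(i), C(i) and `psi[i]`
#' from N(i), CA(i), C(i), N(i+1).  An angle is `NA` (never zero-filled)
#' whenever any defining atom is absent; the first residue has no phi, the
#' last no psi.
#'
#' @param structure a `ProteinStructure`.
#' @return `TorsionAngles`: list with numeric vectors `phi` and `psi` of
#'   length L.
#' @export
compute_torsion_angles <- function(structure) {
  stopifnot(inherits(structure, "ProteinStructure"))
  L <- length(structure$residue)
  phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
  ok <- function(m, i) i >= 1 && i <= L && all(is.finite(m[i, ]))
  for (i in seq_len(L)) {
    if (i > 1 && ok(structure$c, i - 1) && ok(structure$n, i) &&
        ok(structure$ca, i) && ok(structure$c, i)) {
      phi[i] <- .dihedral(structure$c[i - 1, ], structure$n[i, ],
                          structure$ca[i, ], structure$c[i, ])
    }
    if (i < L && ok(structure$n, i) && ok(structure$ca, i) &&
        ok(structure$c, i) && ok(structure$n, i + 1)) {
      psi[i] <- .dihedral(structure$n[i, ], structure$ca[i, ],
                          structure$c[i, ], structure$n[i + 1, ])
    }
  }
  structure(list(phi = phi, psi = psi), class = "TorsionAngles")
}

# angle bin on [-180, 180]: 19 equal bins, left-closed, +180 into last bin
.angle_bin <- function(a, spec) {
  pmin(pmax(floor((a + 180) / spec$width) + 1, 1), spec$nbins)
}

#' Assemble the torsion-angle feature map XA
#'
#' Each residue with both phi and psi defined adds one count to the
#' (phi-bin, psi-bin) cell of the channel of its residue type (extended
#' 23-letter alphabet: 20 standard + ASX + GLX + OTHER).  Channels are then
#' normalized to probability mass 1 and smoothed with a separable 2D
#' Gaussian under symmetric padding, which conserves each channel's mass
#' exactly; channels whose type does not occur stay all-zero.
#'
#' @param structure a `ProteinStructure`.
#' @param torsions optional precomputed [compute_torsion_angles()] result.
#' @param spec an [angle_histogram_spec()].
#' @param smooth set `FALSE` to return the raw normalized histogram.
#' @return `FeatureMapXA`: numeric array (19, 19, 23), axes (phi bin,
#'   psi bin, residue-type channel).
#' @export
build_xa <- function(structure, torsions = compute_torsion_angles(structure),
                     spec = angle_histogram_spec(), smooth = TRUE) {
  xa <- array(0, dim = c(spec$nbins, spec$nbins, 23L),
              dimnames = list(NULL, NULL, extended23()))
  def <- which(!is.na(torsions$phi) & !is.na(torsions$psi))
  if (length(def)) {
    ch <- map_to_extended23(structure$residue[def])
    pb <- .angle_bin(torsions$phi[def], spec)
    sb <- .angle_bin(torsions$psi[def], spec)
    for (r in seq_along(def)) {
      xa[pb[r], sb[r], ch[r]] <- xa[pb[r], sb[r], ch[r]] + 1
    }
    for (m in unique(ch)) {
      sl <- xa[, , m] / sum(xa[, , m])
      if (smooth) sl <- .smooth_2d(sl, spec$sigma)
      xa[, , m] <- sl
    }
  }
  xa
}

# separable 2D Gaussian smoothing (rows then columns), symmetric padding
.smooth_2d <- function(mat, sigma) {
  for (i in seq_len(nrow(mat))) mat[i, ] <- smooth_histogram_1d(mat[i, ], sigma)
  for (j in seq_len(ncol(mat))) mat[, j] <- smooth_histogram_1d(mat[, j], sigma)
  mat
}

#' Pairwise Calpha distances
#'
#' Euclidean distances between the CA atoms of all unordered residue pairs
#' i < j (both CAs present), one record per pair.
#'
#' @param structure a `ProteinStructure`.
#' @param min_separation minimum sequence separation |i - j| strictly above
#'   which pairs are kept; 0 (default) keeps sequence-adjacent pairs.
#' @return data frame with columns `i`, `j`, `type_i`, `type_j`, `d`
#'   (Angstroms); zero rows when fewer than two CAs exist.
#' @export
pairwise_ca_distances <- function(structure, min_separation = 0L) {
  stopifnot(inherits(structure, "ProteinStructure"))
  has_ca <- which(apply(is.finite(structure$ca), 1, all))
  if (length(has_ca) < 2L) {
    return(data.frame(i = integer(0), j = integer(0),
                      type_i = character(0), type_j = character(0),
                      d = numeric(0)))
  }
  D <- as.matrix(stats::dist(structure$ca[has_ca, , drop = FALSE]))
  pr <- which(upper.tri(D), arr.ind = TRUE)
  i <- has_ca[pr[, 1]]; j <- has_ca[pr[, 2]]
  keep <- abs(i - j) > min_separation
  data.frame(i = i[keep], j = j[keep],
             type_i = structure$residue[i[keep]],
             type_j = structure$residue[j[keep]],
             d = D[pr][keep])
}

#' Assemble the Calpha-distance feature map XD
#'
#' Every pair contributes one count to each of the ordered type-channel
#' cells (type_i, type_j) and (type_j, type_i) of the 8-bin histogram over
#' \[5, 40\] A (distances above 40 A are clipped into the last bin; below 5 A
#' discarded).  Non-empty (i, j) slices are normalized to mass 1 and
#' smoothed along the bin axis; the construction makes `XD[i, j, ] ==
#' XD[j, i, ]` exact.
#'
#' @param pairs data frame from [pairwise_ca_distances()].
#' @param spec a [distance_histogram_spec()].
#' @param smooth set `FALSE` to return the raw normalized histogram.
#' @return `FeatureMapXD`: numeric array (23, 23, 8), axes (type channel,
#'   type channel, distance bin).
#' @export
build_xd <- function(pairs, spec = distance_histogram_spec(), smooth = TRUE) {
  xd <- array(0, dim = c(23L, 23L, spec$nbins),
              dimnames = list(extended23(), extended23(), NULL))
  keep <- pairs$d >= spec$dmin
  if (any(keep)) {
    ci <- map_to_extended23(pairs$type_i[keep])
    cj <- map_to_extended23(pairs$type_j[keep])
    bin <- pmin(floor((pairs$d[keep] - spec$dmin) / spec$width) + 1,
                spec$nbins)
    for (r in seq_along(bin)) {
      xd[ci[r], cj[r], bin[r]] <- xd[ci[r], cj[r], bin[r]] + 1
      xd[cj[r], ci[r], bin[r]] <- xd[cj[r], ci[r], bin[r]] + 1
    }
    for (a in 1:23) for (b in a:23) {
      s <- sum(xd[a, b, ])
      if (s > 0) {
        sl <- xd[a, b, ] / s
        if (smooth) sl <- smooth_histogram_1d(sl, spec$sigma)
        xd[a, b, ] <- sl
        xd[b, a, ] <- sl
      }
    }
  }
  xd
}
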