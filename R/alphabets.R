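#' Residue alphabets
#'
#' Fixed, documented residue orderings that define the axes of every feature
#' tensor produced by the package.
#'
#' `standard20` is the 20 proteinogenic amino acids as three-letter codes,
#' sorted alphabetically (ALA, ARG, ..., VAL).  Sorting three-letter codes
#' alphabetically yields the one-letter order A R N D C Q E G H I L K M F P S
#' T W Y V, which is exactly the column order PSI-BLAST uses in its ASCII
#' PSSM output, so PSSM columns map onto `standard20` without reordering.
#'
#' `extended23` appends three extra channels used by the structural feature
#' maps: the ambiguity codes ASX (Asp/Asn) and GLX (Glu/Gln) and a terminal
#' OTHER catch-all for any nonstandard or chemically modified residue
#' (e.g. ASE, THP, UNK, MSE).
#'
#' @return Character vector of residue codes, in fixed tensor-axis order.
#' @examples
#' standard20()[1]   # "ALA"
#' length(extended23())
#' @export
standard20 <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' @rdname standard20
#' @export
extended23 <- function() {
  c(standard20(), "ASX", "GLX", "OTHER")
}

# one-letter <-> three-letter, in standard20 order
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Convert between one- and three-letter residue codes
#'
#' Unknown letters map to "UNK"; unknown three-letter codes map to "X".
#'
#' @param x character vector of residue codes.
#' @return character vector of the same length.
#' @export
aa_three_letter <- function(x) {
  idx <- match(toupper(x), .aa1)
  out <- standard20()[idx]
  out[is.na(idx)] <- "UNK"
  out
}

#' @rdname aa_three_letter
#' @export
aa_one_letter <- function(x) {
  idx <- match(toupper(x), standard20())
  out <- .aa1[idx]
  out[is.na(idx)] <- "X"
  out
}

#' Map a residue code to its channel in the extended 23-type alphabet
#'
#' The mapping is total: the 20 standard three-letter codes map to their
#' alphabetical channel (1-20), ASX to 21, GLX to 22, and every other
#' code -- modified residues such as ASE or THP, UNK, anything else -- to the
#' OTHER channel 23.  One-letter codes are accepted and converted first.
#'
#' @param code character vector of residue codes (three-letter preferred).
#' @return integer vector of channel indices in 1..23.
#' @examples
#' map_to_extended23("ALA")  # 1
#' map_to_extended23("THP")  # 23 (OTHER)
#' @export
map_to_extended23 <- function(code) {
  stopifnot(is.character(code), all(nzchar(code)))
  code <- toupper(code)
  one <- nchar(code) == 1L
  code[one] <- aa_three_letter(code[one])
  idx <- match(code, extended23())
  idx[is.na(idx)] <- 23L
  idx
}
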