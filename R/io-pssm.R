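#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the classic `-out_ascii_pssm` layout: two header lines, a column
#' header with 40 residue letters, then one row per sequence position holding
#' the position index, the query residue, 20 log-odds scores and 20 weighted
#' observed percentages (plus trailing information-content columns).  Only
#' the first 20 (log-odds) columns are kept; the query sequence is read from
#' the residue column.
#'
#' @param path path to the PSSM file.
#' @return A `PSSMProfile`: list with `sequence` (one-letter character
#'   vector, length L) and `scores` (L x 20 numeric matrix, columns in
#'   [standard20()] order, i.e. PSI-BLAST column order).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # data rows: "<pos> <res> <>=20 numeric fields>"
  cand <- grep("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines)
  if (length(cand) == 0L) stop("no PSSM rows found in ", path, " (truncated?)")
  pos <- integer(0); seq <- character(0); rows <- list()
  for (ln in cand) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    sc <- suppressWarnings(as.numeric(f[-(1:2)]))
    sc <- sc[!is.na(sc)]
    if (length(sc) < 20L) {
      stop(sprintf("PSSM row at line %d of %s has %d parsable score fields (need >= 20)",
                   ln, path, length(sc)))
    }
    pos <- c(pos, as.integer(f[1]))
    seq <- c(seq, toupper(f[2]))
    rows[[length(rows) + 1L]] <- sc[1:20]
  }
  if (any(diff(pos) <= 0)) stop("non-monotone position index in ", path)
  scores <- do.call(rbind, rows)
  colnames(scores) <- standard20()
  structure(list(sequence = seq, scores = scores), class = "PSSMProfile")
}

#' @export
print.PSSMProfile <- function(x, ...) {
  cat(sprintf("PSSMProfile: L = %d, scores in [%g, %g]\n",
              length(x$sequence), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Inverse of [read_pssm()]: emits the header, the 40-letter column line, one
#' row per position (log-odds then a dummy weighted-percentage block), and
#' the trailing K/lambda lines, matching the classic PSI-BLAST layout
#' closely enough that [read_pssm()] round-trips it exactly.
#'
#' @param pssm a `PSSMProfile` (integer-valued scores recommended).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "PSSMProfile"))
  aa <- aa_one_letter(standard20())
  hdr <- c("",
           "Last position-specific scoring matrix computed, weight ratio 1.0",
           paste0("           ", paste(sprintf("%3s", aa), collapse = " "),
                  "  ", paste(sprintf("%3s", aa), collapse = " ")))
  body <- vapply(seq_along(pssm$sequence), function(i) {
    paste0(sprintf("%5d %s  ", i, pssm$sequence[i]),
           paste(sprintf("%3d", as.integer(round(pssm$scores[i, ]))),
                 collapse = " "),
           "  ",
           paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
           sprintf("  %4.2f %4.2f", 0, 0))
  }, character(1))
  tail <- c("", "                      K         Lambda",
            "Standard Ungapped    0.1357     0.3175")
  writeLines(c(hdr, body, tail), path)
  invisible(path)
}
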