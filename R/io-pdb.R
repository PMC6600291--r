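#' Read a backbone structure from a PDB file
#'
#' Parses ATOM records (fixed columns) and collects the backbone atoms N, CA
#' and C for each residue, in file order.  Residues missing any backbone atom
#' are retained with `NA` coordinates for that atom; a missing CA raises a
#' warning because distance features skip such residues.  Nonstandard residue
#' names are preserved verbatim.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` (default) keeps only the first MODEL of a
#'   multi-model (e.g. NMR) file; `"all"` concatenates all models.
#' @param chain_policy `"all"` (default) concatenates chains in file order;
#'   otherwise a character vector of chain identifiers to keep.
#' @param ec_label optional integer EC class 1-6 to attach.
#' @param id structure identifier; defaults to the file name.
#' @return A `ProteinStructure`: list with `id`, `residue` (character vector
#'   of residue names), coordinate matrices `n`, `ca`, `c` (L x 3, Angstroms,
#'   `NA` rows where the atom is absent), `chain`, `resseq` and `ec_label`.
#' @export
read_pdb <- function(path, model_policy = c("first", "all"),
                     chain_policy = "all", ec_label = NULL,
                     id = sub("\\.pdb$", "", basename(path))) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  rec <- substr(lines, 1, 6)
  in_model <- 1L
  keep <- logical(length(lines))
  model_of <- integer(length(lines))
  m <- 1L
  for (i in seq_along(lines)) {
    if (rec[i] == "MODEL ") m <- m  # model number taken from ENDMDL count below
    if (rec[i] == "ENDMDL") m <- m + 1L
    model_of[i] <- m
    keep[i] <- rec[i] == "ATOM  "
  }
  if (model_policy == "first") keep <- keep & model_of == 1L
  idx <- which(keep)
  if (length(idx) == 0L) stop("no ATOM records in ", path)

  atom_name <- trimws(substr(lines[idx], 13, 16))
  alt_loc   <- substr(lines[idx], 17, 17)
  res_name  <- trimws(substr(lines[idx], 18, 20))
  chain     <- substr(lines[idx], 22, 22)
  res_seq   <- trimws(substr(lines[idx], 23, 27))  # resSeq + insertion code

  sel <- atom_name %in% c("N", "CA", "C") & alt_loc %in% c(" ", "A")
  if (!identical(chain_policy, "all")) sel <- sel & chain %in% chain_policy
  idx <- idx[sel]
  if (length(idx) == 0L) stop("no backbone ATOM records selected in ", path)
  atom_name <- atom_name[sel]; res_name <- res_name[sel]
  chain <- chain[sel]; res_seq <- res_seq[sel]

  coord <- function(from, to) {
    v <- suppressWarnings(as.numeric(substr(lines[idx], from, to)))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("unparseable coordinate field at line %d of %s",
                   idx[bad[1]], path))
    }
    v
  }
  x <- coord(31, 38); y <- coord(39, 46); z <- coord(47, 54)

  # group atoms into residues by (chain, resSeq+icode), file order
  res_key <- paste(chain, res_seq, sep = "|")
  res_key <- factor(res_key, levels = unique(res_key))
  L <- nlevels(res_key)
  mk <- function() matrix(NA_real_, L, 3, dimnames = list(NULL, c("x", "y", "z")))
  nm <- mk(); cam <- mk(); cm <- mk()
  residue <- character(L); chains <- character(L); resseq <- character(L)
  gi <- as.integer(res_key)
  for (a in seq_along(idx)) {
    r <- gi[a]
    residue[r] <- res_name[a]; chains[r] <- chain[a]; resseq[r] <- res_seq[a]
    p <- c(x[a], y[a], z[a])
    if (atom_name[a] == "N" && is.na(nm[r, 1])) nm[r, ] <- p
    if (atom_name[a] == "CA" && is.na(cam[r, 1])) cam[r, ] <- p
    if (atom_name[a] == "C" && is.na(cm[r, 1])) cm[r, ] <- p
  }
  n_missing_ca <- sum(is.na(cam[, 1]))
  if (n_missing_ca > 0) {
    warning(sprintf("%d residue(s) without a CA atom in %s", n_missing_ca, id))
  }

  structure(
    list(id = id, residue = residue, n = nm, ca = cam, c = cm,
         chain = chains, resseq = resseq, ec_label = ec_label),
    class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat(sprintf("ProteinStructure '%s': %d residues, %d with CA%s\n",
              x$id, length(x$residue), sum(!is.na(x$ca[, 1])),
              if (is.null(x$ec_label)) "" else
                sprintf(", EC class %d", x$ec_label)))
  invisible(x)
}

#' Write a backbone structure to a PDB file
#'
#' Emits ATOM records (N, CA, C per residue) in fixed PDB columns with
#' `%8.3f` coordinate formatting, ending with TER/END.  Atoms with `NA`
#' coordinates are skipped.
#'
#' @param structure a `ProteinStructure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "ProteinStructure"))
  L <- length(structure$residue)
  lines <- character(0)
  serial <- 0L
  element <- c(N = "N", CA = "C", C = "C")
  for (i in seq_len(L)) {
    for (an in c("N", "CA", "C")) {
      p <- switch(an, N = structure$n[i, ], CA = structure$ca[i, ],
                  C = structure$c[i, ])
      if (any(is.na(p))) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, an, structure$residue[i], i, p[1], p[2], p[3], element[[an]]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
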