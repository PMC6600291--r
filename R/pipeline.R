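#' Extract all three feature maps for every protein in a manifest
#'
#' Reads each PDB and PSSM file and builds the angle map XA (19x19x23), the
#' distance map XD (23x23x8) and the mutation map XL (20x20x25).
#'
#' @param manifest a `DatasetManifest` from [read_manifest()] or
#'   [generate_dataset()].
#' @param quiet suppress per-protein warnings about nonstandard residues
#'   (they are expected whenever modified residues are present).
#' @return named list `id -> list(XA, XD, XL, label)`, suitable for
#'   [save_features()].
#' @export
extract_features <- function(manifest, quiet = TRUE) {
  validate_manifest(manifest)
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$id
  for (r in seq_len(nrow(manifest))) {
    st <- read_pdb(manifest$pdb[r], ec_label = manifest$ec[r],
                   id = manifest$id[r])
    ps <- read_pssm(manifest$pssm[r])
    xl <- if (quiet) suppressWarnings(build_xl(ps)) else build_xl(ps)
    out[[r]] <- list(XA = build_xa(st),
                     XD = build_xd(pairwise_ca_distances(st)),
                     XL = xl,
                     label = manifest$ec[r])
  }
  out
}

.maps_of <- function(features, ids, map) lapply(features[ids], `[[`, map)
.labels_of <- function(features, ids) {
  vapply(features[ids], `[[`, numeric(1), "label")
}

# split a 3D map into single-channel (H, W, 1) arrays along dim 3
.split_channels <- function(x) {
  lapply(seq_len(dim(x)[3]), function(ch) {
    array(x[, , ch], dim = c(dim(x)[1], dim(x)[2], 1L))
  })
}

#' Run the full fusion experiment on an extracted feature set
#'
#' Trains the CNN streams on the training partition, fuses the resulting
#' class probabilities (whole-map fusion for Architecture 1: one CNN per
#' map, fused length 3l; per-channel fusion for Architecture 2: one CNN per
#' channel, fused length 56l), fits the correlation-distance KNN on the
#' fused training vectors, and evaluates on the test partition.
#'
#' @param features named feature list from [extract_features()] or
#'   [load_features()].
#' @param split list with `train`/`test` ids or indices
#'   ([split_dataset()]); ids must name entries of `features`.
#' @param architecture 1 (whole-map) or 2 (per-channel).
#' @param config a [cnn_config()]; `config$seed` drives every CNN.
#' @param k KNN neighbour count (default 12).
#' @param verbose print per-stream progress.
#' @return list with `prediction` (labels + scores on the test set),
#'   `truth`, `accuracy`, `confusion` ([confusion_matrix_percent()]), `roc`
#'   ([roc_auc_per_class()]), `histories` (per-stream `TrainingHistory`)
#'   and `fused` (train/test fused-vector matrices).
#' @export
run_experiment <- function(features, split, architecture = 1L,
                           config = cnn_config("desk"), k = 12L,
                           verbose = FALSE) {
  stopifnot(architecture %in% c(1L, 2L))
  tr_ids <- split$train; te_ids <- split$test
  if (is.numeric(tr_ids)) { tr_ids <- names(features)[tr_ids] }
  if (is.numeric(te_ids)) { te_ids <- names(features)[te_ids] }
  y_tr <- .labels_of(features, tr_ids)
  y_te <- .labels_of(features, te_ids)
  l <- config$n_classes

  train_stream <- function(x_tr, x_te, seed_shift, tag) {
    cfg <- config; cfg$seed <- config$seed + seed_shift
    model <- build_cnn(dim(x_tr[[1]]), cfg)
    if (verbose) message("training stream ", tag, " ...")
    fit <- train_cnn(model, x_tr, y_tr)
    list(p_tr = predict_proba(fit$model, x_tr),
         p_te = predict_proba(fit$model, x_te),
         history = fit$history)
  }

  histories <- list()
  if (architecture == 1L) {
    streams <- list()
    for (map in c("XA", "XD", "XL")) {
      s <- train_stream(.maps_of(features, tr_ids, map),
                        .maps_of(features, te_ids, map),
                        seed_shift = match(map, c("XA", "XD", "XL")), map)
      streams[[map]] <- s
      histories[[map]] <- s$history
    }
    fuse_rows <- function(field) {
      t(vapply(seq_len(nrow(streams$XA[[field]])), function(i) {
        fuse_architecture1(streams$XA[[field]][i, ],
                           streams$XD[[field]][i, ],
                           streams$XL[[field]][i, ])
      }, numeric(3 * l)))
    }
    fused_tr <- fuse_rows("p_tr")
    fused_te <- fuse_rows("p_te")
  } else {
    depth <- c(XA = 23L, XD = 8L, XL = 25L)
    probs_tr <- list(); probs_te <- list()
    shift <- 0L
    for (map in c("XA", "XD", "XL")) {
      x_tr_full <- .maps_of(features, tr_ids, map)
      x_te_full <- .maps_of(features, te_ids, map)
      ch_tr <- lapply(x_tr_full, .split_channels)
      ch_te <- lapply(x_te_full, .split_channels)
      for (ch in seq_len(depth[[map]])) {
        shift <- shift + 1L
        s <- train_stream(lapply(ch_tr, `[[`, ch), lapply(ch_te, `[[`, ch),
                          seed_shift = shift, paste0(map, "/ch", ch))
        probs_tr[[shift]] <- s$p_tr
        probs_te[[shift]] <- s$p_te
        histories[[paste0(map, "_ch", ch)]] <- s$history
      }
    }
    fuse_channel_rows <- function(plist, n) {
      t(vapply(seq_len(n), function(i) {
        fuse_architecture2(lapply(plist, function(p) p[i, ]))
      }, numeric(56 * l)))
    }
    fused_tr <- fuse_channel_rows(probs_tr, length(tr_ids))
    fused_te <- fuse_channel_rows(probs_te, length(te_ids))
  }

  knn <- knn_fit(fused_tr, y_tr, k = k, n_classes = l)
  pred <- knn_predict(knn, fused_te)
  list(prediction = pred, truth = y_te,
       accuracy = overall_accuracy(y_te, pred$labels),
       confusion = confusion_matrix_percent(y_te, pred$labels, l),
       roc = roc_auc_per_class(pred$scores, y_te),
       histories = histories,
       fused = list(train = fused_tr, test = fused_te),
       knn = knn, architecture = architecture)
}
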