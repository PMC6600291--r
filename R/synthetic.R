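#' Simulation configuration for class-structured synthetic datasets
#'
#' Stands in for a PDB + PSI-BLAST corpus: each of up to six classes gets a
#' torsion regime (a mixture of canonical (phi, psi) conformations with
#' angular noise) and a PSSM conservation profile (per-residue-type mean
#' score vectors with integer noise), so the angle, distance and mutation
#' feature maps all carry class signal.
#'
#' Default regimes draw on the canonical Ramachandran basins -- alpha helix
#' (-57, -47), beta strand (-120, 130), polyproline II (-75, 150) and
#' left-handed helix (60, 45) -- combined so that the six classes are
#' geometrically distinct; angular noise defaults to sd 8 degrees, a
#' realistic within-basin spread.  Conservation profiles place class-
#' specific high-score targets (scores 9 and 5) on a rotating subset of
#' residue types over a -4 background, with integer noise of +/- 2 units,
#' all clipped into the PSI-BLAST range \[-12, 13\].
#'
#' @param n_classes number of classes (<= 6).
#' @param n_per_class proteins generated per class.
#' @param length_range residue-count range, sampled uniformly (min >= 5).
#' @param angle_noise_sd angular noise around the regime modes, degrees.
#' @param score_noise integer half-width of the uniform PSSM score noise.
#' @param nonstandard_fraction fraction of residues written with a
#'   nonstandard code (UNK); these exercise the OTHER channel.
#' @param seed integer seed; everything downstream derives from it.
#' @return list of class `SimulationConfig` (fields above plus `regimes`, a
#'   per-class list of mode matrices `(phi, psi, weight)`, and `profiles`,
#'   per-class 20 x 20 mean-score matrices).
#' @export
simulation_config <- function(n_classes = 6L, n_per_class = 10L,
                              length_range = c(120L, 200L),
                              angle_noise_sd = 8, score_noise = 2L,
                              nonstandard_fraction = 0.05, seed = 1L) {
  stopifnot(n_classes >= 1, n_classes <= 6, n_per_class >= 1,
            length_range[1] >= 5, length_range[2] >= length_range[1],
            angle_noise_sd >= 0, score_noise >= 0,
            nonstandard_fraction >= 0, nonstandard_fraction < 1)
  helix <- c(-57, -47); strand <- c(-120, 130)
  ppii <- c(-75, 150); lhelix <- c(60, 45)
  mode_mat <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("phi", "psi", "weight")
    stopifnot(abs(sum(m[, "weight"]) - 1) < 1e-9)
    m
  }
  regimes <- list(
    mode_mat(c(helix, 1)),
    mode_mat(c(strand, 1)),
    mode_mat(c(helix, 0.5), c(strand, 0.5)),
    mode_mat(c(ppii, 1)),
    mode_mat(c(lhelix, 1)),
    mode_mat(c(ppii, 0.5), c(lhelix, 0.5))
  )[seq_len(n_classes)]
  profiles <- lapply(seq_len(n_classes), function(cl) {
    pr <- matrix(-4, 20, 20, dimnames = list(standard20(), standard20()))
    for (t in 1:20) {
      pr[t, (t + 2 * cl - 1) %% 20 + 1] <- 9
      pr[t, (t + 2 * cl + 6) %% 20 + 1] <- 5
    }
    pr
  })
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 angle_noise_sd = angle_noise_sd,
                 score_noise = as.integer(score_noise),
                 nonstandard_fraction = nonstandard_fraction,
                 regimes = regimes, profiles = profiles,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# place atom D given chain A-B-C, bond |CD|, angle B-C-D (deg), dihedral
# A-B-C-D (deg): natural extension reference frame
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal backbone geometry (Angstroms / degrees)
.geom <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
              a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7)

#' Generate a synthetic backbone from a torsion regime
#'
#' Samples per-residue (phi, psi) from the regime's mode mixture plus
#' Gaussian angular noise, then builds N/CA/C coordinates by sequential
#' internal-coordinate (NeRF) placement with ideal bond geometry and
#' omega = 180 degrees.  The sampled torsions are attached as attribute
#' `torsions` for round-trip testing: [compute_torsion_angles()] on the
#' result recovers them to numerical precision.
#'
#' @param length number of residues (>= 2).
#' @param regime mode matrix with columns phi, psi, weight (degrees).
#' @param seed integer seed.
#' @param angle_noise_sd angular noise sd in degrees.
#' @param nonstandard_fraction fraction of residues coded UNK.
#' @param ec_label optional class label to attach.
#' @param id structure id.
#' @return a `ProteinStructure` with attribute `torsions` (list phi, psi).
#' @export
generate_structure <- function(length, regime, seed = 1L,
                               angle_noise_sd = 0,
                               nonstandard_fraction = 0,
                               ec_label = NULL, id = "synthetic") {
  stopifnot(length >= 2, is.matrix(regime), ncol(regime) == 3)
  if (is.null(colnames(regime))) colnames(regime) <- c("phi", "psi", "weight")
  withr::with_seed(as.integer(seed), {
    L <- as.integer(length)
    modes <- sample.int(nrow(regime), L, replace = TRUE,
                        prob = regime[, "weight"])
    wrap <- function(a) ((a + 180) %% 360) - 180
    phi <- wrap(regime[modes, "phi"] + stats::rnorm(L, sd = angle_noise_sd))
    psi <- wrap(regime[modes, "psi"] + stats::rnorm(L, sd = angle_noise_sd))
    phi[1] <- NA; psi[L] <- NA
    residue <- sample(standard20(), L, replace = TRUE)
    if (nonstandard_fraction > 0) {
      ns <- stats::runif(L) < nonstandard_fraction
      residue[ns] <- "UNK"
    }
    g <- .geom
    nm <- matrix(NA_real_, L, 3); cam <- nm; cm <- nm
    nm[1, ] <- c(0, 0, 0)
    cam[1, ] <- c(g$b_n_ca, 0, 0)
    a <- g$a_n_ca_c * pi / 180
    cm[1, ] <- cam[1, ] + g$b_ca_c * c(-cos(a), sin(a), 0)
    for (i in 2:L) {
      nm[i, ] <- .place_atom(nm[i - 1, ], cam[i - 1, ], cm[i - 1, ],
                             g$b_c_n, g$a_ca_c_n, psi[i - 1])
      cam[i, ] <- .place_atom(cam[i - 1, ], cm[i - 1, ], nm[i, ],
                              g$b_n_ca, g$a_c_n_ca, 180)
      cm[i, ] <- .place_atom(cm[i - 1, ], nm[i, ], cam[i, ],
                             g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    st <- structure(
      list(id = id, residue = residue, n = nm, ca = cam, c = cm,
           chain = rep("A", L), resseq = as.character(seq_len(L)),
           ec_label = ec_label),
      class = "ProteinStructure")
    attr(st, "torsions") <- list(phi = phi, psi = psi)
    st
  })
}

#' Generate a synthetic PSSM for a sequence
#'
#' Integer scores are the class conservation profile's mean for the
#' position's residue type, plus uniform integer noise, clipped into the
#' PSI-BLAST log-odds range \[-12, 13\].  Positions with nonstandard residues
#' draw from the background mean (-4).
#'
#' @param sequence residue codes (one- or three-letter).
#' @param profile 20 x 20 mean-score matrix (rows: position's residue type,
#'   columns: target type), rows/cols in [standard20()] order.
#' @param seed integer seed.
#' @param score_noise integer half-width of the uniform noise.
#' @return a `PSSMProfile` with integer-valued scores.
#' @export
generate_pssm <- function(sequence, profile, seed = 1L, score_noise = 2L) {
  stopifnot(identical(dim(as.matrix(profile)), c(20L, 20L)))
  withr::with_seed(as.integer(seed), {
    res3 <- sequence
    res3[nchar(res3) == 1L] <- aa_three_letter(res3[nchar(res3) == 1L])
    L <- length(res3)
    ti <- match(res3, standard20())
    scores <- matrix(0L, L, 20L)
    for (i in seq_len(L)) {
      mu <- if (is.na(ti[i])) rep(-4, 20) else profile[ti[i], ]
      noise <- if (score_noise > 0) {
        sample.int(2L * score_noise + 1L, 20L, replace = TRUE) - score_noise - 1L
      } else rep(0L, 20L)
      scores[i, ] <- pmin(pmax(as.integer(round(mu)) + noise, -12L), 13L)
    }
    storage.mode(scores) <- "double"
    colnames(scores) <- standard20()
    structure(list(sequence = aa_one_letter(res3), scores = scores),
              class = "PSSMProfile")
  })
}

#' Generate a labelled on-disk dataset
#'
#' Writes `n_classes * n_per_class` proteins as PDB + PSI-BLAST-dialect
#' PSSM files under `dir`, plus a `manifest.tsv` readable by
#' [read_manifest()].  Byte-identical for identical seeds.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if absent).
#' @return the `DatasetManifest` (paths resolved), invisibly the manifest
#'   path as attribute `path`.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  lens <- withr::with_seed(config$seed, {
    sample(config$length_range[1]:config$length_range[2],
           config$n_classes * config$n_per_class, replace = TRUE)
  })
  idx <- 0L
  for (cl in seq_len(config$n_classes)) {
    for (rep_i in seq_len(config$n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("sim_c%d_%03d", cl, rep_i)
      sub_seed <- (config$seed * 131L + idx * 7L) %% .Machine$integer.max
      st <- generate_structure(lens[idx], config$regimes[[cl]],
                               seed = sub_seed,
                               angle_noise_sd = config$angle_noise_sd,
                               nonstandard_fraction = config$nonstandard_fraction,
                               ec_label = cl, id = id)
      ps <- generate_pssm(st$residue, config$profiles[[cl]],
                          seed = sub_seed + 1L,
                          score_noise = config$score_noise)
      pdb <- file.path(dir, paste0(id, ".pdb"))
      pssm <- file.path(dir, paste0(id, ".pssm"))
      write_pdb(st, pdb)
      write_pssm(ps, pssm)
      rows[[idx]] <- data.frame(id = id, pdb = basename(pdb),
                                pssm = basename(pssm), ec = cl)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  write_manifest(manifest, path)
  read_manifest(path)
}
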