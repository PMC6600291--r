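# Shared fixture builders.  Everything is generated in code at test time;
# PDB fixtures are written with an independent formatter so parser tests do
# not lean on the package's own writer.

# one PDB ATOM line with standard fixed columns
pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z) {
  sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, name, resname, chain, resseq, x, y, z,
          substr(name, 1, 1))
}

# write a PDB from a data frame (name, resname, chain, resseq, x, y, z)
write_pdb_fixture <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    pdb_atom_line(i, df$name[i], df$resname[i], df$chain[i], df$resseq[i],
                  df$x[i], df$y[i], df$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# full-backbone residue rows at given coordinates (one residue per row set)
backbone_df <- function(resnames, coords, chain = "A", start = 1L) {
  n <- length(resnames)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(name = c("N", "CA", "C"), resname = resnames[i],
               chain = chain, resseq = start + i - 1L,
               x = coords[[i]][, 1], y = coords[[i]][, 2],
               z = coords[[i]][, 3])
  }))
}

# random PSSM profile with integer scores in [-12, 13]
rand_pssm <- function(L, seed = 1L) {
  withr::with_seed(seed, {
    seq1 <- sample(aa_one_letter(standard20()), L, replace = TRUE)
    scores <- matrix(sample(-12:13, L * 20, replace = TRUE), L, 20)
    colnames(scores) <- standard20()
    structure(list(sequence = seq1, scores = scores), class = "PSSMProfile")
  })
}

# mixed-conformation random structure
rand_structure <- function(L, seed = 1L, noise = 10) {
  regime <- rbind(c(-57, -47, 0.5), c(-120, 130, 0.5))
  generate_structure(L, regime, seed = seed, angle_noise_sd = noise)
}

# independent dihedral oracle: arccos of normal angle, signed by triple product
dihedral_oracle <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  if (ang >= 180) ang <- ang - 360
  ang
}
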