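test_that("compute_pssm_from_msa implements the profile-times-rate product", {
  set.seed(21)
  w <- matrix(rnorm(400), 20, 20)

  # one-hot profile selects a row of w
  gamma <- matrix(0, 4, 20)
  hot <- c(3, 17, 1, 20)
  for (i in 1:4) gamma[i, hot[i]] <- 1
  out <- compute_pssm_from_msa(gamma, w)
  for (i in 1:4) expect_equal(unname(out$scores[i, ]), w[hot[i], ])

  # identity rate matrix returns the profile
  gamma2 <- matrix(runif(3 * 20), 3, 20)
  expect_equal(unname(compute_pssm_from_msa(gamma2, diag(20))$scores), gamma2)

  # random case against a triple-loop oracle
  oracle <- matrix(0, 3, 20)
  for (i in 1:3) for (j in 1:20) {
    for (k in 1:20) oracle[i, j] <- oracle[i, j] + gamma2[i, k] * w[k, j]
  }
  expect_equal(unname(compute_pssm_from_msa(gamma2, w)$scores), oracle,
               tolerance = 1e-12)

  expect_error(compute_pssm_from_msa(matrix(0, 3, 19), w), "shape")
  wbad <- w; wbad[1, 1] <- NA
  expect_error(compute_pssm_from_msa(gamma2, wbad), "finite")
})

test_that("profile product is linear in the profile", {
  set.seed(22)
  w <- matrix(rnorm(400), 20, 20)
  g1 <- matrix(runif(100), 5, 20); g2 <- matrix(runif(100), 5, 20)
  a <- 0.3; b <- 1.7
  lhs <- compute_pssm_from_msa(a * g1 + b * g2, w)$scores
  rhs <- a * compute_pssm_from_msa(g1, w)$scores +
    b * compute_pssm_from_msa(g2, w)$scores
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("group_rows_by_residue_type partitions rows per type in order", {
  mk <- function(seq1, scores) {
    structure(list(sequence = seq1, scores = scores), class = "PSSMProfile")
  }
  p <- mk(c("A", "A", "A"), matrix(1:60, 3, 20))
  g <- group_rows_by_residue_type(p)
  expect_named(g, "ALA")
  expect_identical(dim(g$ALA), c(3L, 20L))
  expect_identical(g$ALA, p$scores)

  p20 <- mk(aa_one_letter(standard20()), matrix(rnorm(400), 20, 20))
  g20 <- group_rows_by_residue_type(p20)
  expect_length(g20, 20L)
  expect_true(all(vapply(g20, nrow, integer(1)) == 1L))

  # counting oracle on a random sequence, plus nonstandard skipping
  ps <- rand_pssm(50, seed = 23)
  ps$sequence[c(4, 9)] <- "X"
  g <- suppressWarnings(group_rows_by_residue_type(ps))
  res3 <- aa_three_letter(ps$sequence)
  for (n in names(g)) {
    expect_identical(nrow(g[[n]]), sum(res3 == n))
  }
  expect_identical(sum(vapply(g, nrow, integer(1))), 48L)
  expect_warning(group_rows_by_residue_type(ps), "nonstandard")
})

test_that("mutation_histogram matches boundary cases and a binning oracle", {
  spec <- mutation_histogram_spec()
  Y <- matrix(-12, 4, 20)
  H <- mutation_histogram(Y, spec)
  expect_true(all(H[, 1] == 1) && all(H[, -1] == 0))
  Y <- matrix(13, 4, 20)
  H <- mutation_histogram(Y, spec)
  expect_true(all(H[, 25] == 1) && all(H[, -25] == 0))

  set.seed(24)
  Y <- matrix(sample(-12:13, 7 * 20, replace = TRUE), 7, 20)
  H <- mutation_histogram(Y, spec)
  # element-wise oracle: explicit per-bin membership test
  oracle <- matrix(0, 20, 25)
  for (j in 1:20) for (r in 1:7) {
    v <- Y[r, j]
    for (b in 1:25) {
      lo <- -12 + (b - 1); hi <- -12 + b
      inside <- (v >= lo && v < hi) || (b == 25 && v == 13)
      if (inside) oracle[j, b] <- oracle[j, b] + 1 / 7
    }
  }
  expect_equal(H, oracle, tolerance = 1e-12)
  expect_identical(mutation_histogram(matrix(0, 0, 20), spec),
                   matrix(0, 20, 25))
})

test_that("smooth_histogram_1d is a mass-conserving symmetric smoother", {
  expect_identical(smooth_histogram_1d(rep(0, 25)), rep(0, 25))

  h <- rep(0, 25); h[13] <- 1
  s <- smooth_histogram_1d(h)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(s[13 + 1:2], s[13 - 1:2], tolerance = 1e-15)
  expect_gt(s[13], s[12])

  # explicit padded-convolution oracle
  set.seed(25)
  h <- runif(25)
  k <- exp(-((-2:2)^2) / (2 * 0.25)); k <- k / sum(k)
  hp <- c(h[2], h[1], h, h[25], h[24])
  oracle <- vapply(1:25, function(i) sum(k * hp[i:(i + 4)]), numeric(1))
  expect_equal(smooth_histogram_1d(h), oracle, tolerance = 1e-12)
  expect_equal(sum(smooth_histogram_1d(h)), sum(h), tolerance = 1e-12)
  expect_error(smooth_histogram_1d(h, sigma = 0), "positive")
})

test_that("build_xl has fixed shape, unit slices for present types, zero else", {
  ps <- rand_pssm(30, seed = 26)
  xl <- build_xl(ps)
  expect_identical(dim(xl), c(20L, 20L, 25L))
  expect_true(all(xl >= 0))

  present <- unique(aa_three_letter(ps$sequence))
  for (n in standard20()) {
    sums <- unname(apply(xl[n, , ], 1, sum))
    if (n %in% present) expect_equal(sums, rep(1, 20), tolerance = 1e-9)
    else expect_identical(sums, rep(0, 20))
  }

  # composed oracle: histogram then smoothing, per occurring type
  groups <- group_rows_by_residue_type(ps)
  for (n in names(groups)) {
    H <- mutation_histogram(groups[[n]])
    for (j in 1:20) {
      expect_equal(unname(xl[n, j, ]), smooth_histogram_1d(H[j, ]),
                   tolerance = 1e-12)
    }
  }

  # no-lysine sequence gives an all-zero LYS slice
  ps2 <- rand_pssm(30, seed = 27)
  ps2$sequence[ps2$sequence == "K"] <- "A"
  xl2 <- build_xl(ps2)
  expect_identical(unname(xl2["LYS", , ]), matrix(0, 20, 25))
})

test_that("XL is invariant to permuting sequence positions", {
  ps <- rand_pssm(40, seed = 28)
  perm <- withr::with_seed(29, sample.int(40))
  ps_perm <- ps
  ps_perm$sequence <- ps$sequence[perm]
  ps_perm$scores <- ps$scores[perm, ]
  expect_equal(build_xl(ps), build_xl(ps_perm), tolerance = 1e-12)
})

test_that("XL shape is length-invariant and total mass counts present types", {
  for (L in c(1L, 7L, 120L)) {
    ps <- rand_pssm(L, seed = 30 + L)
    xl <- build_xl(ps)
    expect_identical(dim(xl), c(20L, 20L, 25L))
    n_present <- length(unique(ps$sequence))
    expect_equal(sum(xl), 20 * n_present, tolerance = 1e-6)
  }
})
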