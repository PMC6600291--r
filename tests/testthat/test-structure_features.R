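test_that("map_to_extended23 is total with fixed alphabetical channels", {
  expect_identical(map_to_extended23("ALA"), 1L)
  expect_identical(map_to_extended23("THP"), 23L)   # modified residue -> OTHER
  expect_identical(map_to_extended23("ASE"), 23L)
  expect_identical(map_to_extended23("ASX"), 21L)
  expect_identical(map_to_extended23("GLX"), 22L)

  # sort oracle: the 20 standard codes occupy 1..20 in alphabetical order
  idx <- map_to_extended23(standard20())
  expect_identical(idx, seq_len(20L))
  expect_identical(standard20(), sort(standard20()))
  expect_identical(map_to_extended23(sort(standard20())), 1:20)
  # one-letter input accepted
  expect_identical(map_to_extended23("A"), 1L)
})

test_that("compute_torsion_angles follows the signed IUPAC convention", {
  mk <- function(coords, resnames = rep("ALA", nrow(coords) / 3)) {
    L <- length(resnames)
    structure(list(id = "t", residue = resnames,
                   n = coords[seq(1, 3 * L, 3), , drop = FALSE],
                   ca = coords[seq(2, 3 * L, 3), , drop = FALSE],
                   c = coords[seq(3, 3 * L, 3), , drop = FALSE],
                   chain = rep("A", L), resseq = as.character(1:L),
                   ec_label = NULL), class = "ProteinStructure")
  }
  # planar cis arrangement (C1 and C2 on the same side): phi exactly 0
  coords <- rbind(c(5, 5, 5), c(6, 5, 5), c(0, 1, 0),      # res 1: N CA C
                  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))      # res 2: N CA C
  st <- mk(coords)
  ta <- compute_torsion_angles(st)
  expect_equal(ta$phi[2], 0, tolerance = 1e-9)

  # trans arrangement: dihedral 180 reported as -180 (half-open range)
  coords2 <- coords
  coords2[6, ] <- c(1, -1, 0)
  ta2 <- compute_torsion_angles(mk(coords2))
  expect_equal(ta2$phi[2], -180, tolerance = 1e-9)

  # undefined at the ends and around missing atoms, never zero-filled
  expect_true(is.na(ta$phi[1]) && is.na(ta$psi[2]))
  st_miss <- st; st_miss$c[1, ] <- NA
  expect_true(is.na(compute_torsion_angles(st_miss)$phi[2]))
})

test_that("helix round trip and cross-product oracle agree with dihedrals", {
  st <- generate_structure(20, rbind(c(-57, -47, 1)), seed = 31)
  ta <- compute_torsion_angles(st)
  expect_equal(ta$phi[2:20], rep(-57, 19), tolerance = 1e-6)
  expect_equal(ta$psi[1:19], rep(-47, 19), tolerance = 1e-6)

  # 1,000 random quadruples: atan2 implementation vs arccos-with-sign oracle
  # (absolute tolerance: the oracle's acos is ill-conditioned near 0/180)
  mx <- withr::with_seed(32, {
    max(vapply(1:1000, function(rep_i) {
      q <- matrix(rnorm(12, sd = 2), 4, 3)
      abs(ecfuse:::.dihedral(q[1, ], q[2, ], q[3, ], q[4, ]) -
            dihedral_oracle(q[1, ], q[2, ], q[3, ], q[4, ]))
    }, numeric(1)))
  })
  expect_lt(mx, 1e-9)
})

test_that("build_xa bins residues into per-type Ramachandran channels", {
  st <- generate_structure(30, rbind(c(-57, -47, 1)), seed = 33)
  st$residue[] <- "GLY"
  xa <- build_xa(st)
  expect_identical(dim(xa), c(19L, 19L, 23L))
  ch <- map_to_extended23("GLY")
  expect_equal(sum(xa[, , ch]), 1, tolerance = 1e-9)
  expect_identical(sum(xa[, , -ch]), 0)
  # mass concentrated around the helix cell
  cell <- which(xa[, , ch] == max(xa[, , ch]), arr.ind = TRUE)
  expect_identical(unname(cell[1, ]), c(7L, 8L))  # floor((x+180)/(360/19))+1

  # unsmoothed counts match a per-residue binning loop oracle
  st2 <- rand_structure(40, seed = 34)
  ta <- compute_torsion_angles(st2)
  raw <- build_xa(st2, ta, smooth = FALSE)
  oracle <- array(0, c(19, 19, 23))
  wbin <- 360 / 19
  for (i in 1:40) {
    if (is.na(ta$phi[i]) || is.na(ta$psi[i])) next
    pb <- min(floor((ta$phi[i] + 180) / wbin) + 1, 19)
    sb <- min(floor((ta$psi[i] + 180) / wbin) + 1, 19)
    m <- map_to_extended23(st2$residue[i])
    oracle[pb, sb, m] <- oracle[pb, sb, m] + 1
  }
  for (m in 1:23) {
    s <- sum(oracle[, , m])
    if (s > 0) oracle[, , m] <- oracle[, , m] / s
  }
  expect_equal(unname(raw), oracle, tolerance = 1e-12)
})

test_that("pairwise_ca_distances enumerates unordered pairs exactly", {
  st <- rand_structure(5, seed = 35)
  st$ca <- rbind(c(0, 0, 0), c(3, 4, 0), c(10, 10, 10), c(0, 0, 7), c(1, 1, 1))
  pairs <- pairwise_ca_distances(st)
  expect_identical(nrow(pairs), 10L)  # 5*4/2
  expect_equal(pairs$d[pairs$i == 1 & pairs$j == 2], 5)  # 3-4-5 triangle

  st2 <- rand_structure(20, seed = 36)
  pairs2 <- pairwise_ca_distances(st2)
  expect_identical(nrow(pairs2), 190L)
  for (r in sample(190, 25)) {
    i <- pairs2$i[r]; j <- pairs2$j[r]
    expect_equal(pairs2$d[r], sqrt(sum((st2$ca[i, ] - st2$ca[j, ])^2)),
                 tolerance = 1e-12)
  }
  # min_separation removes sequence-adjacent pairs
  pairs3 <- pairwise_ca_distances(st2, min_separation = 1)
  expect_identical(nrow(pairs3), 190L - 19L)
  # fewer than two CAs: empty
  st3 <- st2; st3$ca[] <- NA
  expect_identical(nrow(pairwise_ca_distances(st3)), 0L)
})

test_that("build_xd clips long distances into the last bin and is symmetric", {
  pairs <- data.frame(i = 1L, j = 2L, type_i = "ALA", type_j = "GLY", d = 45)
  xd <- build_xd(pairs)
  expect_identical(dim(xd), c(23L, 23L, 8L))
  sl <- xd[map_to_extended23("ALA"), map_to_extended23("GLY"), ]
  expect_equal(sum(sl), 1, tolerance = 1e-9)
  expect_identical(which.max(sl), 8L)
  expect_true(all(sl[1:5] < 0.05))

  # random pair list: symmetry exact, unsmoothed counts match oracle
  set.seed(37)
  tps <- sample(extended23(), 100, replace = TRUE)
  tqs <- sample(extended23(), 100, replace = TRUE)
  pr <- data.frame(i = 1:100, j = 101:200, type_i = tps, type_j = tqs,
                   d = runif(100, 0, 50))
  xd2 <- build_xd(pr)
  for (b in 1:8) {
    expect_identical(xd2[, , b], t(xd2[, , b]))
  }
  raw <- build_xd(pr, smooth = FALSE)
  oracle <- array(0, c(23, 23, 8))
  for (r in 1:100) {
    if (pr$d[r] < 5) next
    b <- min(floor((pr$d[r] - 5) / 4.375) + 1, 8)
    ci <- map_to_extended23(pr$type_i[r]); cj <- map_to_extended23(pr$type_j[r])
    oracle[ci, cj, b] <- oracle[ci, cj, b] + 1
    oracle[cj, ci, b] <- oracle[cj, ci, b] + 1
  }
  for (a in 1:23) for (bb in 1:23) {
    s <- sum(oracle[a, bb, ])
    if (s > 0) oracle[a, bb, ] <- oracle[a, bb, ] / s
  }
  expect_equal(unname(raw), oracle, tolerance = 1e-12)
})

test_that("XA and XD are invariant under rigid motion", {
  st <- rand_structure(35, seed = 38)
  # random rotation (QR of a random matrix) + translation
  rt <- withr::with_seed(39, {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    list(Q = Q, t = rnorm(3, sd = 20))
  })
  st2 <- st
  for (m in c("n", "ca", "c")) {
    st2[[m]] <- sweep(st[[m]] %*% t(rt$Q), 2, -rt$t)
  }
  expect_equal(build_xa(st), build_xa(st2), tolerance = 1e-9)
  expect_equal(build_xd(pairwise_ca_distances(st)),
               build_xd(pairwise_ca_distances(st2)), tolerance = 1e-9)
})

test_that("2D smoothing conserves per-channel mass", {
  st <- rand_structure(50, seed = 40)
  raw <- build_xa(st, smooth = FALSE)
  sm <- build_xa(st)
  for (m in 1:23) {
    expect_equal(sum(sm[, , m]), sum(raw[, , m]), tolerance = 1e-9)
  }
})
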