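---
title: "Methods: histogram feature maps, parallel CNNs and correlation-KNN fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histogram feature maps, parallel CNNs and correlation-KNN fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

Enzymes are grouped by the Enzyme Commission into six primary reaction
classes (EC1 oxidoreductases through EC6 ligases).  `ecfuse` predicts the
primary class of a single-function enzyme from two complementary sources:

* **sequence conservation**: the PSI-BLAST position-specific scoring matrix
  (PSSM), an $L \times 20$ table of log-odds scores $p_{i,j}$ measuring how
  mutable position $i$ is toward amino-acid type $j$;
* **backbone geometry**: the $(\phi, \psi)$ torsion angles of each residue
  and the pairwise C$\alpha$--C$\alpha$ distances.

Proteins have different lengths, so none of these can feed a fixed-input
classifier directly.  The standardization device is the histogram: every
quantity is binned into a tensor whose shape does not depend on $L$.

* **XL, $20 \times 20 \times 25$** — for each *source* residue type $n$, the
  PSSM rows at positions of type $n$ are collected, and each of the 20
  target-type columns is histogrammed into 25 unit-width bins over the
  log-odds range $[-12, 13]$ (the observed PSI-BLAST range; the arithmetic
  is exact: $(13-(-12))/25 = 1$).
* **XA, $19 \times 19 \times 23$** — a Ramachandran (2-D $\phi/\psi$)
  histogram with 19 bins per axis over $[-180^\circ, 180^\circ]$, one
  channel per residue type in an extended 23-letter alphabet.
* **XD, $23 \times 23 \times 8$** — for each ordered pair of residue-type
  channels, an 8-bin histogram of C$\alpha$ distances over
  $[5, 40]\,$Å (bin width $4.375\,$Å).

Each map feeds a small convolutional network; the per-map class
probabilities are concatenated ("late fusion") and the fused vectors are
classified by a $k$-nearest-neighbour rule ($k = 12$) under the correlation
distance $1 - \rho(u, v)$.  Two fusion layouts exist: **Architecture 1**
trains one CNN per map and fuses to a length-$3l$ vector (18 at $l = 6$);
**Architecture 2** trains one CNN per *channel* ($23 + 8 + 25 = 56$ of
them) and fuses to length $l \cdot 56 = 336$.

# Normalization and numerical choices

Several details are under-determined by the method description; the
package fixes them as follows, and each choice is covered by a test.

**Histograms are probability masses, not counts.**  Every per-slice
histogram (a $(n, j)$ slice of XL, a type channel of XA, a type-pair slice
of XD) is normalized to sum 1 when it has any observations and left
all-zero otherwise.  Length standardization is the stated purpose of the
histograms, and raw counts would re-introduce $L$ as a nuisance scale.  A
zero slice (absent type) is deliberately *not* renormalized — absence is
signal.

**Bin conventions.**  All bins are left-closed/right-open with the final
bin closed, so the boundary values ($13$, $+180^\circ$, $40\,$Å) land in
the last bin.  PSSM scores outside $[-12, 13]$ (rare in real PSI-BLAST
output) are clipped into the end bins.  Distances above $40\,$Å are
clipped into the last bin — long-range mass belongs at "high distances" —
while distances below $5\,$Å are discarded (sub-5 Å C$\alpha$ pairs are
near-sequential backbone contacts below the stated range).  Dihedrals are
reported in $[-180^\circ, 180^\circ)$, with exact $180^\circ$ mapped to
$-180^\circ$.

**Smoothing.**  Histograms are smoothed with a discrete Gaussian of
$\sigma = 0.5$ bins, truncated at $\pm 2$ bins ($4\sigma$) and
renormalized, under symmetric boundary padding.  This combination
conserves each slice's mass *exactly* (to fp rounding), which makes mass a
testable invariant.  The $\sigma$ for the 2-D angle kernel and the distance
kernel is not fixed by the method description; both default to 0.5 bins in
parallel with the stated mutation-map value, and both are configurable in
the specs.  The 2-D smoothing is separable (rows then columns of each
channel).

**The 23-letter alphabet.**  The structural maps use 23 residue-type
channels but the membership of the extra three is not enumerated anywhere;
worked examples show modified residues (ASE, THP) carrying channels.  The
package uses the 20 standard types in alphabetical three-letter order
(which coincides with PSI-BLAST column order), then the ambiguity codes
ASX and GLX, then a single OTHER catch-all that absorbs every modified or
unknown code.  This makes the mapping total and deterministic.  The PSSM,
by contrast, is strictly $L \times 20$: nonstandard positions are skipped
(with a warning) when grouping rows for XL.

**Degenerate inputs.**  Residues missing backbone atoms keep their place in
the chain; any feature needing a missing atom skips that residue, and
nothing is imputed.  Torsions at chain ends are undefined (`NA`), never
zero-filled.  A constant vector has no defined Pearson correlation; its
correlation distance is defined as 1 (the uncorrelated convention).

**The KNN metric.**  The method description prints the metric as
"$1 - \mathrm{cov}(x_A, x_D, x_L)$", which is not a two-argument distance;
since the fusion step has already concatenated the per-map probabilities
into one vector per protein and the text says the metric "measures the
correlation", it is implemented as 1 minus the Pearson correlation between
two fused vectors, with range $[0, 2]$.  Ties in the majority vote are
broken by the smallest summed neighbour distance, then by the lowest class
index, making predictions fully deterministic.  The per-class ROC decision
score is the inverse-distance-weighted vote share among the $k$
neighbours.

# The network

The published stack lists its components — convolution, batch
normalization, ReLU, dropout, max pooling, a fully connected layer and
softmax — with receptive fields 5/5/2, filters 20/50/500, stride 1,
learning rate 0.001, and batch sizes and epochs of 1000/300
(Architecture 1) and 100/150 (Architecture 2).  The ordering and
multiplicity within the stack are not printed.  The package uses the
canonical small-input ordering

    conv5 -> BN -> ReLU -> maxpool2
    conv5 -> BN -> ReLU
    conv2 -> BN -> ReLU -> dropout -> dense(l) -> softmax

with valid padding.  A *single* pooling stage is the only layout under
which all three map geometries stay valid for the 5/5/2 fields: the
19×19 angle map traces $19 \to 15 \to 7 \to 3 \to 2$, and a second pool
would collapse $3 \to 1$ below the final conv2.  Unstated details default
to: plain SGD (momentum 0) at the printed learning rate, dropout 0.5
applied only before the dense layer, 2×2 stride-2 pooling with floor
division.  Optimization minimizes softmax cross-entropy; initialization,
shuffling and dropout are all driven by one seed, so training is
bit-reproducible.

A scaled-down **desk profile** ships for testing: filters 8/16/64,
20 epochs, batch 8, momentum 0.9.  The published batch sizes exceed a
desk-scale training set (48 samples) outright and plain SGD at 0.001 is
calibrated for a 300-epoch schedule, so the desk profile takes its batch
size from the dataset scale (120 SGD updates in 20 epochs) and compensates
for the short schedule with standard momentum rather than an altered
learning rate.  The engine itself is plain R over BLAS matrix products
(im2col convolutions): the largest input is $23 \times 23 \times 25$, and
at that scale compiled code would buy nothing.

# The synthetic world

The generator stands in for a PDB + PSI-BLAST corpus, which cannot be
shipped or recomputed offline.  Each class is given:

* a **torsion regime** — a mixture over canonical Ramachandran basins
  (α-helix $(-57, -47)$, β-strand $(-120, 130)$, polyproline II
  $(-75, 150)$, left-handed helix $(60, 45)$) with Gaussian angular noise
  (default sd $8^\circ$, a realistic within-basin spread).  The six
  default classes are: pure helix, pure strand, helix+strand,
  pure PPII, pure left-helix, PPII+left-helix.
* a **conservation profile** — for each residue type, a 20-vector of mean
  log-odds scores with two class-specific high-score targets (9 and 5) on
  a rotating subset over a $-4$ background, plus uniform integer noise
  $\pm 2$, clipped into $[-12, 13]$.

Backbones are built from the sampled $(\phi, \psi, \omega = 180^\circ)$ by
sequential internal-coordinate (NeRF) placement with ideal bond geometry
(N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å), which makes the torsion
round trip exact to numerical precision — the basis of the
parameter-recovery test.  Default lengths are 120–200 residues: enzyme
domains run to hundreds of residues and short chains make the per-type
PSSM histograms statistically meaningless (at $L \approx 50$ each type
occurs 2–3 times, so each 25-bin histogram would be built from 2–3
values).  Signal is injected through *both* geometry and sequence so that
each of XA, XD and XL is individually informative, mirroring the claim
that adding sequence information to structure helps.

What the generator does **not** emulate: real folds (chains are
self-avoiding only by accident), homology between classes, length/class
correlations, PSI-BLAST's iteration behaviour, or crystallographic
artifacts (alternate locations, gaps).  A green end-to-end test therefore
establishes that the pipeline is wired correctly and can exploit
class-conditional structure at desk scale — not that the published
corpus-scale accuracies are reproduced.  Those (92.34% / 90.01% overall)
would require the 43,843-protein corpus and full-scale training, and no
test here asserts them.

# Evaluation protocol

`split_dataset` makes a seeded 80/20 partition, stratified by default
(stratification is not stated in the protocol; the flag can disable it).
`confusion_matrix_percent` is row-normalized so the diagonal carries the
per-class accuracies; `roc_auc_per_class` sweeps thresholds over the
one-vs-rest decision scores with tie groups stepping diagonally and
trapezoidal area, and flags (rather than zeroes) classes absent from the
truth.  The ROC in the published protocol came from unspecified
cross-validation; here curves are computed on the held-out test partition,
a documented deviation of unknown fidelity.

# Worked example

```{r}
library(ecfuse)

cfg <- simulation_config(n_classes = 6, n_per_class = 10, seed = 42)
man <- generate_dataset(cfg, file.path(tempdir(), "demo"))
feats <- extract_features(man)
sp <- split_dataset(man, seed = 42)
res <- run_experiment(feats, sp, architecture = 1,
                      config = cnn_config("desk", seed = 42))
res$accuracy
res$confusion
res$roc$macro_auc
```

# Known limitations

* The feature container is RDS, not HDF5 (no R HDF5 binding is available
  in the supported environment); the bit-exact round-trip contract is
  kept, language portability is not.
* Architecture 2 trains 56 independent CNNs; at the published scale this
  is expensive, and the package makes no attempt to share parameters
  across channels (the description reads as independent models).
* The paper-scale profiles (`cnn_config("arch1")`, `"arch2"`) are
  faithful to the printed hyperparameters but are not exercised by the
  test suite beyond construction — training them needs corpus-scale data.
* The CNN engine is single-threaded reference R; it is sized for
  desk-scale experiments, not production training.
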