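---
title: "Haplotype assembly from learned read correlations: model and methods"
author: "CorrHap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype assembly from learned read correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CorrHap)
```

## The problem

Reference-guided haplotype assembly asks: given aligned sequencing reads
from a single k-ploid individual, reconstruct the k sequences of alleles at
its heterozygous SNP sites. After alignment and SNP calling, each read
reduces to a *fragment*: its alleles at the called sites it covers. The
fragments form an n x l matrix S over {A, C, G, T, uncovered} — rows are
fragments (paired-end mates merged, with the insert uncovered), columns are
SNP sites. Assembly is equivalent to clustering the reads by haplotype of
origin and calling a consensus per cluster; with sequencing errors the
problem is NP-hard, and most methods score solutions by the minimum error
correction (MEC): the number of allele changes needed to make every read
consistent with its closest reconstructed haplotype.

The difficulty is that only *overlapping* reads carry a measurable pairwise
signal. For reads i and j sharing covered sites, the measured correlation

  C_ij = (kSim - kDissim) / (kSim + kDissim)

(agreeing minus disagreeing shared sites over their total) is near +1 for
same-haplotype pairs and near -1 for different-haplotype pairs; for
non-overlapping pairs it is identically zero. CorrHap's model *learns* a
full correlation matrix, propagating the polarity of overlapping pairs to
non-overlapping ones through chains of overlaps.

## The correlation model

Each fragment row is one-hot encoded (uncovered cells map to the zero
vector, making all four bases mutually equidistant) and embedded by a
convolutional encoder: three convolution layers with kernels (4,5), (1,5),
(1,3) — the first consumes the nucleotide axis, all use "same" padding
along the genome axis — with 32, 64 and 128 filters, a parametric ReLU
after each, then a flatten and an affine map to a d_R = 128 dimensional
embedding z_i. A transformer encoder (three standard layers: multi-head
self-attention over the n reads with four heads, add-and-layer-normalize,
position-wise feed-forward of width 4 d_R, add-and-layer-normalize) maps
the embedding matrix to an n x d_Q head output Q with d_Q = d_R / 2. Row
normalization gives Q-tilde, and

  Sigma = Q-tilde %*% t(Q-tilde)

is symmetric positive semi-definite with unit diagonal — a valid kernel.
No positional encodings are added: read order in S is arbitrary, and the
forward pass should be (and is) permutation-equivariant.

Training is unsupervised and alternates two steps per epoch, starting from
an initial attribution obtained by kernel k-means on the PSD-repaired
measured correlations (a data-driven warm start; a random initialization is
available behind `trainConfig(init = "random")`):

1. with the pair indicator p fixed (p_ij = 1 when reads i, j are currently
   attributed to the same haplotype), one pass of Adam updates over
   mini-batches of ceiling(n/5) reads minimizes

   L = L_c + lambda_r L_r + lambda_s L_s,  lambda_r = 100, lambda_s = 10,

   where the contrastive loss L_c sums p_ij (1 - Sigma_ij)^2 +
   (1 - p_ij)(1 + Sigma_ij)^2 over unordered pairs in the batch, the
   consistency term L_r is the Frobenius norm of (Sigma - C) masked to the
   support of C, and the sparsity term L_s sums |Sigma_ij| off the
   diagonal;
2. Sigma is recomputed on all reads and the attribution refreshed by kernel
   k-means with Sigma as the kernel.

After the final epoch the consensus haplotypes and the MEC score are
computed; the whole procedure is restarted from several random
initializations (five by default) and the lowest-MEC model is kept, with
ties broken by the lower final loss. Full-scale defaults follow the
calibrated setting: learning rate 1e-5, 2000 epochs, batch ceiling(n/5).

### Design choices the architecture leaves open

* **Padding.** Kernel shapes and filter counts fix everything except
  padding; "same" padding along the genome axis keeps the flatten size at
  l x 128, which pins the dense-layer dimensions.
* **Pair summation.** The contrastive sum is over unordered pairs (i < j);
  an ordered double sum only doubles the gradient, which the learning rate
  absorbs.
* **Batch-local pairs.** Losses need pairs; with mini-batches of reads,
  pairs are restricted to reads within the same batch, while step 2 always
  uses all reads. This reconciles mini-batching with losses defined over
  read pairs.
* **Feed-forward width.** Set to 4 d_R, the usual transformer convention.
* **Minimum block length.** "Same" padding works for any l at least the
  widest kernel (5 columns); shorter inputs raise an error.
* **Row-normalization guard.** Head rows with norm below 1e-8 are left as
  zero rows (their off-diagonal correlations are 0; the diagonal is forced
  to 1), avoiding division blow-ups.
* **Warm-started refresh.** The per-epoch kernel k-means competes ten
  random restarts *and* the previous epoch's assignment on the k-means
  objective. Without the warm start the refresh can flip between near-tied
  clusterings while Sigma is still moving, making the final epoch a
  lottery on small inputs; with it the attribution changes only when a
  strictly better clustering exists. The `kernelKmeans()` contract itself
  is unchanged.
* **Final epoch returned.** The result is the final epoch's model (the
  per-epoch history, including MEC, is kept in the result for inspection);
  restart selection then operates on final-epoch MEC.

All gradients are computed by hand-derived backpropagation through the
convolutions (im2col), PReLU, attention, layer normalization, row
normalization and the Gram head; a finite-difference check in the test
suite verifies every layer's gradient to a relative 1e-3. One caveat worth
recording: the key-projection bias has exactly zero gradient (softmax is
invariant to constant row shifts), so that direction is compared in
absolute terms.

## Kernel k-means and consensus

Kernel k-means assigns reads to minimize within-cluster distance in the
feature space implied by the kernel, computed entirely from kernel entries;
clusters that empty are reseeded with the point farthest from its current
centroid, and the best of ten random restarts (by objective) is kept. For
n of at most 8 the test suite checks the returned objective against
exhaustive enumeration of all bipartitions.

Consensus calling takes, per cluster and column, the majority allele among
covering reads; ties fall back to the allele's count across *all* reads,
then to lexicographic base order; a column with no covering read in a
cluster is imputed with the all-reads majority. MEC is always recomputed
from the fragment matrix and the returned haplotypes, never trusted from
the training loop.

## The simulator

`simConfig()` / `makeDataset()` emulate the semi-experimental pipeline the
method is calibrated on. Variant positions are placed by accumulating
inter-SNP distances drawn log-normally — log-mean 3.03, log-sd 1.293 over
10 kb in short-read mode (mean spacing about 48 bp, about 200 variants),
log-mean 6.07 over 100 kb in long-read mode (about 100 variants). Sites
are biallelic and heterozygous by construction (reference plus one
alternative allele, assigned independently per haplotype with rejection of
homozygous draws). Short mode draws round(coverage x L / 500) paired-end
fragments of 2 x 250 bp with insert length N(550, 10); long mode draws
round(coverage x L / 9000) reads with log-normal lengths of mean 9000 bp
and CV 0.3 (the length model only fixes the mean; the CV is a generator
choice). Substitution errors hit covered SNP cells i.i.d. (0.1% short, 5%
long) uniformly over the three alternative bases.

Two deliberate simplifications: errors are applied only at SNP cells
(errors elsewhere never reach the fragment matrix), and alignment is
bypassed — fragments are emitted directly as matrix rows, with optional
FASTQ export for running an external aligner. Consequently read-mapping
artifacts (soft-clips, mismapping, indel noise, quality-score structure)
are *not* represented, and passing tests say nothing about robustness to
them.

One part of the alignment pipeline is emulated explicitly: SNP calling.
The matrix is restricted to sites where at least two alleles reach a
variant allele frequency of 0.2 among the covering reads. This matters at
region edges, where coverage tapers and a site may be covered by reads of
only one haplotype: a real caller sees no variant there and never emits the
site, and keeping such sites would make them unphaseable by construction
(their imputed alleles cap the correct phasing rate below 1 even for a
perfect clustering). `makeDataset()` therefore returns the ground truth
restricted to called sites alongside the full truth.

The spacing parameters imply a mean distance of exp(3.03 + 1.293^2/2),
about 47.8 bp (respectively about 956 bp at log-mean 6.07) — slightly
below the rounded 50 bp / 1000 bp usually quoted for them; the generator
follows the parameters, not the rounded means.

## Metrics

* **MEC**: per read, Hamming distance over its covered columns to the
  closest haplotype, summed.
* **CPR** (correct phasing rate): fraction of alleles agreeing with the
  truth under the best one-to-one row mapping (exhaustive over k!, k at
  most 8).
* **SWER / VER**: per column the best permutation aligning the
  reconstruction to the truth is found (for diploids: identity or swap);
  the rate of permutation changes between adjacent columns is the switch
  (k = 2) or vector (k > 2) error rate. Ambiguous columns — homozygous in
  truth, or predicted alleles outside the true pair, costing both
  pairings equally — inherit the previous column's permutation, so they
  never count as switches. SWER and VER coincide for k = 2.
* When a dataset's connectivity splits it into several independently
  phased blocks, `evaluatePhasing()` averages CPR weighted by block length
  and pools switch errors over within-block adjacent pairs — the
  convention used for methods that return fragmented haplotypes.

## Long ranges

For long SNP ranges the matrix is processed in overlapping column blocks
(250 SNPs with 50-SNP overlaps by default), each assembled independently;
consecutive blocks are phased together by the permutation minimizing
Hamming distance over the overlap (exhaustive over k!, ties to the
lexicographically smallest permutation), with the earlier block's alleles
kept in overlaps — a deterministic, order-stable rule the overlap matching
itself does not fix. A block with no informative fragments breaks phasing:
its columns are imputed from the all-reads consensus and a new phase set
starts. Blocks are processed sequentially.

## Desk-scale configuration and what the tests show

The full-scale configuration (d_R = 128, 2000 epochs, hundreds of reads)
is a cluster-scale computation. The package's test suite and acceptance
script run a reduced configuration chosen once: a 2.5 kb region (about 50
called SNPs at the short-read spacing), 30x coverage (about 150
fragments), encoder dimension d_R = 32 (filters 8/16/32, d_Q = 16), 150
epochs at learning rate 5e-5 — a larger step than the full-scale 1e-5
because far fewer epochs are taken — with batch ceiling(n/5) and five
restarts. Under these conditions, error-free diploid data is recovered
exactly (MEC 0, correct phasing rate 1) on the largest connectivity block
for 10/10 seeds, and with 0.1% substitution errors the mean correct
phasing rate over five datasets is above 0.99 with switch error rates near
zero.

Two desk-scale phenomena are worth understanding:

* **Block splits.** With mean insert 550 +- 10 bp, an inter-SNP gap beyond
  about 550 bp cannot be bridged by any fragment; the log-normal tail
  produces such a gap in roughly a quarter of 2.5 kb datasets. The matrix
  then genuinely splits, each block is phased on its own, and no assembler
  could do otherwise; evaluation is per block in that case.
* **MEC ties.** At small scale a switched solution occasionally attains
  exactly the optimal MEC (a boundary bridged by a single fragment whose
  few cells trade off against sequencing errors). MEC-based model
  selection cannot distinguish the tied solutions; this is a property of
  the objective, not of the optimizer, and it shrinks with problem size.

## Limitations

Indels, chimeric reads, base-quality models and realignment are out of
scope; SNP calling uses no mapping- or base-quality filters (none are
specified for the pipeline being emulated). CPR's exhaustive mapping stops
at k = 8. The model trains one block at a time on a single CPU; no
multi-device execution is provided. Pre-trained weights are not shipped:
training is unsupervised and per-dataset by design.
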