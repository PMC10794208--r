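---
title: "Methods: contrastive multi-view binning of metagenomic contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrastive multi-view binning of metagenomic contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Metagenomic assembly yields contigs from many genomes mixed together;
binning groups contigs that originate from the same genome into draft
genome bins. Two signals carry most of the information: sequence
composition (tetranucleotide frequencies, which are genome-characteristic)
and coverage (the per-base read depth of a contig across sequencing
samples, which follows the genome's abundance profile). `contrabin` learns
a joint embedding of both signals by multi-view contrastive learning and
clusters the embeddings with a constrained Leiden community detection.

# Multi-view augmentation

The proxy task rests on one assumption: contiguous sub-sequences of a
contig belong to the same genome (assembly chimerism aside). Each contig
therefore gets `n_aug = 5` augmented views — random contiguous fragments of
at least 1000 bp — plus the original sequence, six views in total. Views of
the same contig are positives; all views of other contigs in a batch are
negatives.

The fragment law is: length uniform on `[min_frag_len, L]`, then start
uniform on `[0, L - length]`. This is the simplest law consistent with
"random contiguous fragments of at least 1 kbp"; it is exposed through
`augment_contigs()` so other laws can be substituted. Fragments may overlap
and may repeat; no deduplication is applied. Augmentations are drawn once
per run (not per epoch), from per-contig RNG streams derived from
`(seed, contig_id)`, making the view set independent of contig order and of
parallel scheduling.

# Feature construction

**Composition.** A sliding window of length `k = 4`, stride 1, counts
tetramers; a tetramer and its reverse complement are pooled into one
canonical class because the assembled strand is arbitrary. Enumeration
gives `T = 136` classes (120 complement pairs + 16 palindromic singletons).
Windows containing non-ACGT characters are skipped deterministically
(rather than randomized, for reproducibility). Counts get a pseudocount of
1 per class — no zero entries — and are normalized to sum to one, removing
contig-length effects.

**Coverage.** For each view and each of the `M` samples, the per-base
depth mean and standard deviation are computed over the view's parent
interval, straight from a run-length encoding of the depth track (per-base
arrays are never materialized). The standard deviation is the population
form: it is a descriptive statistic of the multiset of per-base depths,
not an estimate from a sample of them. Each of the `2M` entries gets a
`1e-5` offset so no vector is identically zero, then every column is
divided by its maximum over *original-contig* views. Fragments reuse the
original-contig divisors: the original contigs' features are thereby
invariant to which fragments were drawn. Mean and standard-deviation
columns are normalized independently, each by its own maximum; the
between-sample scale differences this removes are exactly the arbitrary
sequencing-effort differences.

Contigs with zero aligned reads in all samples are retained — the offset
keeps their features finite — because dropping them silently would change
the contig universe between stages.

# Encoders and objective

A coverage network (three affine layers, LeakyReLU, dropout) embeds the
`2M`-dim coverage vector; its output is L2-normalized — matching the
cosine geometry of the loss — and concatenated with the 136-dim
composition vector as input to a combine network of the same shape whose
output `z` is the contig embedding. There is no separate projection head:
the combine output is both the contrastive space and the clustering input.

The objective is the normalized temperature-scaled cross-entropy (NT-Xent)
extended to `V` views. For anchor view `v` of contig `i` in a batch of
`N_bs` contigs:

- positives: all `V - 1` other views of contig `i`, each contributing an
  ordered term;
- the denominator of each term is the positive's own exponential plus the
  anchor's similarity to *all* `V` views of every other contig in the
  batch; the anchor contig's remaining views are not part of the
  denominator;
- similarities are cosines scaled by a temperature `tau`.

With `V = 2` this reduces algebraically to the symmetric two-view NT-Xent
(the suite verifies the identity numerically to 1e-9, and the multi-view
form against a brute-force triple-loop oracle to 1e-6). The temperature
default follows the assembly N50: `tau = 0.07` for N50 > 10 kbp, `0.15`
otherwise — fragmented assemblies give noisier views and benefit from a
softer similarity scale.

## Training

Batches sample `batch_size` contigs (default 1024) and carry all their
views; the gradient of the batch loss is computed analytically (verified
against finite differences to ~1e-9) and applied with Adam. A trailing
incomplete batch is dropped, because NT-Xent's negative set must have a
fixed structure; when the whole assembly is smaller than `batch_size`, the
full set forms one batch. Contig order reshuffles each epoch. Training
runs for up to 200 epochs with early stopping on a training-loss plateau
(no improvement above `1e-4` for 10 epochs); there are no labels to
validate on, so training loss is the only available monitor. All
randomness — initialization, shuffling, dropout — derives from one seed,
and identical seeds give identical loss histories.

The peak learning rate (default `1e-3`) follows a half-cosine decay to
zero over the epoch budget (`lr_schedule = "cosine"`), the standard
schedule for NT-Xent-style training. The decay matters beyond convergence
speed: contrastive objectives optimize both alignment (views of one contig
together) and uniformity (everything else apart), and on small communities
prolonged constant-rate training keeps sharpening uniformity until
genome-level cohesion — which the loss never explicitly rewards — erodes
and clusters fragment or dissolve. A decayed rate organizes the embedding
early and then effectively freezes it. A `"constant"` schedule remains
available. Layer widths (2048/2048 hidden, latent 128) are package
defaults, config-exposed; they are not prescriptions from the method's
source, and the test fixtures use smaller widths scaled to their data
(see "Problem sizes" below).

# Clustering

Embeddings of the original contigs (view 0 only, dropout off) are
clustered as follows.

1. **k-NN graph.** Exact blocked squared-L2 k-nearest-neighbour search
   (`k = min(100, N - 1)` by default), directed lists symmetrized by
   union. At the scales this package targets an exact search is fast and
   removes an approximation parameter; any approximate index that passes
   the brute-force recall oracle in the suite could be substituted.
2. **Edge filtering.** Keep the `floor(ratio * E)` smallest-distance edges,
   `ratio` in {0.5, 0.8, 1.0} — focusing community detection on confident
   neighbourhoods.
3. **Similarity.** `S_ij = exp(-d2_ij / sigma)`, squared L2 in the
   exponent, `sigma` in {0.05, 0.1, 0.15, 0.2, 0.3}.
4. **Constrained Leiden.** Initial membership is singleton-per-contig.
   The single-copy marker gene hitting the most distinct contigs is chosen
   as the seed marker (ties: lexicographically smallest id); the contigs
   carrying it are *fixed members* — frozen in their distinct initial
   communities — because contigs sharing a single-copy gene must come from
   different genomes. Node sizes are contig lengths, treating each node as
   an aggregation of base pairs. The backend is `leidenalg`'s
   Erdős–Rényi-null resolution-parametrized partition
   (`RBERVertexPartition`), the quality function in that library that
   accepts both weights and node sizes while keeping the null term on the
   scale of the observed edge density; a literal constant-Potts reading of
   "resolution with node sizes" would put the null term on the scale of
   squared base-pair counts and shatter every partition across the entire
   resolution grid, so it was rejected. The optimiser is run to
   convergence under a per-combination seed, making the sweep independent
   of worker count and schedule.
5. **Selection.** Resolutions {1, 5, 10, 30, 50, 70, 90, 110} × the sigma
   and ratio grids (120 combinations). Each partition is scored by
   single-copy-gene estimates: per bin, completeness
   `= 100 * distinct_markers / G` and contamination
   `= 100 * (hits - distinct) / G`; the partition score is the number of
   bins passing each of six threshold pairs (contamination strictly below
   5% or 10% × completeness strictly above 50/70/90%), summed. The
   partition with the maximal score wins; ties resolve to the first
   combination in (edge_ratio, sigma, resolution) sweep order. This
   estimator is intentionally simple — a distinct/duplicate marker count,
   not a trained quality model — and is the single formula all tests
   target.
6. **Size filter.** Bins strictly smaller than 200 kbp are dropped (their
   contigs become unbinned); a bin of exactly 200 kbp survives.

# Binning modes

Co-assembly (pooled contigs, coverage from all samples), single-sample
(one sample's contigs and coverage) and multi-sample (sample-specific
contigs with coverage aggregated across all samples' alignments) differ
only in input arity: the feature machinery always produces `2M` coverage
columns from `M` depth inputs. The multi-sample contract follows the
aggregated-coverage convention (sample-specific contigs, cross-sample
depth); the concatenate-then-split variant is out of scope.

# The synthetic community generator

`simulate_community()` builds fully self-contained test data: genomes
drawn from per-genome order-1 base-transition laws (bias strength
`composition_divergence`; 0 collapses all genomes onto the uniform law),
fragmented into contigs with lengths uniform on [1, 5] kbp, per-sample
depth equal to abundance × scale × a per-contig lognormal factor
(`sd = 0.3`), modulated along the contig by a smooth sinusoid so the
within-contig depth variance is nonzero, and `G` markers planted exactly
once per genome per marker on random contigs. Abundance profiles default
to i.i.d. lognormal(0, 1).

The `"easy"` preset (10 genomes × 300 kbp, 5 samples, divergence 1.5,
~100 contigs/genome) is the canonical end-to-end fixture; its abundance
profiles are rotations of one peaked profile with peaks evenly spaced
across the (circular) sample axis, so every pair of genomes has a distinct
profile by construction rather than with high probability. The
`"hard-strain"` preset gives two genomes one shared composition law and
mirror-image abundance profiles: composition cannot separate them,
coverage can — the regime where joint embeddings earn their keep.

What the generator does *not* emulate: assembly chimeras and repeats,
shared k-mer composition between related (non-identical) genomes,
mapping ambiguity, uneven genome sizes, strain microdiversity within one
genome. Passing the end-to-end tests therefore demonstrates the machinery
is correct and the signals are integrated, not that real-data performance
matches any benchmark.

# Problem sizes and numerical choices

The suite runs everything at desk scale, chosen as the package's own
test-design point: unit fixtures use 2–4 genomes of 15–80 kbp; the
canonical end-to-end fixture has ~1000 contigs, trained with 128/256-wide
encoders, latent 64, batch 512, up to 200 epochs. Tetramer counting and
loss values are checked against brute-force oracles at 1e-12/1e-6;
gradient checks at 1e-5 against central differences; k-NN recall ≥ 0.99
against exhaustive search. Degenerate inputs are defined, not crashed:
an empty marker table runs unconstrained clustering and makes selection
degenerate (first combination, with a warning); a contig absent from a
depth file is zero-covered; a batch of one contig has loss exactly zero.

# Known limitations

- The SCG table is an input contract; gene calling and HMM search are not
  reimplemented. The synthetic generator is the no-dependency provider.
- The quality estimator is deliberately crude; it ranks partitions well
  but its completeness/contamination values are not comparable to
  CheckM-style estimates.
- The Leiden backend shells out to Python's `leidenalg` (a declared system
  requirement); R-side `igraph` lacks fixed-membership support.
- Training is CPU matrix code: adequate into the tens of thousands of
  contigs, not for million-contig assemblies.
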