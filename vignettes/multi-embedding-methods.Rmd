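---
title: "Locality-sensitive multi-embeddings for edit distance: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locality-sensitive multi-embeddings for edit distance: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Finding all pairs of similar sequences in large DNA datasets — overlap
detection, barcode demultiplexing, clustering — is usually posed in terms of
the edit (Levenshtein) distance, which is biologically meaningful but
expensive: it is quadratic per pair and the all-vs-all comparison is
quadratic in the dataset. Hashing-style approaches (minimizers, LSH) decide
similarity by *collision*, which is binary and loses information; classical
single-vector embeddings of edit distance into normed spaces carry provable
distortion lower bounds.

A *(d1, d2)-locality-sensitive multi-embedding* (LSME) sidesteps both
limits. A function \(g\) maps a length-\(N\) sequence to \(k\) vectors
\(g_1(s), \dots, g_k(s) \in \mathbb{R}^m\), and similarity of a pair
\((s, t)\) is judged by the *minimum component-aligned* Euclidean distance

\[ z(s,t) = \min_{1 \le i \le k} \lVert g_i(s) - g_i(t) \rVert_2 . \]

The target property, for thresholds \(d_1 < d_2\) and a margin
\(\delta > 0\): if \(\mathrm{edit}(s,t) \le d_1\) then \(z(s,t) \le \delta\)
(at least one component pair is close), and if \(\mathrm{edit}(s,t) \ge d_2\)
then \(z(s,t) > \delta\) (all component pairs are far). Distributing the
representational burden over \(k\) components is what lets the scheme evade
the single-embedding distortion bounds: individual components may be poor
global embeddings as long as they complement each other. `z_distance()` is
deliberately *not* a metric — the min over components breaks the triangle
inequality — and the package only ever asserts symmetry, non-negativity and
identity for it.

## Encoder

The embedding function is an inception-style CNN (`lsme_config()`,
`lsme_train()`):

* input: one-hot matrix, 4 nucleotide channels (fixed row order A, C, G, T)
  by \(N\) positions;
* each of `num_layers` (default 2) blocks runs `units` (default 6) parallel
  convolution units; unit \(j\) has window `widths[j]` (default \(j + 1\))
  spanning all input channels, with 'same' zero padding so every unit's
  output keeps spatial length and the outputs can be concatenated
  channel-wise. Each unit applies ReLU and a stride-1 max-pool of window
  `pool` (default 2), shrinking the spatial axis by `pool - 1` per block;
* a single linear layer (no nonlinearity or normalisation after it) maps the
  flattened features to \(k \times m\) numbers, read as the \(k\) embedding
  vectors.

The distinct window widths per unit are the point of the inception design:
small windows see individual edit operations, wide windows see context. Our
reading of the architecture treats the 4 nucleotide rows as channels of a 1-D
convolution along the sequence — the natural DNA-CNN idiom — with stride-1
pooling; where the architecture's published description is ambiguous (pooling
stride, exact kernel geometry) these choices are one consistent
interpretation, fixed here and exposed in the configuration.

## Training

Training pairs are labelled \(y = +1\) if \(d \le d_1\) and \(y = -1\) if
\(d \ge d_2\); pairs in the open gap get no label and never enter a batch.
One pair contributes the hinge contrastive loss

\[ L(s, t, y) = \max\{0,\; (z(s,t) - \delta) \cdot y\}, \]

which is zero exactly when the pair already satisfies the locality-sensitive
goal. Both branches of the Siamese arrangement are literally the same
parameter set — the implementation embeds the concatenated batch
\([s_1..s_B, t_1..t_B]\) with one forward pass. The subgradient flows through
the argmin component only, which is what trains the components to
specialise.

The optimiser is Adam (learning rate \(10^{-3}\), batch 256 by default);
everything stochastic — initialisation (seeded He-scaled normals via an
internal Box–Muller generator, so results do not depend on a C++ standard
library's normal sampler) and epoch shuffling — is derived from the single
`seed` in the configuration, making runs bit-reproducible on a fixed
platform. Arithmetic is double precision throughout, R's native width; the
contrastive hinge is scale-robust enough that single precision would buy
nothing here.

## Pair simulation

The simulator (`build_pair_dataset()`) draws a uniform random sequence,
applies a number of uniform random edits (substitution / insertion /
deletion, one-third each; substitutions always change the character), then
right-pads with random characters or right-truncates back to length \(N\).
Because edits cancel and padding perturbs, the *true* distance of every pair
is recomputed with the DP oracle and the pair is bucketed by that true
distance; the number of applied edits is drawn uniformly from
\([d, d + 2]\) for a still-unfilled target \(d\), and rejection on the
recomputed distance does the rest. Every emitted pair re-verifies
`d == edit_distance(s, t)` by construction, and the TSV reader re-checks it
again on load.

Boundary training follows the active-learning observation that models are
weakest at the decision boundary: the training set holds pairs only at
\(d \in \{d_1 - 1, d_1, d_2, d_2 + 1\}\) (for \((1,3)\):
\(\{0, 1, 3, 4\}\)).

What the simulator emulates is uniform random edit noise — it does not model
platform-specific error structure (homopolymer slippage, quality-dependent
substitution spectra), nor non-uniform sequence composition. Tests passing
on simulated data therefore demonstrate the learning machinery and the
locality-sensitive property under the stated noise model, not performance on
any particular instrument's reads.

## Evaluation

`evaluate_model()` applies the margin rule (similar iff \(z \le \delta\),
boundary inclusive) and scores a labelled pair correct when \(d \le d_1\)
and \(z \le \delta\), or \(d \ge d_2\) and \(z > \delta\). For gapped
settings (\(d_1 < d_2 - 1\)) the rule is undefined on gap distances; those
are reported descriptively (fraction classified similar) and excluded from
the overall aggregate — under the stated rule they could never be correct,
and including them would make near-perfect overall accuracy structurally
impossible. Every reported fraction carries a binomial 95% Wilson interval.
`lsme_sweep()` retrains per value of \(m\), \(\delta\) or \(k\) with all
other settings and seeds fixed.

## Search and curve accounting

`lsme_index()` builds one index per embedding component (never one over the
concatenation: the min-over-components semantics requires component-aligned
distances). The shipped backend is the exact brute-force reference, which is
the normative definition of correctness here; approximate ANN backends are
adapters a user can bolt on behind the same report schema, and none is
bundled. `radius_search()` at radius \(\delta\) over all \(k\) components
returns exactly the pairs the margin rule calls similar; `knn_search()`
retrieves top-\(K\) per component (default \(K = 1\)) and then filters at
\(\delta\).

`build_curve()` performs the repetition-union accounting shared by every
method: point \(i\) aggregates the distinct pairs reported by the first
\(i\) repetitions (components, random minimizer orders, or LSH repetitions —
one code path for all), deduplicating a pair at its smallest repetition
index; a pair is a TP at ground-truth distance \(\le d_1\), an FP at
\(\ge d_2\), and ignored in the gapped "don't care" region. Self-pairs
(equal IDs) are excluded so the query set may coincide with the base set.

## Baselines

* **Minimizers**: per random order (a seeded splitmix64-style hash of the
  k-mer bytes gives the order; seeds derive from one master seed), each
  sequence's seed is its minimal k-mer; two sequences match when they share
  a seed under the same order. Repetitions = orders.
* **CGK embedding**: the classical one-pass randomized walk from edit space
  into Hamming space, output length \(3N\); all sequences of one repetition
  share the pre-drawn bits (shared randomness is what makes the embedded
  Hamming distances comparable). When the walk exhausts the input it emits
  the sentinel `$`, mirroring the original construction's terminal symbol.
* **Bit-sampling LSH**: buckets Hamming-space strings by the characters at
  `num_bits` sampled positions; collision probability for normalized
  distance \(h\) is \((1-h)^{\text{bits}}\) up to the (negligible for long
  strings) without-replacement correction, which the tests verify by Monte
  Carlo.

## Barcode application

The whitelist workflow mirrors single-cell barcode error correction: a
whitelist of valid barcodes is the base set, observed erroneous barcodes are
queries, and a query is recovered when the search assigns it to its true
origin. Real barcode read sets are not bundled; a synthetic generator
reproduces the workflow's statistical skeleton instead:

* `generate_whitelist()` rejection-samples barcodes at pairwise edit
  distance \(\ge\) `min_pairwise_distance` (default profile: 200 barcodes,
  \(N = 16\), separation 5);
* `generate_erroneous_barcodes()` mutates uniform-random origins to an exact
  target distance drawn from a truncated-geometric profile favouring one or
  two edits (sequencing barcode errors are predominantly few); with
  2·d below the whitelist separation, the triangle inequality guarantees
  the nearest entry is the origin, and an ambiguity control regenerates the
  rare query that lands near a different entry, so the recorded origin is a
  valid accuracy reference;
* read multiplicities per unique barcode follow a log-series distribution
  (parameter 0.7) — a standard heavy-tailed abundance shape chosen as an
  assumption, not a claim about any real dataset;
* `classify_barcodes()` assigns each query to its closest surviving match
  and reports recall, precision and the read-multiplicity-weighted recovery
  fraction.

## Problem sizes and numerical choices

The package's own study conditions, used by the tests and by
`scripts/acceptance.R`, are deliberately desk-scale: a \((1,3)\)-sensitive
model at \(N = 16\) with \(k = 4\), \(m = 8\), \(\delta = 10\), trained for
10 epochs on \(5 \times 10^4\) boundary pairs (12 500 per distance in
\(\{0, 1, 3, 4\}\)) and tested on \(10^3\) held-out pairs per boundary
distance; a 200-entry whitelist with 2 000 single-edit queries. At this
scale training runs in minutes on one CPU and reaches well above the 0.75
boundary-accuracy floor asserted in the tests. Larger \(k\), \(m\) (the
full-scale regime uses \(m = 40\), \(\delta = 10\), millions of pairs and
GPU hours) monotonically improve accuracy; the sweep driver exists to
reproduce that shape, not the full-scale numbers.

Numerical details worth knowing:

* the stall guards (default \(10^7\) consecutive rejections for pair
  simulation, \(10^5\) for whitelist growth) turn infeasible requests into
  diagnostics rather than hangs; unreachable distances (\(d > N\)) fail
  before generation;
* `mutate_sequence()` may pass through the empty string when deletions
  outnumber the length; padding restores the length, and the pad/truncate
  count is returned as an attribute because it enters the distance bound
  \(d \le \text{edits} + \text{pads}\);
* ties in KNN ranking break by base order; equal-\(z\) boundary pairs
  classify as similar (`z <= delta`, inclusive);
* curve accounting tolerates reports without distances (minimizer and LSH
  candidates carry `NA`), so one accounting path serves all methods.

## Known limitations

Fixed-length input is intrinsic to the formulation — both sequences must
have length \(N\), and a model is specific to its \((N, d_1, d_2, \delta)\)
setting. The learned property is empirical, not certified: a trained model
approximates the LSME property and the acceptance checks measure how well;
no guarantee extends to distances or sequence compositions far from the
training distribution. The exact-reference index is quadratic per query
batch and is meant as the correctness baseline; large-scale use would swap
in an ANN backend behind the same interface.
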