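# lsme — locality-sensitive multi-embeddings for edit distance

Identifying all pairs of similar DNA sequences under the edit (Levenshtein)
distance is a bottleneck in overlap detection, clustering and barcode
demultiplexing: edit distance is expensive per pair and all-vs-all scales
quadratically. Hash-based bucketing (minimizers, LSH) only answers
"collide or not", while single-vector embeddings of edit distance into
normed spaces carry provable distortion lower bounds.

`lsme` implements a learned *(d1, d2)-locality-sensitive multi-embedding*:
an inception-style convolutional encoder maps each fixed-length sequence
`s` to `k` vectors `g_1(s), ..., g_k(s) ∈ R^m`, trained so that the
component-aligned minimum distance

    z(s, t) = min_i || g_i(s) − g_i(t) ||_2

satisfies `z ≤ δ` whenever `edit(s, t) ≤ d1` and `z > δ` whenever
`edit(s, t) ≥ d2`. Training uses a Siamese arrangement (one shared
parameter set applied to both pair members) with the hinge contrastive loss
`L(s, t, y) = max{0, (z(s,t) − δ)·y}`, on simulated pairs concentrated at
the boundary distances `{d1−1, d1, d2, d2+1}`. The min-over-components rule
turns similarity search into `k` component-aligned Euclidean neighbour
searches, and the package ships the exact-reference index, repetition-union
TP/FP curve accounting, classical baselines (random-order minimizers, the
CGK edit-to-Hamming embedding, bit-sampling Hamming LSH), and a synthetic
cell-barcode whitelist application. The neural encoder, backpropagation and
Adam live in compiled RcppArmadillo code, so scaled-down training runs in
minutes on one CPU.

Intended users: bioinformatics methods developers who need fast
similar-pair identification with controllable (d1, d2) semantics, and
anyone studying learned alternatives to seeding/LSH for edit distance.

## Worked example

Train the desk-scale (1,3)-sensitive model at N = 16 and evaluate it on
held-out boundary pairs:

```r
library(lsme)

train <- label_pairs(build_pair_dataset(16, c(0, 1, 3, 4), 12500, seed = 101), 1, 3)
test  <- label_pairs(build_pair_dataset(16, c(1, 3), 1000, seed = 202), 1, 3)

cfg <- lsme_config(N = 16, k = 4, m = 8, delta = 10, d1 = 1, d2 = 3,
                   epochs = 10, seed = 7)
model <- lsme_train(cfg, train)
model
#> <lsme_model> trained, N=16 (d1,d2)=(1,3) k=4 m=8 delta=10
#>   loss: 4.6326 (initial) -> 0.0010 after 10 epoch(s)

evaluate_model(model, test)
#> <lsme_accuracy> overall 0.9735 on 2000 labelled pairs (delta = 10)
#> # A tibble: 2 × 6
#>       d     n value    lo    hi type
#>   <int> <int> <dbl> <dbl> <dbl> <chr>
#> 1     1  1000 0.985 0.975 0.991 similar
#> 2     3  1000 0.962 0.948 0.972 dissimilar
```

The report reads: of 1000 held-out pairs at edit distance 1, 98.5% fall
within the margin in at least one embedding component (correctly called
similar); of 1000 pairs at distance 3, 96.2% stay outside the margin in all
components. `lo`/`hi` are binomial 95% Wilson intervals.

The same model then recovers erroneous barcodes against a synthetic
whitelist (200 barcodes, length 16, pairwise separation ≥ 5; 2000 queries
at one edit from a random whitelist entry):

```r
wl  <- generate_whitelist(200, 16, 5, seed = 303)
qs  <- generate_erroneous_barcodes(wl, 2000, error_distribution = c(`1` = 1), seed = 404)
classify_barcodes(model, wl, qs, mode = "radius")
#> <barcode_assignment> radius mode, delta = 10
#>   1969/2000 queries assigned; recall 0.9720, precision 0.9873, read-weighted recovery 0.9707
```

A thin command-line front-end over the same functions is installed as
`exec/lsme` (subcommands `simulate`, `train`, `embed`, `evaluate`,
`search`, `curve`, `barcode-simulate`, `barcode-classify`).

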