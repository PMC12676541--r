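# Shared fixtures, built once per test run and memoised.

.lsme_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .lsme_test_cache)) {
    assign(key, build(), envir = .lsme_test_cache)
  }
  get(key, envir = .lsme_test_cache)
}

# The scaled-down study model: a (1,3)-sensitive embedding at N = 16 with
# k = 4 components of dimension m = 8, margin delta = 10, trained on 5e4
# boundary pairs (12500 per distance in {0, 1, 3, 4}).
scaled_config <- function() {
  lsme_config(N = 16, k = 4, m = 8, delta = 10, d1 = 1, d2 = 3,
              epochs = 10, batch_size = 256, learning_rate = 1e-3, seed = 7)
}

scaled_train_set <- function() {
  cache_get("scaled_train", function() {
    label_pairs(build_pair_dataset(16, c(0, 1, 3, 4), 12500, seed = 101), 1, 3)
  })
}

scaled_test_set <- function() {
  cache_get("scaled_test", function() {
    label_pairs(build_pair_dataset(16, c(1, 3), 1000, seed = 202), 1, 3)
  })
}

scaled_model <- function() {
  cache_get("scaled_model", function() lsme_train(scaled_config(), scaled_train_set()))
}

# A tiny untrained model for plumbing tests (embeddings are arbitrary but
# deterministic).
tiny_model <- function(N = 12, k = 3, m = 4, seed = 3) {
  lsme_init(lsme_config(N = N, k = k, m = m, delta = 1, d1 = 1, d2 = 3,
                        seed = seed))
}

# random k x m embedding matrices
random_embedding <- function(k, m) {
  matrix(stats::rnorm(k * m), nrow = k)
}
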