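#' One-hot encode a DNA sequence
#'
#' @param s a single sequence over \{A,C,G,T\}.
#' @param N expected length (defaults to `nchar(s)`); a mismatch is an error.
#' @return a 4 x N numeric matrix with rows in the fixed order A, C, G, T;
#'   every column sums to one.
#' @export
one_hot <- function(s, N = nchar(s)) {
  check_sequences(s, N = N, arg = "s")
  stopifnot(length(s) == 1L)
  idx <- encode_sequences(s, N) + 1L
  m <- matrix(0, nrow = 4, ncol = N, dimnames = list(DNA_ALPHABET, NULL))
  m[cbind(as.integer(idx), seq_len(N))] <- 1
  m
}

new_lsme_model <- function(config, params, training_log, initial_loss, trained) {
  structure(list(config = config, params = params,
                 training_log = training_log, initial_loss = initial_loss,
                 trained = trained),
            class = "lsme_model")
}

#' Initialise an untrained multi-embedding model
#'
#' Weights are drawn from seeded He-scaled normals (linear head
#' Glorot-scaled); biases start at zero. Mostly useful for testing and as the
#' starting point of [lsme_train()].
#'
#' @param config an [lsme_config()].
#' @return an `lsme_model` with an empty training log.
#' @export
lsme_init <- function(config) {
  stopifnot(inherits(config, "lsme_config"))
  params <- lsme_init_cpp(cfg_list(config), config$seed)
  new_lsme_model(config, params,
                 tibble::tibble(epoch = integer(0), loss = numeric(0)),
                 NA_real_, trained = FALSE)
}

#' Train a multi-embedding model with the Siamese contrastive loss
#'
#' Optimises the mean of `max(0, (z(s,t) - delta) * y)` over labelled pairs
#' with Adam, where `z` is the minimum component-wise Euclidean distance
#' between the two multi-embeddings and both Siamese branches share one
#' parameter set. Gap pairs (`y = NA`) are excluded. Reproducible for a fixed
#' `config$seed` on a fixed platform.
#'
#' @param config an [lsme_config()].
#' @param data a labelled `pair_dataset` (see [label_pairs()]).
#' @return a trained `lsme_model`; `training_log` holds the mean per-epoch
#'   loss and `initial_loss` the mean loss before the first update.
#' @export
lsme_train <- function(config, data) {
  stopifnot(inherits(config, "lsme_config"), inherits(data, "pair_dataset"))
  if (data$N != config$N) stop("dataset length N does not match config", call. = FALSE)
  pairs <- data$pairs[!is.na(data$pairs$y), , drop = FALSE]
  if (nrow(pairs) == 0) stop("no labelled pairs to train on", call. = FALSE)
  if (length(unique(pairs$y)) < 2) {
    stop("training data must contain both similar (+1) and dissimilar (-1) pairs",
         call. = FALSE)
  }
  init <- lsme_init_cpp(cfg_list(config), config$seed)
  fit <- lsme_train_cpp(init, cfg_list(config),
                        encode_sequences(pairs$s, config$N),
                        encode_sequences(pairs$t, config$N),
                        as.numeric(pairs$y),
                        config$epochs, config$batch_size,
                        config$learning_rate, config$seed)
  new_lsme_model(config, fit$params,
                 tibble::tibble(epoch = seq_len(config$epochs),
                                loss = as.numeric(fit$epoch_loss)),
                 fit$initial_loss, trained = TRUE)
}

#' Embed sequences into k vectors of dimension m
#'
#' Deterministic inference pass of the encoder; embedding a sequence alone
#' gives the same vectors as embedding it inside any batch.
#'
#' @param model an `lsme_model`.
#' @param seqs character vector of sequences of length `model$config$N`.
#' @return numeric array of dimension `c(k, m, length(seqs))`; slice
#'   `[, , i]` holds the k embedding vectors of sequence i as rows.
#' @export
lsme_embed <- function(model, seqs) {
  stopifnot(inherits(model, "lsme_model"))
  cfg <- model$config
  check_sequences(seqs, N = cfg$N, arg = "seqs")
  E <- lsme_forward_cpp(model$params, cfg_list(cfg), encode_sequences(seqs, cfg$N))
  # head rows store component i in block [ (i-1)*m + 1 .. i*m ]
  out <- aperm(array(E, dim = c(cfg$m, cfg$k, length(seqs))), c(2, 1, 3))
  dimnames(out) <- list(NULL, NULL, names(seqs))
  out
}

#' Minimum component-wise Euclidean distance between two multi-embeddings
#'
#' `z(a, b) = min_i || a_i - b_i ||_2` with component i of `a` compared only
#' with component i of `b`. This is the latent-space statistic the margin
#' `delta` thresholds; it is symmetric and non-negative but deliberately not
#' a metric (the min over components breaks the triangle inequality).
#'
#' @param a,b k x m matrices (rows = embedding components).
#' @return a non-negative scalar.
#' @export
z_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    stop("embeddings must share the same k x m shape", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("embeddings must be finite", call. = FALSE)
  }
  sqrt(min(rowSums((a - b)^2)))
}

#' Contrastive hinge loss for one labelled pair
#'
#' `L = max(0, (z(a, b) - delta) * y)`: zero exactly when the
#' locality-sensitive goal is already met for the pair (similar pairs inside
#' the margin, dissimilar pairs outside).
#'
#' @param a,b k x m embedding matrices.
#' @param y label, `+1` (similar) or `-1` (dissimilar); gap pairs are
#'   rejected.
#' @param delta margin.
#' @return a non-negative scalar.
#' @export
contrastive_loss <- function(a, b, y, delta) {
  if (length(y) != 1 || is.na(y) || !(y %in% c(-1, 1))) {
    stop("`y` must be +1 or -1; gap pairs never enter the loss", call. = FALSE)
  }
  stopifnot(delta > 0)
  max(0, (z_distance(a, b) - delta) * y)
}

# z for many pairs at once from two (k, m, n) arrays
z_distance_batch <- function(Ea, Eb) {
  ss <- apply((Ea - Eb)^2, c(1, 3), sum) # k x n squared component distances
  sqrt(apply(ss, 2, min))
}

#' Save or load a model checkpoint
#'
#' Single-file RDS checkpoint holding the configuration, weights and training
#' log; the round-trip preserves embeddings bit-for-bit.
#'
#' @param model an `lsme_model`.
#' @param path checkpoint path.
#' @export
save_lsme <- function(model, path) {
  stopifnot(inherits(model, "lsme_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_lsme
#' @export
load_lsme <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lsme_model")) stop("not an lsme checkpoint", call. = FALSE)
  model
}

#' @export
print.lsme_model <- function(x, ...) {
  cat(sprintf("<lsme_model> %s, N=%d (d1,d2)=(%d,%d) k=%d m=%d delta=%g\n",
              if (x$trained) "trained" else "untrained",
              x$config$N, x$config$d1, x$config$d2, x$config$k, x$config$m,
              x$config$delta))
  if (x$trained) {
    cat(sprintf("  loss: %.4f (initial) -> %.4f after %d epoch(s)\n",
                x$initial_loss, x$training_log$loss[nrow(x$training_log)],
                nrow(x$training_log)))
  }
  invisible(x)
}
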