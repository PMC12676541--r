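#' Configuration of a locality-sensitive multi-embedding model
#'
#' Collects every hyperparameter of the encoder and its training run. The
#' encoder stacks `num_layers` inception blocks; each block applies `units`
#' parallel convolutions (unit j spans `widths[j]` sequence positions over all
#' input channels, 'same' zero padding), a ReLU, and a stride-1 max-pool of
#' window `pool`, then concatenates the unit outputs channel-wise. A single
#' linear layer maps the flattened features to `k * m` values, read as `k`
#' embedding vectors of dimension `m`.
#'
#' @param N sequence length.
#' @param k number of embedding vectors per sequence.
#' @param m embedding dimension.
#' @param delta Euclidean margin separating similar from dissimilar pairs.
#' @param d1,d2 edit-distance thresholds (`d1 < d2`): pairs with distance at
#'   most `d1` are similar, at least `d2` dissimilar.
#' @param num_layers number of inception blocks.
#' @param units parallel convolution units per block.
#' @param channels output channels per unit.
#' @param pool max-pool window (stride 1).
#' @param widths per-unit convolution window; default `(1:units) + 1` gives
#'   each unit a distinct multi-scale window.
#' @param epochs,batch_size,learning_rate Adam optimisation settings.
#' @param seed training seed controlling initialisation and shuffling.
#' @return an `lsme_config` object.
#' @export
lsme_config <- function(N, k = 4, m = 8, delta = 10, d1, d2,
                        num_layers = 2, units = 6, channels = 8, pool = 2,
                        widths = NULL, epochs = 10, batch_size = 256,
                        learning_rate = 1e-3, seed = 1L) {
  if (is.null(widths)) widths <- seq_len(units) + 1L
  stopifnot(N >= 2, k >= 1, m >= 1, delta > 0, num_layers >= 1, units >= 1,
            channels >= 1, pool >= 1, length(widths) == units,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  if (!(d1 < d2)) stop("`d1` must be strictly less than `d2`", call. = FALSE)
  if (d1 < 0 || d2 > N) stop("thresholds must satisfy 0 <= d1 < d2 <= N", call. = FALSE)
  if (N - num_layers * (pool - 1) < 1) {
    stop("pool window too large: no sequence axis left after pooling", call. = FALSE)
  }
  structure(
    list(N = as.integer(N), k = as.integer(k), m = as.integer(m),
         delta = as.numeric(delta), d1 = as.integer(d1), d2 = as.integer(d2),
         num_layers = as.integer(num_layers), units = as.integer(units),
         channels = as.integer(channels), pool = as.integer(pool),
         widths = as.integer(widths), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = as.numeric(learning_rate), seed = as.integer(seed)),
    class = "lsme_config")
}

# plain list for the C++ core
cfg_list <- function(config) {
  unclass(config)
}

#' @export
print.lsme_config <- function(x, ...) {
  cat(sprintf(
    "<lsme_config> N=%d (d1,d2)=(%d,%d) k=%d m=%d delta=%g\n", x$N, x$d1,
    x$d2, x$k, x$m, x$delta))
  cat(sprintf("  encoder: %d inception layer(s), %d units (widths %s), %d channels, pool %d\n",
              x$num_layers, x$units, paste(x$widths, collapse = "/"),
              x$channels, x$pool))
  cat(sprintf("  training: %d epoch(s), batch %d, lr %g, seed %d\n",
              x$epochs, x$batch_size, x$learning_rate, x$seed))
  invisible(x)
}
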