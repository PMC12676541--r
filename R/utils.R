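DNA_ALPHABET <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(seed, index, salt = 1L) {
  ((as.double(seed) %% 2147483647) * 48271 + as.double(index) * 7919 +
     as.double(salt) * 104729) %% 2147483647 + 1
}

check_sequences <- function(x, N = NULL, arg = "sequences") {
  if (!is.character(x) || length(x) == 0) {
    stop(sprintf("`%s` must be a non-empty character vector", arg), call. = FALSE)
  }
  if (any(grepl("[^ACGT]", x))) {
    stop(sprintf("`%s` contains characters outside {A,C,G,T}", arg), call. = FALSE)
  }
  if (!is.null(N) && any(nchar(x) != N)) {
    stop(sprintf("`%s` must all have length %d", arg, N), call. = FALSE)
  }
  invisible(x)
}

# 0-based integer encoding (A=0, C=1, G=2, T=3), one column per sequence.
encode_sequences <- function(x, N) {
  m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                    DNA_ALPHABET) - 1L, nrow = N)
  storage.mode(m) <- "integer"
  m
}

random_dna <- function(n, length) {
  ch <- sample(DNA_ALPHABET, n * length, replace = TRUE)
  if (n == 1L) return(paste(ch, collapse = ""))
  apply(matrix(ch, nrow = length), 2, paste, collapse = "")
}

#' Generate uniform random DNA sequences
#'
#' Draws sequences with i.i.d. uniform characters over \{A,C,G,T\}.
#'
#' @param n number of sequences.
#' @param length sequence length N.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return character vector of `n` sequences.
#' @export
random_sequences <- function(n, length, seed = NULL) {
  stopifnot(n >= 1, length >= 1)
  with_seed(seed, random_dna(n, length))
}

# Wilson 95% score interval for a binomial fraction.
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, mid - half), min(1, mid + half))
}
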