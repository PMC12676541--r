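#' Random-order minimizer scheme
#'
#' Holds the k-mer size and the seeds of `num_orders` independent
#' pseudo-random total orders on k-mers; under each order a sequence's seed
#' is its minimal k-mer.
#'
#' @param kmer_size k-mer length.
#' @param num_orders number of random orders (repetitions).
#' @param seed master seed from which the per-order seeds are derived.
#' @return a `minimizer_scheme`.
#' @export
minimizer_scheme <- function(kmer_size, num_orders = 20, seed = 1L) {
  stopifnot(kmer_size >= 1, num_orders >= 1)
  structure(
    list(kmer_size = as.integer(kmer_size),
         num_orders = as.integer(num_orders),
         order_seeds = as.integer(round(
           vapply(seq_len(num_orders), function(i) derive_seed(seed, i, 11L),
                  numeric(1))))),
    class = "minimizer_scheme")
}

#' Minimizer of a sequence under a (seeded) total order
#'
#' Enumerates all k-mers of each sequence and returns the minimum under the
#' pseudo-random order induced by a seeded hash of the k-mer bytes;
#' `order_seed = NULL` uses the plain lexicographic order. Duplicate k-mers
#' collapse to one candidate, so no tie-break on the order is needed.
#'
#' @param s character vector of sequences.
#' @param kmer_size k-mer length, at most the sequence length.
#' @param order_seed integer seed of the random order, or `NULL` for
#'   lexicographic.
#' @return character vector of minimizing k-mers.
#' @export
minimizer_seed <- function(s, kmer_size, order_seed = NULL) {
  check_sequences(s, arg = "s")
  if (any(nchar(s) < kmer_size)) {
    stop("`kmer_size` exceeds a sequence length", call. = FALSE)
  }
  vapply(s, function(x) {
    kmers <- unique(substring(x, seq_len(nchar(x) - kmer_size + 1L),
                              seq_len(nchar(x) - kmer_size + 1L) + kmer_size - 1L))
    if (is.null(order_seed)) {
      min(kmers)
    } else {
      kmers[which.min(kmer_rank_cpp(kmers, as.numeric(order_seed)))]
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Do two sequences share a minimizer within the first r orders?
#'
#' True iff some order index `i <= repetitions` gives both sequences the same
#' minimal k-mer (seed equality within the same order). Monotone in
#' `repetitions` by construction.
#'
#' @param a,b sequences.
#' @param scheme a [minimizer_scheme()].
#' @param repetitions number of orders to use, at most `scheme$num_orders`.
#' @return logical.
#' @export
minimizer_match <- function(a, b, scheme, repetitions = scheme$num_orders) {
  stopifnot(inherits(scheme, "minimizer_scheme"),
            repetitions <= scheme$num_orders)
  for (i in seq_len(repetitions)) {
    os <- scheme$order_seeds[i]
    if (minimizer_seed(a, scheme$kmer_size, os) ==
        minimizer_seed(b, scheme$kmer_size, os)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Candidate pairs reported by minimizer seeding
#'
#' For each random order, reports every (query, base) pair whose minimizers
#' under that order coincide; the order index becomes the repetition index so
#' the result feeds [build_curve()] directly.
#'
#' @param queries,base named character vectors of sequences.
#' @param scheme a [minimizer_scheme()].
#' @param repetitions number of orders to evaluate.
#' @return tibble with columns `query_id`, `base_id`, `embedding_distance`
#'   (`NA`; minimizers report no distance), `repetition_index`.
#' @export
minimizer_candidates <- function(queries, base, scheme,
                                 repetitions = scheme$num_orders) {
  stopifnot(inherits(scheme, "minimizer_scheme"),
            repetitions <= scheme$num_orders)
  qid <- ids_of(queries, "q")
  bid <- ids_of(base, "b")
  out <- list()
  for (i in seq_len(repetitions)) {
    os <- scheme$order_seeds[i]
    sq <- minimizer_seed(queries, scheme$kmer_size, os)
    sb <- minimizer_seed(base, scheme$kmer_size, os)
    shared <- intersect(unique(sq), unique(sb))
    for (seed_val in shared) {
      qs <- which(sq == seed_val)
      bs <- which(sb == seed_val)
      grid <- expand.grid(q = qs, b = bs)
      keep <- qid[grid$q] != bid[grid$b]
      if (any(keep)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          query_id = qid[grid$q[keep]], base_id = bid[grid$b[keep]],
          embedding_distance = NA_real_, repetition_index = i)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(query_id = character(0), base_id = character(0),
                          embedding_distance = numeric(0),
                          repetition_index = integer(0)))
  }
  do.call(rbind, out)
}

#' CGK randomized embedding from edit space into Hamming space
#'
#' One-pass random walk: at output step j the current input character is
#' emitted and the input pointer advances iff a pre-drawn uniform bit for
#' (step, character) is one; once the input is exhausted a fixed sentinel
#' `"$"` is emitted. The output has length exactly `3 * N`. All sequences
#' embedded with the same `seed` share the random bits, which is what makes
#' Hamming distances between their embeddings meaningful.
#'
#' @param s character vector of sequences, all of one length N.
#' @param seed integer seed of the repetition (shared randomness).
#' @return character vector of 3N-character strings over \{A,C,G,T,$\}.
#' @export
cgk_embed <- function(s, seed) {
  check_sequences(s, arg = "s")
  N <- unique(nchar(s))
  if (length(N) != 1) stop("all sequences must share one length", call. = FALSE)
  n <- length(s)
  M <- encode_sequences(s, N) + 1L # N x n, 1-based codes
  bits <- with_seed(seed,
                    matrix(sample(0:1, 3L * N * 4L, replace = TRUE), nrow = 3L * N))
  out <- matrix("$", nrow = 3L * N, ncol = n)
  ptr <- rep(1L, n)
  for (j in seq_len(3L * N)) {
    active <- ptr <= N
    if (any(active)) {
      code <- M[cbind(ptr[active], which(active))]
      out[j, active] <- DNA_ALPHABET[code]
      ptr[active] <- ptr[active] + bits[cbind(j, code)]
    }
  }
  apply(out, 2, paste, collapse = "")
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character vectors (element-wise comparison).
#' @return integer vector of mismatch counts.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(length(a) == length(b) || length(a) == 1 || length(b) == 1)
  if (any(nchar(a) != nchar(b))) stop("strings must have equal length", call. = FALSE)
  mapply(function(x, y) sum(x != y),
         strsplit(a, "", fixed = TRUE), strsplit(b, "", fixed = TRUE),
         USE.NAMES = FALSE)
}

#' Bit-sampling LSH for Hamming space
#'
#' Buckets strings by their characters at a random subset of positions; two
#' strings collide iff they agree on every sampled position, which for
#' uniformly sampled positions happens with probability
#' `(1 - h)^num_bits` for normalized Hamming distance `h`.
#'
#' @param num_bits number of positions to sample (0 gives the trivial bucket
#'   everything collides in).
#' @param input_length length of the strings to be bucketed.
#' @param seed integer seed.
#' @return a `bit_sampling_lsh` with distinct `positions`.
#' @export
bit_sampling_lsh <- function(num_bits, input_length, seed = 1L) {
  stopifnot(num_bits >= 0, num_bits <= input_length)
  positions <- if (num_bits == 0) integer(0) else
    with_seed(seed, sort(sample.int(input_length, num_bits)))
  structure(list(num_bits = as.integer(num_bits),
                 input_length = as.integer(input_length),
                 positions = positions, seed = seed),
            class = "bit_sampling_lsh")
}

#' @param h character vector of Hamming-space strings.
#' @param lsh a [bit_sampling_lsh()].
#' @rdname bit_sampling_lsh
#' @return `lsh_bucket()` returns the bucket key of each string (its
#'   characters at the sampled positions, concatenated).
#' @export
lsh_bucket <- function(h, lsh) {
  stopifnot(inherits(lsh, "bit_sampling_lsh"))
  if (any(nchar(h) < lsh$input_length)) {
    stop("string shorter than the LSH input length", call. = FALSE)
  }
  if (lsh$num_bits == 0) return(rep("", length(h)))
  vapply(h, function(x) paste(substring(x, lsh$positions, lsh$positions),
                              collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Candidate pairs from CGK embedding + bit-sampling LSH
#'
#' Per repetition: embeds queries and base with one shared CGK seed, buckets
#' both with one bit-sampling LSH over the 3N-length embeddings, and reports
#' every (query, base) pair falling in a common bucket.
#'
#' @param queries,base named sequence vectors of one common length.
#' @param num_bits sampled positions per repetition.
#' @param repetitions number of independent repetitions.
#' @param seed master seed; per-repetition CGK and LSH seeds are derived.
#' @return tibble in the [build_curve()] report schema.
#' @export
cgk_lsh_candidates <- function(queries, base, num_bits, repetitions = 20,
                               seed = 1L) {
  check_sequences(queries, arg = "queries")
  check_sequences(base, arg = "base")
  N <- unique(nchar(c(queries, base)))
  if (length(N) != 1) stop("all sequences must share one length", call. = FALSE)
  qid <- ids_of(queries, "q")
  bid <- ids_of(base, "b")
  out <- list()
  for (i in seq_len(repetitions)) {
    cgk_seed <- derive_seed(seed, i, 101L)
    hq <- cgk_embed(queries, cgk_seed)
    hb <- cgk_embed(base, cgk_seed)
    lsh <- bit_sampling_lsh(num_bits, 3L * N, derive_seed(seed, i, 211L))
    kq <- lsh_bucket(hq, lsh)
    kb <- lsh_bucket(hb, lsh)
    for (key in intersect(unique(kq), unique(kb))) {
      grid <- expand.grid(q = which(kq == key), b = which(kb == key))
      keep <- qid[grid$q] != bid[grid$b]
      if (any(keep)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          query_id = qid[grid$q[keep]], base_id = bid[grid$b[keep]],
          embedding_distance = NA_real_, repetition_index = i)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(query_id = character(0), base_id = character(0),
                          embedding_distance = numeric(0),
                          repetition_index = integer(0)))
  }
  do.call(rbind, out)
}

ids_of <- function(x, prefix) {
  if (!is.null(names(x)) && all(nzchar(names(x)))) names(x)
  else paste0(prefix, seq_along(x))
}
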