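#' Apply random edits to a sequence
#'
#' Applies `num_edits` sequential edits, each drawn uniformly from
#' substitution, insertion and deletion at a uniformly random valid position
#' (one-third probability each when all three are valid). Substitutions always
#' change the character (uniform over the other three); insertions draw a
#' uniform character. The result is then padded on the right with uniform
#' random characters, or truncated on the right, so its length equals the
#' length of `s`. The true edit distance of the output to `s` must be
#' recomputed with [edit_distance()]: edits can cancel and padding can add or
#' remove differences.
#'
#' @param s a single sequence over \{A,C,G,T\}.
#' @param num_edits non-negative number of edits to apply.
#' @param seed optional integer seed.
#' @return the mutated sequence (same length as `s`), with attribute `n_pad`
#'   giving the number of characters padded or truncated to restore length.
#' @export
mutate_sequence <- function(s, num_edits, seed = NULL) {
  check_sequences(s, arg = "s")
  stopifnot(length(s) == 1L, num_edits >= 0)
  with_seed(seed, {
    N <- nchar(s)
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    for (e in seq_len(num_edits)) {
      L <- length(x)
      op <- if (L == 0L) 2L else sample.int(3L, 1L) # only insertion on empty
      if (op == 1L) {
        pos <- sample.int(L, 1L)
        x[pos] <- sample(setdiff(DNA_ALPHABET, x[pos]), 1L)
      } else if (op == 2L) {
        pos <- sample.int(L + 1L, 1L)
        x <- append(x, sample(DNA_ALPHABET, 1L), after = pos - 1L)
      } else {
        pos <- sample.int(L, 1L)
        x <- x[-pos]
      }
    }
    n_pad <- abs(length(x) - N)
    if (length(x) > N) {
      x <- x[seq_len(N)]
    } else if (length(x) < N) {
      x <- c(x, sample(DNA_ALPHABET, N - length(x), replace = TRUE))
    }
    structure(paste(x, collapse = ""), n_pad = n_pad)
  })
}

#' Simulate a pair dataset bucketed by exact edit distance
#'
#' Repeatedly draws a uniform random sequence `s` of length `N`, mutates it
#' with a number of edits sampled uniformly from `[d, d + 2]` for a currently
#' unfilled target distance `d` (overshooting compensates for edit
#' cancellation), recomputes the true edit distance of the pair, and accepts
#' the pair into the bucket for that distance if the bucket is still under
#' quota. Generation stops when every requested bucket holds exactly
#' `pairs_per_distance` pairs. Deterministic for a fixed `seed`.
#'
#' @param N sequence length.
#' @param distances integer vector of requested edit distances (each `<= N`).
#' @param pairs_per_distance bucket quota.
#' @param seed integer seed (required for a reproducible dataset).
#' @param stall_limit abort with a diagnostic after this many consecutive
#'   rejections (guards against infeasible configurations).
#' @return a `pair_dataset`: list with `pairs` (tibble of `s`, `t`, `d`, `y`),
#'   `by_distance` (indices per distance), `N` and `seed`. Labels `y` are `NA`
#'   until [label_pairs()] is applied.
#' @seealso [label_pairs()], [mutate_sequence()]
#' @export
build_pair_dataset <- function(N, distances, pairs_per_distance, seed = NULL,
                               stall_limit = 1e7) {
  distances <- sort(unique(as.integer(distances)))
  if (length(distances) == 0) stop("`distances` must be non-empty", call. = FALSE)
  if (any(distances < 0) || any(distances > N)) {
    stop("requested distances must lie in [0, N]", call. = FALSE)
  }
  stopifnot(pairs_per_distance >= 1)
  with_seed(seed, {
    need <- stats::setNames(rep(pairs_per_distance, length(distances)),
                            as.character(distances))
    ss <- tt <- vector("list", length(distances))
    names(ss) <- names(tt) <- names(need)
    stalled <- 0L
    cycle <- 0L
    while (any(need > 0)) {
      open <- names(need)[need > 0]
      target <- as.integer(open[cycle %% length(open) + 1L])
      cycle <- cycle + 1L
      s <- random_dna(1L, N)
      ne <- sample(target:(target + 2L), 1L)
      t <- as.character(mutate_sequence(s, ne))
      d <- as.character(edit_dist_pair_cpp(s, t))
      if (!is.na(need[d]) && need[d] > 0) {
        ss[[d]][[length(ss[[d]]) + 1L]] <- s
        tt[[d]][[length(tt[[d]]) + 1L]] <- t
        need[d] <- need[d] - 1L
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
        if (stalled >= stall_limit) {
          stop(sprintf(
            "pair simulation stalled: %d consecutive rejections; unfilled buckets: %s",
            stalled, paste(open, collapse = ", ")), call. = FALSE)
        }
      }
    }
    pairs <- tibble::tibble(
      s = unlist(ss, use.names = FALSE),
      t = unlist(tt, use.names = FALSE),
      d = rep(distances, each = pairs_per_distance),
      y = NA_integer_
    )
    structure(
      list(pairs = pairs,
           by_distance = split(seq_len(nrow(pairs)), pairs$d),
           N = as.integer(N),
           seed = seed,
           d1 = NULL, d2 = NULL),
      class = "pair_dataset")
  })
}

#' Label pairs for (d1, d2)-sensitive training
#'
#' Assigns `y = +1` to pairs with `d <= d1`, `y = -1` to pairs with
#' `d >= d2`, and `NA` to pairs in the open gap `d1 < d < d2`; gap pairs are
#' excluded from training batches and from overall accuracy.
#'
#' @param ds a `pair_dataset`.
#' @param d1,d2 distance thresholds, `d1 < d2`.
#' @return the dataset with labels and thresholds attached.
#' @export
label_pairs <- function(ds, d1, d2) {
  stopifnot(inherits(ds, "pair_dataset"))
  if (!(d1 < d2)) stop("`d1` must be strictly less than `d2`", call. = FALSE)
  ds$pairs$y <- ifelse(ds$pairs$d <= d1, 1L,
                       ifelse(ds$pairs$d >= d2, -1L, NA_integer_))
  ds$d1 <- as.integer(d1)
  ds$d2 <- as.integer(d2)
  ds
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset> %d pairs, N = %d\n", nrow(x$pairs), x$N))
  tab <- vapply(x$by_distance, length, integer(1))
  cat("  pairs per distance:",
      paste(sprintf("d=%s: %d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$d1)) {
    cat(sprintf("  labelled for (d1, d2) = (%d, %d)\n", x$d1, x$d2))
  }
  invisible(x)
}

#' Read and write pair datasets as TSV
#'
#' Four columns: `s`, `t`, `d`, `y` (`y` empty for unlabelled or gap pairs).
#'
#' @param ds a `pair_dataset`.
#' @param path file path.
#' @return `read_pairs_tsv()` returns a `pair_dataset` (with every stored
#'   distance re-verified against the dynamic-programming oracle).
#' @export
write_pairs_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "pair_dataset"))
  write.table(ds$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "integer", "integer"))
  check_sequences(df$s, arg = "s")
  check_sequences(df$t, arg = "t")
  d <- edit_dist_pair_cpp(df$s, df$t)
  if (!identical(d, df$d)) {
    stop("stored distances disagree with the DP oracle; file is corrupted",
         call. = FALSE)
  }
  N <- unique(nchar(df$s))
  if (length(N) != 1) stop("sequences in a dataset must share one length", call. = FALSE)
  structure(
    list(pairs = tibble::as_tibble(df),
         by_distance = split(seq_len(nrow(df)), df$d),
         N = as.integer(N), seed = NULL, d1 = NULL, d2 = NULL),
    class = "pair_dataset")
}

#' Export the unique sequences of a dataset as FASTA
#'
#' Headers carry the index of the first pair each sequence occurs in.
#'
#' @param ds a `pair_dataset`.
#' @param path output file.
#' @export
write_dataset_fasta <- function(ds, path) {
  stopifnot(inherits(ds, "pair_dataset"))
  seqs <- c(ds$pairs$s, ds$pairs$t)
  first <- !duplicated(seqs)
  ids <- sprintf("seq%06d pair=%d", seq_len(sum(first)),
                 ((which(first) - 1L) %% nrow(ds$pairs)) + 1L)
  write_fasta(stats::setNames(seqs[first], ids), path)
  invisible(path)
}

write_fasta <- function(seqs, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  }
  invisible(path)
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    stats::setNames(
      vapply(split(lines[!hdr], cumsum(hdr)[!hdr]), paste, character(1),
             collapse = ""),
      ids)
  }
}
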