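#' Synthetic barcode whitelist
#'
#' Rejection-samples random barcodes, keeping each candidate only if its edit
#' distance to every barcode already kept is at least
#' `min_pairwise_distance`. A well-separated whitelist is what makes
#' error correction well-posed: a query at distance `d` from its origin with
#' `2 d < min_pairwise_distance` is guaranteed (triangle inequality) to be
#' closer to its origin than to any other entry.
#'
#' @param size number of barcodes.
#' @param N barcode length.
#' @param min_pairwise_distance minimum edit distance between any two kept
#'   barcodes.
#' @param seed integer seed.
#' @param stall_limit abort after this many consecutive rejected candidates.
#' @return a `barcode_whitelist`: named barcodes (`bc0001`, ...) plus the
#'   generation settings.
#' @export
generate_whitelist <- function(size, N, min_pairwise_distance, seed = NULL,
                               stall_limit = 1e5) {
  stopifnot(size >= 1, min_pairwise_distance >= 1, min_pairwise_distance <= N)
  with_seed(seed, {
    kept <- character(0)
    stalled <- 0L
    while (length(kept) < size) {
      cand <- random_dna(1L, N)
      ok <- length(kept) == 0 ||
        min(edit_dist_cross_cpp(cand, kept)) >= min_pairwise_distance
      if (ok) {
        kept <- c(kept, cand)
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
        if (stalled >= stall_limit) {
          stop(sprintf(
            "whitelist generation infeasible: %d consecutive rejections at %d/%d barcodes",
            stalled, length(kept), size), call. = FALSE)
        }
      }
    }
    structure(
      list(barcodes = stats::setNames(kept, sprintf("bc%04d", seq_len(size))),
           N = as.integer(N),
           min_pairwise_distance = as.integer(min_pairwise_distance),
           seed = seed),
      class = "barcode_whitelist")
  })
}

#' Truncated geometric error-distance distribution
#'
#' Probability proportional to `p * (1 - p)^(d - 1)` on `d = 1..max_d`;
#' the default profile concentrates errors on one or two edits, the regime
#' sequencing barcode errors live in.
#'
#' @param p geometric parameter in (0, 1).
#' @param max_d largest error distance.
#' @return named probability vector summing to one.
#' @export
geometric_error_distribution <- function(p = 0.6, max_d = 4) {
  stopifnot(p > 0, p < 1, max_d >= 1)
  w <- p * (1 - p)^(seq_len(max_d) - 1)
  stats::setNames(w / sum(w), as.character(seq_len(max_d)))
}

# log-series read-count distribution: P(X = j) = -p^j / (j * log(1 - p))
rlogseries <- function(n, p = 0.7, max_count = 1000L) {
  j <- seq_len(max_count)
  pmf <- p^j / j
  sample(j, n, replace = TRUE, prob = pmf / sum(pmf))
}

#' Simulate erroneous copies of whitelist barcodes
#'
#' Each query picks a uniform whitelist origin, draws a target edit distance
#' from `error_distribution`, and mutates the origin (rejection on the
#' recomputed true distance) until the distance is exactly the target. With
#' `ambiguity_control` (default), a query landing within distance `d - 1` of
#' a *different* whitelist entry is regenerated, so the recorded true origin
#' is a valid accuracy reference. Per-query read multiplicities follow a
#' log-series distribution.
#'
#' @param whitelist a `barcode_whitelist` from `generate_whitelist()`.
#' @param n_queries number of unique erroneous barcodes.
#' @param error_distribution named probability vector over target distances
#'   (names are the distances).
#' @param seed integer seed.
#' @param ambiguity_control regenerate ambiguous queries?
#' @param logseries_p log-series parameter for read multiplicities.
#' @return a `barcode_queries`: `observed` (named sequences), `true_origin`
#'   (whitelist ID per query), `target_d`, `multiplicity`.
#' @export
generate_erroneous_barcodes <- function(whitelist, n_queries,
                                        error_distribution = geometric_error_distribution(),
                                        seed = NULL, ambiguity_control = TRUE,
                                        logseries_p = 0.7) {
  stopifnot(inherits(whitelist, "barcode_whitelist"), n_queries >= 1)
  if (abs(sum(error_distribution) - 1) > 1e-8 || is.null(names(error_distribution))) {
    stop("`error_distribution` must be a named vector summing to one", call. = FALSE)
  }
  ds <- as.integer(names(error_distribution))
  if (any(ds < 1) || any(ds > whitelist$N)) {
    stop("error distances must lie in 1..N", call. = FALSE)
  }
  wl <- whitelist$barcodes
  with_seed(seed, {
    observed <- character(n_queries)
    origin <- character(n_queries)
    target <- integer(n_queries)
    for (q in seq_len(n_queries)) {
      repeat {
        oi <- sample.int(length(wl), 1L)
        d <- ds[sample.int(length(ds), 1L, prob = error_distribution)]
        t <- NULL
        for (attempt in 1:1000) {
          cand <- as.character(mutate_sequence(wl[[oi]], sample(d:(d + 2L), 1L)))
          if (edit_dist_pair_cpp(wl[[oi]], cand) == d) { t <- cand; break }
        }
        if (is.null(t)) {
          stop("erroneous-barcode simulation stalled", call. = FALSE)
        }
        if (ambiguity_control && length(wl) > 1L) {
          other <- min(edit_dist_cross_cpp(t, wl[-oi]))
          if (other <= d - 1L) next # ambiguous: closer to a non-origin entry
        }
        observed[q] <- t
        origin[q] <- names(wl)[oi]
        target[q] <- d
        break
      }
    }
    structure(
      list(observed = stats::setNames(observed, sprintf("q%05d", seq_len(n_queries))),
           true_origin = origin, target_d = target,
           multiplicity = rlogseries(n_queries, logseries_p),
           N = whitelist$N, seed = seed),
      class = "barcode_queries")
  })
}

#' Match erroneous barcodes against a whitelist
#'
#' Embeds whitelist and queries with a trained model, runs radius (all
#' entries within `delta`) or KNN (top-K then delta filter) search over the
#' exact-reference index, and assigns each query to its closest surviving
#' whitelist entry. When the true origins are known (synthetic data) each
#' assignment is flagged correct/incorrect and summary rates are computed,
#' weighting unique barcodes by read multiplicity for the recovered-read
#' fraction.
#'
#' @param model a trained `lsme_model` with `config$N` equal to the barcode
#'   length.
#' @param whitelist a `barcode_whitelist`.
#' @param queries a `barcode_queries` (or named character vector).
#' @param mode `"radius"` or `"knn"`.
#' @param K neighbours per component in KNN mode.
#' @param delta margin; defaults to the model margin.
#' @return a `barcode_assignment`: `reports` (all surviving matches),
#'   `assignments` (per query: `assigned_id`, `embedding_distance`,
#'   `true_origin`, `correct`), and `summary` (recall, precision,
#'   read-weighted recovery).
#' @export
classify_barcodes <- function(model, whitelist, queries,
                              mode = c("radius", "knn"), K = 1,
                              delta = model$config$delta) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "lsme_model"), inherits(whitelist, "barcode_whitelist"))
  if (model$config$N != whitelist$N) {
    stop("model N does not match barcode length", call. = FALSE)
  }
  obs <- if (inherits(queries, "barcode_queries")) queries$observed else queries
  truth <- if (inherits(queries, "barcode_queries")) queries$true_origin else NULL
  mult <- if (inherits(queries, "barcode_queries")) queries$multiplicity else
    rep(1L, length(obs))
  index <- lsme_index(model, whitelist$barcodes)
  reports <- if (mode == "radius") {
    radius_search(index, obs, delta = delta)
  } else {
    knn_search(index, obs, K = K, delta = delta)
  }
  qid <- ids_of(obs, "q")
  assigned <- rep(NA_character_, length(obs))
  adist <- rep(NA_real_, length(obs))
  if (nrow(reports)) {
    ord <- order(match(reports$query_id, qid), reports$embedding_distance,
                 match(reports$base_id, names(whitelist$barcodes)))
    best <- reports[ord, ][!duplicated(reports$query_id[ord]), ]
    hit <- match(best$query_id, qid)
    assigned[hit] <- best$base_id
    adist[hit] <- best$embedding_distance
  }
  assignments <- tibble::tibble(
    query_id = qid, assigned_id = assigned, embedding_distance = adist,
    true_origin = if (is.null(truth)) NA_character_ else truth,
    correct = if (is.null(truth)) NA else !is.na(assigned) & assigned == truth)
  summary <- list(
    n_queries = length(obs),
    n_assigned = sum(!is.na(assigned)),
    recall = if (is.null(truth)) NA_real_ else mean(assignments$correct),
    precision = if (is.null(truth)) NA_real_ else {
      n_as <- sum(!is.na(assigned))
      if (n_as == 0) NA_real_ else sum(assignments$correct) / n_as
    },
    read_weighted_recovery = if (is.null(truth)) NA_real_ else
      sum(mult[assignments$correct]) / sum(mult))
  structure(list(reports = reports, assignments = assignments,
                 summary = summary, mode = mode, delta = delta),
            class = "barcode_assignment")
}

#' @export
print.barcode_assignment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<barcode_assignment> %s mode, delta = %g\n", x$mode, x$delta))
  cat(sprintf("  %d/%d queries assigned", s$n_assigned, s$n_queries))
  if (!is.na(s$recall)) {
    cat(sprintf("; recall %.4f, precision %.4f, read-weighted recovery %.4f",
                s$recall, s$precision, s$read_weighted_recovery))
  }
  cat("\n")
  invisible(x)
}

#' Read and write barcode sets
#'
#' FASTA (ID = barcode label) or two-column TSV (`id`, `sequence`) with an
#' optional `multiplicity` column.
#'
#' @param x named character vector of barcodes (or a `barcode_whitelist` /
#'   `barcode_queries`).
#' @param path file path; format chosen by extension (`.fa`/`.fasta` vs
#'   `.tsv`).
#' @return `read_barcodes()` returns a named character vector; a
#'   `multiplicity` attribute is attached when the TSV has that column.
#' @export
write_barcodes <- function(x, path) {
  mult <- NULL
  if (inherits(x, "barcode_whitelist")) x <- x$barcodes
  if (inherits(x, "barcode_queries")) {
    mult <- x$multiplicity
    x <- x$observed
  }
  if (grepl("\\.(fa|fasta)$", path)) {
    write_fasta(x, path)
  } else {
    df <- data.frame(id = names(x), sequence = as.character(x))
    if (!is.null(mult)) df$multiplicity <- mult
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_barcodes
#' @export
read_barcodes <- function(path) {
  if (grepl("\\.(fa|fasta)$", path)) {
    out <- read_fasta(path)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    out <- stats::setNames(df$sequence, df$id)
    if (!is.null(df$multiplicity)) attr(out, "multiplicity") <- df$multiplicity
  }
  check_sequences(out, arg = "barcodes")
  out
}
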