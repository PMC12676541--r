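#' Exact edit-distance ground truth for a search instance
#'
#' Full query-by-base matrix of exact edit distances via the DP oracle.
#'
#' @param queries,base named sequence vectors of one common length.
#' @return integer matrix with query/base IDs as dimnames.
#' @export
build_ground_truth <- function(queries, base) {
  N <- unique(nchar(c(queries, base)))
  if (length(N) != 1) stop("all sequences must share one length", call. = FALSE)
  m <- edit_distance_matrix(queries, base)
  rownames(m) <- ids_of(queries, "q")
  colnames(m) <- ids_of(base, "b")
  m
}

#' Build an embedding index over a base set
#'
#' One exact-reference (brute-force) index per embedding component: component
#' i of a query is only ever compared with component i of the base entries,
#' matching the min-over-components semantics of [z_distance()]. The exact
#' backend returns provably complete results.
#'
#' @param model an `lsme_model`.
#' @param base named character vector of base sequences of length `config$N`.
#' @return an `lsme_index`.
#' @export
lsme_index <- function(model, base) {
  stopifnot(inherits(model, "lsme_model"))
  ids <- ids_of(base, "b")
  if (anyDuplicated(ids)) stop("base IDs must be unique", call. = FALSE)
  structure(
    list(model = model, embeddings = lsme_embed(model, base), ids = ids,
         backend = "exact"),
    class = "lsme_index")
}

# component i of a (k, m, n) embedding array as an (n x m) matrix
component_matrix <- function(E, i) {
  t(matrix(E[i, , ], nrow = dim(E)[2], ncol = dim(E)[3]))
}

# component-i Euclidean cross-distances: queries (nq x m) vs base (nb x m)
component_cross_dist <- function(Q, B) {
  d2 <- outer(rowSums(Q^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(Q)), rowSums(B^2)) - 2 * Q %*% t(B)
  sqrt(pmax(d2, 0))
}

search_prepare <- function(index, queries, repetitions) {
  stopifnot(inherits(index, "lsme_index"))
  k <- index$model$config$k
  if (repetitions < 1 || repetitions > k) {
    stop("`repetitions` must lie in 1..k", call. = FALSE)
  }
  list(qid = ids_of(queries, "q"),
       E = lsme_embed(index$model, queries),
       k = k)
}

search_report <- function(rows) {
  if (length(rows) == 0) {
    return(tibble::tibble(query_id = character(0), base_id = character(0),
                          embedding_distance = numeric(0),
                          repetition_index = integer(0)))
  }
  do.call(rbind, rows)
}

#' Radius search at the margin
#'
#' For each embedding component `i <= repetitions`, reports every base entry
#' whose component-i distance from the query is at most `delta`. With all
#' `k` components this reports exactly the pairs [classify_pair()] calls
#' similar. Self-pairs (equal IDs) are excluded.
#'
#' @param index an [lsme_index()].
#' @param queries named query sequences.
#' @param delta search radius; defaults to the model margin.
#' @param repetitions number of components searched (`1..k`).
#' @return tibble of match reports: `query_id`, `base_id`,
#'   `embedding_distance` (the component distance that produced the match),
#'   `repetition_index` (the component).
#' @export
radius_search <- function(index, queries,
                          delta = index$model$config$delta,
                          repetitions = index$model$config$k) {
  prep <- search_prepare(index, queries, repetitions)
  rows <- list()
  for (i in seq_len(repetitions)) {
    D <- component_cross_dist(component_matrix(prep$E, i),
                              component_matrix(index$embeddings, i))
    hit <- which(D <= delta, arr.ind = TRUE)
    if (nrow(hit)) {
      keep <- prep$qid[hit[, 1]] != index$ids[hit[, 2]]
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          query_id = prep$qid[hit[keep, 1]],
          base_id = index$ids[hit[keep, 2]],
          embedding_distance = D[hit[keep, , drop = FALSE]],
          repetition_index = i)
      }
    }
  }
  search_report(rows)
}

#' K-nearest-neighbour search with the delta filter
#'
#' For each component `i <= repetitions`, retrieves the `K` nearest base
#' vectors in component-i space (ties broken by base order) and keeps those
#' within `delta`. Equals brute-force top-K-then-filter exactly under the
#' exact-reference backend. Self-pairs are excluded before ranking.
#'
#' @inheritParams radius_search
#' @param K neighbours retrieved per component before filtering.
#' @return tibble of match reports (see [radius_search()]).
#' @export
knn_search <- function(index, queries, K = 1,
                       delta = index$model$config$delta,
                       repetitions = index$model$config$k) {
  stopifnot(K >= 1)
  prep <- search_prepare(index, queries, repetitions)
  rows <- list()
  for (i in seq_len(repetitions)) {
    D <- component_cross_dist(component_matrix(prep$E, i),
                              component_matrix(index$embeddings, i))
    for (q in seq_len(nrow(D))) {
      cand <- which(prep$qid[q] != index$ids)
      ord <- cand[order(D[q, cand])][seq_len(min(K, length(cand)))]
      ord <- ord[D[q, ord] <= delta]
      if (length(ord)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          query_id = prep$qid[q], base_id = index$ids[ord],
          embedding_distance = D[q, ord], repetition_index = i)
      }
    }
  }
  search_report(rows)
}

#' Repetition-union TP/FP curve from match reports
#'
#' Point `i` aggregates the distinct (query, base) pairs reported by the
#' first `i` repetitions (a pair found by several components is counted once,
#' at its smallest repetition index). Each distinct pair is a TP if its
#' ground-truth edit distance is at most `d1`, an FP if at least `d2`, and is
#' ignored (counted in `total_reported` only) if it falls in the open
#' "don't care" gap.
#'
#' @param reports match-report tibble from [radius_search()], [knn_search()],
#'   [minimizer_candidates()] or [cgk_lsh_candidates()].
#' @param ground_truth matrix from [build_ground_truth()].
#' @param d1,d2 similarity thresholds.
#' @param max_reps number of curve points (defaults to the largest
#'   repetition index present).
#' @return tibble of `repetitions`, `tp`, `fp`, `total_reported`.
#' @export
build_curve <- function(reports, ground_truth, d1, d2,
                        max_reps = max(reports$repetition_index, 1L)) {
  stopifnot(d1 < d2)
  if (nrow(reports)) {
    qi <- match(reports$query_id, rownames(ground_truth))
    bi <- match(reports$base_id, colnames(ground_truth))
    if (anyNA(qi) || anyNA(bi)) {
      stop("report references an ID absent from the ground truth", call. = FALSE)
    }
    ord <- order(reports$repetition_index)
    first <- ord[!duplicated(paste0(reports$query_id, "\r", reports$base_id)[ord])]
    d <- ground_truth[cbind(qi[first], bi[first])]
    rep_idx <- reports$repetition_index[first]
    cls <- ifelse(d <= d1, "tp", ifelse(d >= d2, "fp", "ignored"))
  } else {
    rep_idx <- integer(0)
    cls <- character(0)
  }
  tibble::tibble(
    repetitions = seq_len(max_reps),
    tp = vapply(seq_len(max_reps), function(i) sum(cls == "tp" & rep_idx <= i), integer(1)),
    fp = vapply(seq_len(max_reps), function(i) sum(cls == "fp" & rep_idx <= i), integer(1)),
    total_reported = vapply(seq_len(max_reps), function(i) sum(rep_idx <= i), integer(1)))
}
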