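#' Edit (Levenshtein) distance between DNA sequences
#'
#' Unit-cost substitution/insertion/deletion distance computed by dynamic
#' programming. `edit_distance()` compares two vectors element-wise (lengths
#' of the individual strings may differ); `edit_distance_matrix()` computes
#' the full query-by-base matrix used as search ground truth.
#'
#' @param s,t character vectors over \{A,C,G,T\} of equal length (recycling a
#'   length-1 vector is allowed).
#' @return integer vector of distances.
#' @examples
#' edit_distance("ACGT", "AGT")   # 1
#' @export
edit_distance <- function(s, t) {
  check_sequences(s, arg = "s")
  check_sequences(t, arg = "t")
  if (length(s) == 1L && length(t) > 1L) s <- rep(s, length(t))
  if (length(t) == 1L && length(s) > 1L) t <- rep(t, length(s))
  if (length(s) != length(t)) {
    stop("`s` and `t` must have the same length (or length 1)", call. = FALSE)
  }
  edit_dist_pair_cpp(s, t)
}

#' @param query,base character vectors of sequences; names (or `q1..`/`b1..`
#'   defaults) become the dimnames of the result.
#' @rdname edit_distance
#' @export
edit_distance_matrix <- function(query, base) {
  check_sequences(query, arg = "query")
  check_sequences(base, arg = "base")
  m <- edit_dist_cross_cpp(query, base)
  rownames(m) <- if (!is.null(names(query))) names(query) else paste0("q", seq_along(query))
  colnames(m) <- if (!is.null(names(base))) names(base) else paste0("b", seq_along(base))
  m
}
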