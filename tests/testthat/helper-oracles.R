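# Independent edit-distance oracles, deliberately different algorithms from
# the package's dynamic programme.

# Memoization-free recursive Levenshtein on integer vectors.
edit_rec <- function(a, b) {
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    min(rec(i - 1L, j) + 1L,
        rec(i, j - 1L) + 1L,
        rec(i - 1L, j - 1L) + (a[i] != b[j]))
  }
  rec(length(a), length(b))
}

edit_rec_str <- function(s, t) {
  edit_rec(utf8ToInt(s), utf8ToInt(t))
}

# Edit distance as shortest path in the single-edit move graph, found by
# breadth-first search over all {A,T} strings of bounded length. Any optimal
# edit script between strings of length <= maxlen/2 stays within the length
# bound, so BFS level = true edit distance for those pairs.
bfs_edit_oracle <- function(alphabet = c("A", "T"), maxlen = 12L) {
  all_strings <- unlist(lapply(0:maxlen, function(L) {
    if (L == 0L) return("")
    apply(do.call(expand.grid, rep(list(alphabet), L)), 1,
          paste, collapse = "")
  }), use.names = FALSE)
  idx <- seq_along(all_strings)
  names(idx) <- paste0("#", all_strings) # prefix: "" is not a legal name
  neighbours <- lapply(all_strings, function(s) {
    L <- nchar(s)
    out <- character(0)
    if (L > 0) {
      for (p in seq_len(L)) {
        pre <- substr(s, 1, p - 1); post <- substr(s, p + 1, L)
        cur <- substr(s, p, p)
        out <- c(out, paste0(pre, setdiff(alphabet, cur), post), # substitutions
                 paste0(pre, post))                              # deletion
      }
    }
    if (L < maxlen) {
      for (p in 0:L) {
        out <- c(out, paste0(substr(s, 1, p), alphabet, substr(s, p + 1, L)))
      }
    }
    unname(idx[paste0("#", unique(out))])
  })
  list(
    strings = all_strings,
    # all distances from `source` up to level `maxd`
    dist_from = function(source, maxd = maxlen) {
      d <- rep(NA_integer_, length(all_strings))
      frontier <- unname(idx[paste0("#", source)])
      d[frontier] <- 0L
      level <- 0L
      while (length(frontier) && level < maxd) {
        level <- level + 1L
        nxt <- unique(unlist(neighbours[frontier], use.names = FALSE))
        nxt <- nxt[is.na(d[nxt])]
        d[nxt] <- level
        frontier <- nxt
      }
      stats::setNames(d, all_strings)
    })
}
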