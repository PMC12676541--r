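# Brute-force reference: all component distances computed with plain loops,
# independent of the package's vectorised search path.
brute_component_dists <- function(Eq, Eb) {
  k <- dim(Eq)[1]
  nq <- dim(Eq)[3]; nb <- dim(Eb)[3]
  D <- array(NA_real_, c(k, nq, nb))
  for (i in seq_len(k))
    for (q in seq_len(nq))
      for (b in seq_len(nb))
        D[i, q, b] <- sqrt(sum((Eq[i, , q] - Eb[i, , b])^2))
  D
}

search_instance <- function(nq = 20, nb = 20, seed = 51) {
  mod <- tiny_model(N = 12, k = 3, m = 4, seed = 8)
  qs <- stats::setNames(random_sequences(nq, 12, seed = seed), paste0("q", seq_len(nq)))
  bs <- stats::setNames(random_sequences(nb, 12, seed = seed + 1), paste0("b", seq_len(nb)))
  list(mod = mod, qs = qs, bs = bs, index = lsme_index(mod, bs),
       D = brute_component_dists(lsme_embed(mod, qs), lsme_embed(mod, bs)))
}

test_that("ground truth delegates to the DP oracle", {
  expect_identical(unname(build_ground_truth("ACGTAC", "ACTTAC")[1, 1]),
                   edit_distance("ACGTAC", "ACTTAC"))
})

test_that("radius search at r = k reports exactly the z <= delta pairs", {
  inst <- search_instance()
  delta <- stats::median(inst$D) # a radius that keeps a non-trivial subset
  rep <- radius_search(inst$index, inst$qs, delta = delta)
  got <- unique(paste(rep$query_id, rep$base_id))
  want <- character(0)
  for (q in seq_along(inst$qs))
    for (b in seq_along(inst$bs))
      if (min(inst$D[, q, b]) <= delta)
        want <- c(want, paste(names(inst$qs)[q], names(inst$bs)[b]))
  expect_setequal(got, want)
  # every reported pair agrees with classify_pair and its distance recomputes
  for (r in sample(nrow(rep), min(10, nrow(rep)))) {
    expect_identical(classify_pair(inst$mod, inst$qs[[rep$query_id[r]]],
                                   inst$bs[[rep$base_id[r]]], delta = delta),
                     "similar")
    expect_equal(rep$embedding_distance[r],
                 inst$D[rep$repetition_index[r],
                        match(rep$query_id[r], names(inst$qs)),
                        match(rep$base_id[r], names(inst$bs))])
  }
})

test_that("radius search honours the repetition prefix and degenerate radii", {
  inst <- search_instance(nq = 10, nb = 10)
  delta <- stats::median(inst$D)
  full <- radius_search(inst$index, inst$qs, delta = delta)
  r1 <- radius_search(inst$index, inst$qs, delta = delta, repetitions = 1)
  expect_true(all(r1$repetition_index == 1L))
  expect_true(all(paste(r1$query_id, r1$base_id) %in%
                    paste(full$query_id, full$base_id)))
  # delta = 0 with no duplicated embeddings reports nothing
  expect_identical(nrow(radius_search(inst$index, inst$qs, delta = 0)), 0L)
  # delta beyond the largest distance reports the full cross product
  huge <- radius_search(inst$index, inst$qs, delta = max(inst$D) + 1)
  expect_identical(nrow(unique(huge[, c("query_id", "base_id")])), 100L)
})

test_that("KNN search equals brute-force top-K-then-filter", {
  inst <- search_instance()
  delta <- stats::median(inst$D)
  for (K in c(1, 3)) {
    rep <- knn_search(inst$index, inst$qs, K = K, delta = delta)
    want <- list()
    for (i in seq_len(dim(inst$D)[1]))
      for (q in seq_along(inst$qs)) {
        ord <- order(inst$D[i, q, ])[seq_len(K)]
        ord <- ord[inst$D[i, q, ord] <= delta]
        if (length(ord))
          want[[length(want) + 1L]] <- paste(i, names(inst$qs)[q], names(inst$bs)[ord])
      }
    expect_setequal(paste(rep$repetition_index, rep$query_id, rep$base_id),
                    unlist(want))
  }
})

test_that("self-pairs are excluded when query and base sets coincide", {
  mod <- tiny_model(N = 12, k = 2, m = 3, seed = 10)
  s <- stats::setNames(random_sequences(8, 12, seed = 61), paste0("s", 1:8))
  idx <- lsme_index(mod, s)
  rep <- radius_search(idx, s, delta = 1e6)
  expect_true(all(rep$query_id != rep$base_id))
  expect_true(all(knn_search(idx, s, K = 8, delta = 1e6)$query_id !=
                    knn_search(idx, s, K = 8, delta = 1e6)$base_id))
})

test_that("curve accounting reproduces the hand-enumerable toy instance", {
  gt <- matrix(c(1L, 7L, 4L), nrow = 1,
               dimnames = list("q1", c("b1", "b2", "b3")))
  reports <- tibble::tibble(
    query_id = c("q1", "q1", "q1"),
    base_id = c("b1", "b2", "b3"),
    embedding_distance = NA_real_,
    repetition_index = c(1L, 1L, 2L))
  curve <- build_curve(reports, gt, d1 = 3, d2 = 5, max_reps = 2)
  expect_identical(curve$tp, c(1L, 1L))
  expect_identical(curve$fp, c(1L, 1L))
  expect_identical(curve$total_reported, c(2L, 3L)) # distance-4 pair ignored
  # boundary: ground truth == d1 is a TP from its repetition onward
  gtb <- matrix(3L, 1, 1, dimnames = list("q1", "b1"))
  cb <- build_curve(tibble::tibble(query_id = "q1", base_id = "b1",
                                   embedding_distance = 0,
                                   repetition_index = 2L),
                    gtb, 3, 5, max_reps = 3)
  expect_identical(cb$tp, c(0L, 1L, 1L))
})

test_that("curves deduplicate pairs at the smallest repetition and stay monotone", {
  gt <- matrix(c(0L, 9L), nrow = 1, dimnames = list("q1", c("b1", "b2")))
  reports <- tibble::tibble(
    query_id = "q1", base_id = c("b1", "b1", "b2"),
    embedding_distance = NA_real_, repetition_index = c(3L, 1L, 2L))
  curve <- build_curve(reports, gt, 1, 3, max_reps = 3)
  expect_identical(curve$total_reported, c(1L, 2L, 2L)) # b1 counted once, at rep 1
  expect_identical(curve$tp, c(1L, 1L, 1L))

  inst <- search_instance(nq = 15, nb = 15, seed = 71)
  gt2 <- build_ground_truth(inst$qs, inst$bs)
  rep2 <- radius_search(inst$index, inst$qs, delta = stats::median(inst$D))
  curve2 <- build_curve(rep2, gt2, 1, 3, max_reps = 3)
  expect_true(all(diff(curve2$tp) >= 0))
  expect_true(all(diff(curve2$total_reported) >= 0))
  expect_true(all(curve2$tp + curve2$fp <= curve2$total_reported))

  expect_error(
    build_curve(tibble::tibble(query_id = "nope", base_id = "b1",
                               embedding_distance = 0, repetition_index = 1L),
                gt, 1, 3),
    "absent")
  empty <- build_curve(rep2[0, ], gt2, 1, 3, max_reps = 2)
  expect_identical(empty$total_reported, c(0L, 0L))
})
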