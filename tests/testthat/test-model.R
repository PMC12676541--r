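test_that("one-hot encoding uses fixed A,C,G,T row order with unit columns", {
  m <- one_hot("ACGT")
  expect_identical(dim(m), c(4L, 4L))
  expect_identical(unname(m), diag(4))
  expect_identical(unname(colSums(one_hot("GATTACGT"))), rep(1, 8))
  a <- one_hot("AAAA")
  expect_true(all(a["A", ] == 1) && sum(a) == 4)
  expect_error(one_hot("ACG", N = 4), "length")
})

test_that("embedding has shape (k, m, n), is deterministic and batch-invariant", {
  mod <- tiny_model(N = 12, k = 3, m = 4)
  set.seed(2)
  seqs <- random_sequences(7, 12)
  E <- lsme_embed(mod, seqs)
  expect_identical(dim(E), c(3L, 4L, 7L))
  expect_true(all(is.finite(E)))
  expect_identical(E, lsme_embed(mod, seqs))
  # a sequence alone embeds identically to the same sequence inside a batch
  expect_equal(lsme_embed(mod, seqs[4])[, , 1], E[, , 4])
  expect_error(lsme_embed(mod, "ACGT"), "length")
})

test_that("a zero linear head annihilates every embedding", {
  mod <- tiny_model()
  mod$params$head$W[] <- 0
  mod$params$head$b[] <- 0
  E <- lsme_embed(mod, random_sequences(3, 12, seed = 1))
  expect_true(all(E == 0))
})

test_that("checkpoint round-trip reproduces embeddings bit-for-bit", {
  mod <- tiny_model(seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_lsme(mod, path)
  back <- load_lsme(path)
  seqs <- random_sequences(5, 12, seed = 3)
  expect_identical(lsme_embed(back, seqs), lsme_embed(mod, seqs))
})

test_that("z distance is the min component-wise Euclidean distance", {
  expect_identical(z_distance(matrix(0, 2, 1), matrix(c(3, 4), 2, 1)), 3)
  a <- rbind(c(0, 0), c(1, 1), c(2, 2))
  b <- rbind(c(0, 0), c(5, 5), c(9, 9))
  expect_identical(z_distance(a, b), 0)
  set.seed(13)
  for (i in 1:50) {
    x <- random_embedding(4, 3); y <- random_embedding(4, 3)
    expect_identical(z_distance(x, y), z_distance(y, x))
    expect_gte(z_distance(x, y), 0)
    expect_identical(z_distance(x, x), 0)
    # joint component permutation leaves z unchanged
    p <- sample(4)
    expect_equal(z_distance(x[p, ], y[p, ]), z_distance(x, y))
  }
  expect_error(z_distance(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("contrastive loss reproduces the hinge arithmetic", {
  z12 <- matrix(12, 1, 1); z8 <- matrix(8, 1, 1); zero <- matrix(0, 1, 1)
  expect_identical(contrastive_loss(zero, z12, +1, 10), 2)
  expect_identical(contrastive_loss(zero, z12, -1, 10), 0)
  expect_identical(contrastive_loss(zero, z8, -1, 10), 2)
  expect_error(contrastive_loss(zero, z8, NA, 10), "gap")
  set.seed(17)
  for (i in 1:200) {
    a <- random_embedding(3, 5); b <- random_embedding(3, 5)
    delta <- stats::runif(1, 0.1, 3)
    expect_equal(contrastive_loss(a, b, +1, delta) + contrastive_loss(a, b, -1, delta),
                 abs(z_distance(a, b) - delta))
  }
})

test_that("training descends on a learnable task and is seed-reproducible", {
  ds <- label_pairs(build_pair_dataset(12, c(0, 1, 3, 4), 400, seed = 21), 1, 3)
  cfg <- lsme_config(N = 12, k = 2, m = 4, delta = 10, d1 = 1, d2 = 3,
                     epochs = 3, batch_size = 128, seed = 5)
  m1 <- lsme_train(cfg, ds)
  expect_lt(m1$training_log$loss[3], m1$initial_loss)
  m2 <- lsme_train(cfg, ds)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$params, m2$params)
})

test_that("training requires both label classes and excludes gap pairs", {
  ds <- label_pairs(build_pair_dataset(12, c(0, 1), 50, seed = 22), 1, 3)
  expect_error(lsme_train(lsme_config(N = 12, d1 = 1, d2 = 3, epochs = 1), ds),
               "both similar")
  gap_only <- label_pairs(build_pair_dataset(12, 2, 50, seed = 23), 1, 3)
  expect_error(lsme_train(lsme_config(N = 12, d1 = 1, d2 = 3, epochs = 1), gap_only),
               "no labelled pairs")
})
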