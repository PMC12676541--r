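# A model whose linear head is zeroed embeds everything at the origin, so
# z = 0 for every pair: the degenerate classifier that calls everything
# similar. Useful as an analytically known model.
zeroed_model <- function(N = 12) {
  mod <- lsme_init(lsme_config(N = N, k = 2, m = 3, delta = 10, d1 = 1, d2 = 3))
  mod$params$head$W[] <- 0
  mod$params$head$b[] <- 0
  mod
}

test_that("margin rule classifies z <= delta as similar, including the boundary", {
  mod <- zeroed_model()
  s <- random_sequences(2, 12, seed = 1)
  expect_identical(classify_pair(mod, s[1], s[1]), "similar")
  # z == delta exactly (z = 0, delta = 0) still classifies similar
  expect_identical(classify_pair(mod, s[1], s[2], delta = 0), "similar")
})

test_that("degenerate all-similar model scores 1 below d1 and 0 above d2", {
  mod <- zeroed_model()
  ds <- label_pairs(build_pair_dataset(12, c(1, 3, 4), 30, seed = 31), 1, 3)
  rep <- evaluate_model(mod, ds)
  expect_identical(rep$per_distance$value[rep$per_distance$d == 1], 1)
  expect_identical(rep$per_distance$value[rep$per_distance$d >= 3], c(0, 0))
  expect_identical(rep$overall, 30 / 90)
})

test_that("overall accuracy is the count-weighted mean of labelled distances", {
  mod <- tiny_model(N = 12, k = 2, m = 3, seed = 2)
  ds <- label_pairs(build_pair_dataset(12, c(0, 1, 2, 3, 4), 25, seed = 32), 1, 3)
  rep <- evaluate_model(mod, ds, delta = 0.5)
  labelled <- rep$per_distance[rep$per_distance$type != "gap", ]
  expect_equal(rep$overall,
               sum(labelled$value * labelled$n) / sum(labelled$n))
  expect_identical(rep$overall_n, sum(labelled$n))
  # the gap distance is reported descriptively, not aggregated
  expect_identical(rep$per_distance$type[rep$per_distance$d == 2], "gap")
  expect_true(all(rep$per_distance$value >= 0 & rep$per_distance$value <= 1))
  expect_true(all(rep$per_distance$lo <= rep$per_distance$value &
                    rep$per_distance$value <= rep$per_distance$hi))
})

test_that("flipping every label complements the overall accuracy", {
  mod <- tiny_model(N = 12, k = 2, m = 3, seed = 4)
  ds <- label_pairs(build_pair_dataset(12, c(0, 1, 3, 5), 20, seed = 33), 1, 3)
  rep <- evaluate_model(mod, ds, delta = 0.4)
  flipped <- ds
  flipped$pairs$y <- -flipped$pairs$y
  rep2 <- evaluate_model(mod, flipped, delta = 0.4)
  expect_equal(rep2$overall, 1 - rep$overall)
})

test_that("a single-value sweep equals direct train-and-evaluate", {
  ds <- label_pairs(build_pair_dataset(10, c(0, 1, 3, 4), 60, seed = 34), 1, 3)
  test <- label_pairs(build_pair_dataset(10, c(1, 3), 40, seed = 35), 1, 3)
  cfg <- lsme_config(N = 10, k = 2, m = 3, delta = 4, d1 = 1, d2 = 3,
                     epochs = 2, batch_size = 64, seed = 6)
  sw <- lsme_sweep("m", 3, cfg, ds, test)
  expect_length(sw, 1)
  direct <- evaluate_model(lsme_train(cfg, ds), test)
  expect_identical(sw[[1]]$per_distance, direct$per_distance)
  expect_identical(sw[[1]]$overall, direct$overall)
})

test_that("sweeps rerun identically and write the summary TSV", {
  ds <- label_pairs(build_pair_dataset(10, c(0, 1, 3, 4), 60, seed = 34), 1, 3)
  test <- label_pairs(build_pair_dataset(10, c(1, 3), 40, seed = 35), 1, 3)
  cfg <- lsme_config(N = 10, k = 2, m = 3, delta = 4, d1 = 1, d2 = 3,
                     epochs = 2, batch_size = 64, seed = 6)
  out1 <- withr::local_tempfile(fileext = ".tsv")
  out2 <- withr::local_tempfile(fileext = ".tsv")
  sw1 <- lsme_sweep("m", c(2, 4), cfg, ds, test, out_tsv = out1)
  sw2 <- lsme_sweep("m", c(2, 4), cfg, ds, test, out_tsv = out2)
  expect_identical(readLines(out1), readLines(out2))
  tab <- read.delim(out1)
  expect_identical(tab$value, c(2L, 4L))
  expect_equal(tab$overall, vapply(sw1, `[[`, numeric(1), "overall"))
})
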