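test_that("evaluate_pair matches hand-derived accuracies and is symmetric", {
  # feature equal to the binary class code: perfect 1-NN separator
  df <- tibble::tibble(sep = rep(c(0, 1), each = 5),
                       junk = withr::with_seed(1, stats::rnorm(10)),
                       class = rep(c("A", "B"), each = 5))
  knn1 <- eval_config("knn", k = 1)
  expect_equal(evaluate_pair(df, "sep", "junk", config = knn1), 1.0)

  # both features constant, balanced labels: leaving one sample out makes its
  # class the training minority, so the majority vote is always wrong
  cst <- tibble::tibble(c1 = rep(1, 10), c2 = rep(2, 10),
                        class = rep(c("A", "B"), each = 5))
  expect_equal(evaluate_pair(cst, "c1", "c2", config = eval_config("naive_bayes")), 0.0)
  expect_equal(evaluate_pair(cst, "c1", "c2", config = eval_config("svm_linear")), 0.0)

  sim <- generate_dataset(synthetic_spec(n_samples = 30, n_univariate = 4,
    n_xor_pairs = 1, n_redundant = 0, n_noise = 4, seed = 9))
  for (cfg in list(eval_config("svm_linear"), eval_config("knn"),
                   eval_config("naive_bayes"), eval_config("random_forest", n_trees = 25))) {
    expect_equal(evaluate_pair(sim$data, 2, 7, config = cfg),
                 evaluate_pair(sim$data, 7, 2, config = cfg))
  }
  expect_error(evaluate_pair(sim$data, 3, 3), "distinct")
  expect_error(evaluate_pair(sim$data, 1, 99), "out of range")
})

test_that("build_pair_table is complete, canonical and correctly sorted", {
  sim <- generate_dataset(synthetic_spec(n_samples = 24, n_univariate = 3,
    n_xor_pairs = 1, n_redundant = 1, n_noise = 5, seed = 3))
  pt <- build_pair_table(sim$data, config = eval_config("knn"))
  feats <- pair_table_features(pt)
  n <- length(feats)
  expect_equal(n, 11L)  # 3 univariate + 2 xor members + 1 redundant + 5 noise
  expect_equal(nrow(pt), n * (n - 1) / 2)

  # completeness: every unordered pair exactly once, i before j
  pos_i <- match(pt$feature_i, feats)
  pos_j <- match(pt$feature_j, feats)
  expect_true(all(pos_i < pos_j))
  expect_equal(sort(paste(pmin(pos_i, pos_j), pmax(pos_i, pos_j))),
               sort(apply(utils::combn(n, 2), 2, paste, collapse = " ")))

  # sort: accuracy descending, ties by ascending (i, j)
  expect_false(is.unsorted(rev(pt$accuracy)))
  ties <- split(seq_len(nrow(pt)), pt$accuracy)
  for (rows in ties) {
    if (length(rows) > 1) {
      expect_false(is.unsorted(pos_i[rows]))
    }
  }
  expect_true(all(pt$accuracy >= 0 & pt$accuracy <= 1))

  # row values agree with evaluate_pair
  for (r in c(1, 10, 45)) {
    expect_equal(pt$accuracy[r],
                 evaluate_pair(sim$data, pt$feature_i[r], pt$feature_j[r],
                               config = eval_config("knn")))
  }
  expect_error(build_pair_table(sim$data["class"]), "no feature columns")
})

test_that("pair tables are identical for 1 and 4 workers", {
  sim <- generate_dataset(synthetic_spec(n_samples = 20, n_univariate = 2,
    n_xor_pairs = 1, n_redundant = 0, n_noise = 8, seed = 21))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_pair_table(build_pair_table(sim$data, config = eval_config("knn"),
                                    workers = 1), f1)
  write_pair_table(build_pair_table(sim$data, config = eval_config("knn"),
                                    workers = 4), f4)
  expect_identical(readLines(f1), readLines(f4))
})

test_that("label-shuffled data gives chance-level pair accuracies", {
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_univariate = 5,
    n_xor_pairs = 1, n_redundant = 0, n_noise = 8, seed = 6))
  shuffled <- sim$data
  shuffled$class <- withr::with_seed(99, sample(shuffled$class))
  majority <- max(table(shuffled$class)) / nrow(shuffled)
  pt <- build_pair_table(shuffled, config = eval_config("knn"))
  expect_lt(abs(mean(pt$accuracy) - majority), 0.1)
})

test_that("a planted XOR pair ranks in the top 5% of the pair table", {
  sim <- generate_dataset(synthetic_spec(n_samples = 100, n_univariate = 5,
    effect_size = 1, n_xor_pairs = 1, n_redundant = 0, n_noise = 24, seed = 11))
  pt <- build_pair_table(sim$data, config = eval_config("knn"))
  row <- which(pt$feature_i == "xorA_01" & pt$feature_j == "xorB_01")
  expect_lte(row, ceiling(0.05 * nrow(pt)))
})

test_that("top_pairs takes a prefix and preserves order", {
  pt <- make_pt(c("a", "c", "a"), c("b", "d", "e"), c(0.9, 0.8, 0.7),
                features = c("a", "b", "c", "d", "e"))
  expect_equal(nrow(top_pairs(pt, 0)), 0L)
  expect_equal(as.data.frame(top_pairs(pt, 99)), as.data.frame(pt))
  two <- top_pairs(pt, 2)
  expect_equal(two$feature_j, c("b", "d"))
  expect_identical(pair_table_features(two), pair_table_features(pt))
})
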