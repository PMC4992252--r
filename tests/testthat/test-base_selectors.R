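test_that("chi-squared statistic matches the closed form", {
  # binned feature vs class table [[10,0],[0,10]]: all E = 5, statistic 20
  df <- tibble::tibble(f = rep(c(0, 1), each = 10),
                       class = rep(c("A", "B"), each = 10))
  expect_equal(chi_squared_rank(df)$score, 20)

  # exactly proportional counts: O = E everywhere
  df2 <- tibble::tibble(f = c(0, 0, 1, 1, 0, 0, 1, 1),
                        class = rep(c("A", "B"), each = 4))
  expect_equal(chi_squared_rank(df2)$score, 0)
})

test_that("gain ratio matches hand-computed entropies", {
  df <- tibble::tibble(f = rep(c(0, 1), each = 10),
                       class = rep(c("A", "B"), each = 10))
  expect_equal(gain_ratio_rank(df)$score, 1.0)

  cst <- tibble::tibble(f = rep(5, 8), g = rep(c(0, 1), 4),
                        class = rep(c("A", "B"), each = 4))
  rk <- gain_ratio_rank(cst)
  expect_equal(rk$score[rk$feature == "f"], 0)

  # joint table {(0,A):2, (1,A):1, (1,B):3}: IG = 0.4591479, H(F) = 0.9182958
  df3 <- tibble::tibble(f = c(0, 0, 1, 1, 1, 1),
                        class = c("A", "A", "A", "B", "B", "B"))
  expect_equal(gain_ratio_rank(df3)$score, 0.5, tolerance = 1e-7)
})

test_that("ReliefF weights match a hand trace and basic geometry", {
  # 4 samples, 1 feature, disjoint class ranges, k = 1: every hit-diff is 0
  # and every miss-diff is 1 after range scaling, so the weight is 1
  df <- tibble::tibble(f = c(0, 0, 1, 1), class = c("A", "A", "B", "B"))
  w <- relief_rank(df, k_neighbors = 1)$score
  expect_gt(w, 0)
  expect_equal(w, 1.0)

  # identical-for-all-instances feature has weight 0
  df2 <- tibble::tibble(f = c(0, 0, 1, 1), g = rep(3, 4),
                        class = c("A", "A", "B", "B"))
  rk <- relief_rank(df2, k_neighbors = 1)
  expect_equal(rk$score[rk$feature == "g"], 0)
  expect_error(relief_rank(df, k_neighbors = 2), "per class")
})

test_that("FSDD separates class means and penalizes within-class variance", {
  # two equal classes at constant 0/1: zero within-class variance; after
  # z-normalization the between-class term is 1 (0.25 on the raw scale)
  df <- tibble::tibble(f = c(0, 0, 1, 1), class = c("A", "A", "B", "B"))
  expect_equal(fsdd_rank(df)$score, 1.0)

  # equal class means with positive within-class variance: J < 0
  df2 <- tibble::tibble(f = c(-1, 1, -1, 1), class = c("A", "A", "B", "B"))
  expect_lt(fsdd_rank(df2)$score, 0)

  # affine invariance of the raw feature
  sim <- generate_dataset(synthetic_spec(n_samples = 30, n_univariate = 3,
    n_xor_pairs = 0, n_redundant = 0, n_noise = 3, seed = 12))
  scaled <- sim$data
  for (f in setdiff(names(scaled), "class")) scaled[[f]] <- 7 * scaled[[f]] - 3
  expect_equal(fsdd_rank(scaled)$score, fsdd_rank(sim$data)$score)
})

test_that("every filter ranks a planted separator above pure noise (10 seeds)", {
  rankers <- list(chi_squared_rank, gain_ratio_rank, relief_rank, fsdd_rank)
  for (s in 1:10) {
    sim <- generate_dataset(synthetic_spec(n_samples = 50, n_univariate = 1,
      effect_size = 2.5, n_xor_pairs = 0, n_redundant = 0, n_noise = 6,
      seed = 200 + s))
    for (ranker in rankers) {
      expect_identical(ranker(sim$data)$feature[1], "univ_01")
    }
  }
})

test_that("filter rankings are permutations sorted by score with index ties", {
  sim <- generate_dataset(synthetic_spec(n_samples = 30, n_univariate = 2,
    n_xor_pairs = 1, n_redundant = 1, n_noise = 4, seed = 8))
  feats <- setdiff(names(sim$data), "class")
  for (rk in list(chi_squared_rank(sim$data), gain_ratio_rank(sim$data),
                  relief_rank(sim$data), fsdd_rank(sim$data),
                  mi_rank(sim$data))) {
    expect_setequal(rk$feature, feats)
    expect_false(is.unsorted(rev(rk$score)))
  }
})

test_that("eval_subset generalizes pair evaluation and sees interactions", {
  df <- tibble::tibble(sep = rep(c(0, 1), each = 5),
                       junk = withr::with_seed(2, stats::rnorm(10)),
                       class = rep(c("A", "B"), each = 5))
  knn1 <- eval_config("knn", k = 1)
  expect_equal(eval_subset(df, "sep", config = knn1), 1.0)
  expect_error(eval_subset(df, character(0)), "at least one")

  sim <- generate_dataset(synthetic_spec(n_samples = 80, n_univariate = 0,
    n_xor_pairs = 1, n_redundant = 0, n_noise = 2, seed = 13))
  pair_acc <- eval_subset(sim$data, c("xorA_01", "xorB_01"), config = knn1)
  single_best <- max(eval_subset(sim$data, "xorA_01", config = knn1),
                     eval_subset(sim$data, "xorB_01", config = knn1))
  expect_gt(pair_acc, single_best)
})

test_that("forward search and backward elimination match greedy oracles", {
  cfg <- eval_config("knn")
  for (s in 1:4) {
    sim <- generate_dataset(synthetic_spec(n_samples = 24, n_univariate = 2,
      effect_size = 1.2, n_xor_pairs = 1, n_redundant = 1, n_noise = 1,
      seed = 300 + s))
    fs <- forward_search(sim$data, config = cfg)
    of <- oracle_forward(sim$data, cfg)
    expect_identical(fs$chosen, of$chosen)
    expect_equal(fs$accuracy, of$accuracy)

    be <- backward_elimination(sim$data, config = cfg)
    ob <- oracle_backward(sim$data, cfg)
    expect_setequal(be$chosen, ob$chosen)
    expect_equal(be$accuracy, ob$accuracy)

    # greedy never beats the exhaustive best subset
    expect_lte(fs$accuracy, oracle_best_subset(sim$data, cfg))
    # traces move monotonically
    expect_false(is.unsorted(fs$trace$accuracy))
    expect_false(is.unsorted(be$trace$accuracy))
  }
})

test_that("forward search degenerate cases behave as specified", {
  # one feature reaching 1.0 alone: single step
  df <- tibble::tibble(sep = rep(c(0, 1), each = 5),
                       junk = withr::with_seed(3, stats::rnorm(10)),
                       class = rep(c("A", "B"), each = 5))
  fs <- forward_search(df, config = eval_config("knn", k = 1))
  expect_identical(fs$chosen, "sep")
  expect_equal(nrow(fs$trace), 1L)

  # all-constant features: no candidate improves on the empty-set baseline
  cst <- tibble::tibble(c1 = rep(1, 8), c2 = rep(2, 8),
                        class = rep(c("A", "B"), 4))
  fs0 <- forward_search(cst, config = eval_config("naive_bayes"))
  expect_length(fs0$chosen, 0L)
})

test_that("backward elimination drops redundant copies and stops cleanly", {
  df <- tibble::tibble(sep1 = rep(c(0, 1), each = 5),
                       sep2 = rep(c(0, 1), each = 5),
                       class = rep(c("A", "B"), each = 5))
  be <- backward_elimination(df, config = eval_config("knn", k = 1))
  expect_length(be$chosen, 1L)
  expect_equal(be$accuracy, 1.0)

  # when every removal strictly hurts, the full set is retained
  sim <- generate_dataset(synthetic_spec(n_samples = 60, n_univariate = 0,
    n_xor_pairs = 1, n_redundant = 0, n_noise = 0, seed = 14))
  be2 <- backward_elimination(sim$data, config = eval_config("knn"))
  expect_length(be2$chosen, 2L)
})

test_that("mRMR follows the MID criterion", {
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_univariate = 3,
    n_xor_pairs = 0, n_redundant = 0, n_noise = 5, seed = 15))
  expect_identical(mrmr_rank(sim$data, m = 1)$feature,
                   mi_rank(sim$data)$feature[1])

  # f2 an exact copy of a 4-level perfect separator f1 (H(f1) = 2 >
  # I(f1;C) = 1), f3 a weaker feature: the copy's second-step score
  # I(f2;C) - I(f2;f1) = 1 - 2 = -1 is beaten by f3, so the second pick is f3
  df <- tibble::tibble(f1 = c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3),
                       f2 = c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3),
                       f3 = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0),
                       class = rep(c("A", "B"), each = 8))
  rk <- mrmr_rank(df, m = 3)
  expect_identical(rk$feature[1:2], c("f1", "f3"))

  # deterministic across runs
  expect_identical(mrmr_rank(sim$data, m = 8), mrmr_rank(sim$data, m = 8))
  expect_error(mrmr_rank(sim$data, m = 9), "between 1 and")
})
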