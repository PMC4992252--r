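test_that("pairwise_reorder reproduces hand traces of the pop/scan loop", {
  # base [3,1,2,4,5] with top rows (3,5) then (2,4): pop 3 pulls 5; pop 1
  # matches nothing; pop 2 pulls 4
  feats <- paste0("f", 1:5)
  base <- pairsel:::new_ranking(paste0("f", c(3, 1, 2, 4, 5)), sort = FALSE)
  pt <- make_pt(c("f3", "f2", "f1"), c("f5", "f4", "f3"), c(0.9, 0.8, 0.1),
                features = feats)
  out <- pairwise_reorder(base, pt, top = 2)
  expect_identical(out$feature, paste0("f", c(3, 5, 1, 2, 4)))

  # partner order follows table order: row (0,1) precedes (0,2)
  base2 <- pairsel:::new_ranking(c("a", "b", "c"), sort = FALSE)
  pt2 <- make_pt(c("a", "a"), c("b", "c"), c(0.9, 0.8),
                 features = c("a", "b", "c"))
  expect_identical(pairwise_reorder(base2, pt2, top = 2)$feature,
                   c("a", "b", "c"))

  # top = 0 is the identity limit
  expect_identical(pairwise_reorder(base, pt, top = 0)$feature, base$feature)

  # a base feature missing from the table is an error naming the feature
  pt3 <- make_pt("f1", "f2", 0.5, features = c("f1", "f2"))
  expect_error(pairwise_reorder(base, pt3, top = 1), "'f3'")
})

test_that("pairwise_reorder equals the brute-force oracle on random instances", {
  for (seed in 1:12) {
    n <- 4 + (seed %% 9)  # 4..12 features
    feats <- paste0("g", seq_len(n))
    pt <- random_pt(feats, seed = seed)
    base_feats <- withr::with_seed(1000 + seed, sample(feats))
    base <- pairsel:::new_ranking(base_feats, sort = FALSE)
    for (top in c(0, 3, nrow(pt))) {
      got <- pairwise_reorder(base, pt, top = top)$feature
      expect_identical(got, oracle_reorder(base_feats, pt$feature_i,
                                           pt$feature_j, top))
      expect_setequal(got, base_feats)  # always a permutation
    }
  }
})

test_that("modified filter rankings compose reorder with the base filter", {
  sim <- generate_dataset(synthetic_spec(n_samples = 30, n_univariate = 3,
    n_xor_pairs = 1, n_redundant = 1, n_noise = 4, seed = 17))
  pt <- build_pair_table(sim$data, config = eval_config("knn"))
  for (method in c("chi_squared", "gain_ratio", "relief", "fsdd")) {
    base <- switch(method,
      chi_squared = chi_squared_rank(sim$data),
      gain_ratio = gain_ratio_rank(sim$data),
      relief = relief_rank(sim$data),
      fsdd = fsdd_rank(sim$data))
    expect_identical(modified_filter_rank(sim$data, method, pt, top = 8)$feature,
                     pairwise_reorder(base, pt, top = 8)$feature)
    # T = 0 reduces to the original method
    expect_identical(modified_filter_rank(sim$data, method, pt, top = 0)$feature,
                     base$feature)
  }
  expect_error(modified_filter_rank(sim$data, "pca", pt), "unknown filter")
})

test_that("modified forward search moves come from the pair pool", {
  # pool with a single perfect row: chosen = that pair, one step
  df <- tibble::tibble(sep = rep(c(0, 1), each = 5),
                       aid = rep(c(10, 20), each = 5),
                       junk = withr::with_seed(5, stats::rnorm(10)),
                       class = rep(c("A", "B"), each = 5))
  pt1 <- make_pt("sep", "aid", 1.0, features = c("sep", "aid", "junk"))
  ms <- modified_forward_search(df, pt1, top = 1, config = eval_config("knn", k = 1))
  expect_setequal(ms$chosen, c("sep", "aid"))
  expect_equal(nrow(ms$trace), 1L)
  expect_equal(ms$accuracy, 1.0)

  # a row overlapping CHOSEN by one feature adds a single feature, so the
  # final subset can have odd size: pool (a,b) then (a,c) over an XOR pair
  # (a,b) plus an independent univariate c
  sim <- generate_dataset(synthetic_spec(n_samples = 60, n_univariate = 1,
    effect_size = 1.5, n_xor_pairs = 1, n_redundant = 0, n_noise = 0, seed = 19))
  pool <- make_pt(c("xorA_01", "xorA_01"), c("xorB_01", "univ_01"),
                  c(0.9, 0.7),
                  features = c("univ_01", "xorA_01", "xorB_01"))
  ms2 <- modified_forward_search(sim$data, pool, top = 2,
                                 config = eval_config("knn"))
  expect_identical(ms2$chosen, c("xorA_01", "xorB_01", "univ_01"))
  expect_identical(ms2$trace$feature, c("xorA_01+xorB_01", "univ_01"))
  expect_false(is.unsorted(ms2$trace$accuracy))

  # pool covering none of the dataset's features
  ptx <- make_pt("other1", "other2", 0.9, features = c("other1", "other2"))
  expect_error(modified_forward_search(df, ptx, top = 1), "raise `top`")
})

test_that("modified backward elimination starts from the top-pair union", {
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_univariate = 3,
    effect_size = 1.5, n_xor_pairs = 0, n_redundant = 2, n_noise = 5, seed = 23))
  cfg <- eval_config("knn")
  pt <- build_pair_table(sim$data, config = cfg)

  # full-table pool reduces exactly to original backward elimination
  full <- modified_backward_elimination(sim$data, pt, top = nrow(pt), config = cfg)
  orig <- backward_elimination(sim$data, config = cfg)
  expect_identical(full$chosen, orig$chosen)
  expect_equal(full$accuracy, orig$accuracy)

  # small pool: the starting set is the union of the top rows' features
  pool <- top_pairs(pt, 3)
  union_feats <- unique(c(pool$feature_i, pool$feature_j))
  mb <- modified_backward_elimination(sim$data, pt, top = 3, config = cfg)
  expect_equal(mb$trace$n_features[1], length(union_feats))
  expect_true(all(mb$chosen %in% union_feats))
  # redundant copies are planted, so pruning goes below the initial union
  expect_lt(length(mb$chosen), length(union_feats))
})

test_that("modified mRMR accumulates exactly m features from pool moves", {
  sim <- generate_dataset(synthetic_spec(n_samples = 40, n_univariate = 3,
    n_xor_pairs = 1, n_redundant = 1, n_noise = 4, seed = 29))
  pt <- build_pair_table(sim$data, config = eval_config("knn"))

  # full pool, m = 1: same first feature as original mRMR
  expect_identical(modified_mrmr(sim$data, pt, top = nrow(pt), m = 1)$feature,
                   mrmr_rank(sim$data, m = 1)$feature)

  # m = 2 on a 3-feature toy: top row holds the two most relevant features
  # (f1 = class, f2 = class with one flip), f3 alternates independently of
  # the class, so the (f1, f2) move score 1 + rel(f2) beats (f2, f3)
  df <- tibble::tibble(f1 = c(0, 0, 0, 0, 1, 1, 1, 1),
                       f2 = c(0, 0, 0, 1, 1, 1, 1, 1),
                       f3 = c(0, 1, 0, 1, 0, 1, 0, 1),
                       class = rep(c("A", "B"), each = 4))
  ptt <- make_pt(c("f1", "f2"), c("f2", "f3"), c(0.95, 0.6),
                 features = c("f1", "f2", "f3"))
  expect_setequal(modified_mrmr(df, ptt, top = 2, m = 2)$feature, c("f1", "f2"))

  # contract: length m, no duplicates, for several m
  for (m in c(1, 3, 5, 9)) {
    rk <- modified_mrmr(sim$data, pt, top = nrow(pt), m = m)
    expect_length(rk$feature, m)
    expect_false(anyDuplicated(rk$feature) > 0)
  }
  expect_error(modified_mrmr(sim$data, pt, top = 1, m = 5), "raise `top`")
})
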