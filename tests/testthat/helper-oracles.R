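# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain loops, separately from the package code paths they check.

# hand dataset: two numeric features, binary class
tiny_df <- function() {
  tibble::tibble(f1 = c(1, 2, 3, 4), f2 = c(4, 3, 2, 1),
                 class = c("A", "A", "B", "B"))
}

# construct a pair table directly from rows (bypassing build_pair_table)
make_pt <- function(feature_i, feature_j, accuracy, features, sort = TRUE) {
  pairsel:::new_pair_table(
    tibble::tibble(feature_i = feature_i, feature_j = feature_j,
                   accuracy = accuracy),
    features = features, sort = sort)
}

# independent re-implementation of the pop/scan reorder loop
oracle_reorder <- function(base, feature_i, feature_j, top) {
  keep <- seq_len(min(top, length(feature_i)))
  fi <- feature_i[keep]
  fj <- feature_j[keep]
  chosen <- base
  out <- character(0)
  while (length(chosen) > 0) {
    f <- chosen[1]
    chosen <- chosen[-1]
    out <- c(out, f)
    for (r in seq_along(fi)) {
      partner <- NA_character_
      if (fi[r] == f) partner <- fj[r]
      if (fj[r] == f) partner <- fi[r]
      if (!is.na(partner) && partner %in% chosen) {
        out <- c(out, partner)
        chosen <- chosen[chosen != partner]
      }
    }
  }
  out
}

# greedy forward oracle built on eval_subset() only
oracle_forward <- function(data, config, label = "class") {
  feats <- setdiff(names(data), label)
  chosen <- character(0)
  best <- 0
  repeat {
    cand <- setdiff(feats, chosen)
    if (length(cand) == 0) break
    accs <- vapply(cand, function(x) eval_subset(data, c(chosen, x), label, config), 0)
    top <- cand[which.max(accs)]
    if (max(accs) > best) {
      chosen <- c(chosen, top)
      best <- max(accs)
    } else break
  }
  list(chosen = chosen, accuracy = best)
}

# greedy backward oracle (ties accepted)
oracle_backward <- function(data, config, label = "class") {
  feats <- setdiff(names(data), label)
  chosen <- feats
  best <- eval_subset(data, chosen, label, config)
  while (length(chosen) > 1) {
    accs <- vapply(chosen, function(x) eval_subset(data, setdiff(chosen, x), label, config), 0)
    if (max(accs) >= best) {
      chosen <- setdiff(chosen, chosen[which.max(accs)])
      best <- max(accs)
    } else break
  }
  list(chosen = chosen, accuracy = best)
}

# exhaustive best subset accuracy
oracle_best_subset <- function(data, config, label = "class") {
  feats <- setdiff(names(data), label)
  best <- 0
  for (k in seq_along(feats)) {
    combs <- utils::combn(feats, k, simplify = FALSE)
    for (s in combs) {
      a <- eval_subset(data, s, label, config)
      if (a > best) best <- a
    }
  }
  best
}

# random pair table over the features of `data` with seeded accuracies
random_pt <- function(features, seed, n_rows = NULL) {
  pairs <- t(utils::combn(features, 2))
  withr::with_seed(seed, {
    acc <- round(stats::runif(nrow(pairs)), 4)
    if (!is.null(n_rows)) {
      keep <- sort(sample.int(nrow(pairs), min(n_rows, nrow(pairs))))
      pairs <- pairs[keep, , drop = FALSE]
      acc <- acc[keep]
    }
  })
  make_pt(pairs[, 1], pairs[, 2], acc, features = features)
}
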