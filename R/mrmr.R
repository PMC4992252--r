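#' Minimum-redundancy maximum-relevance ranking (MID scheme)
#'
#' Greedy mRMR on discretized codes: the first feature maximises relevance
#' I(F; C); each subsequent pick maximises
#' `I(x; C) - mean(I(x; s) for s in selected)`. There is no stopping
#' condition; exactly `m` features are returned in pick order. Ties break
#' towards the lower column position.
#'
#' @inheritParams discretize_features
#' @param m Number of features to rank; at most the feature count.
#' @return A `ps_ranking` with the greedy mRMR score of each pick (the score
#'   of the step at which it was chosen).
#' @export
mrmr_rank <- function(data, label = "class", m, n_bins = 5L,
                      strategy = "equal_frequency") {
  parts <- dataset_parts(data, label)
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m > parts$n_features) {
    abort(paste0("`m` must be between 1 and the number of features (",
                 parts$n_features, ")"),
          class = "pairsel_error_input")
  }
  st <- mrmr_state(parts, n_bins, strategy)
  picked <- integer(0)
  scores <- numeric(0)
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(parts$n_features), picked)
    sc <- vapply(cand, function(x) mrmr_score(st, x, picked), 0)
    best <- which.max(sc)
    picked <- c(picked, cand[best])
    scores <- c(scores, sc[best])
  }
  new_ranking(parts$features[picked], scores, method = "mrmr", sort = FALSE)
}

# Precomputed discretized codes, relevance vector and a lazy pairwise-MI
# cache shared by mrmr_rank() and modified_mrmr().
mrmr_state <- function(parts, n_bins, strategy) {
  codes <- apply(parts$values, 2L, discretize_vector, n_bins = n_bins,
                 strategy = strategy)
  relevance <- apply(codes, 2L, mi_score, labels = parts$labels)
  env <- new.env(parent = emptyenv())
  env$codes <- codes
  env$relevance <- relevance
  env$mi_cache <- matrix(NA_real_, ncol(codes), ncol(codes))
  env
}

mi_between <- function(st, a, b) {
  v <- st$mi_cache[a, b]
  if (is.na(v)) {
    v <- mi_score(st$codes[, a], st$codes[, b])
    st$mi_cache[a, b] <- v
    st$mi_cache[b, a] <- v
  }
  v
}

# MID criterion for candidate x against the selected set
mrmr_score <- function(st, x, selected) {
  if (length(selected) == 0L) {
    return(st$relevance[x])
  }
  red <- mean(vapply(selected, function(s) mi_between(st, x, s), 0))
  st$relevance[x] - red
}
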