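#' Plug-in mutual information between a discrete feature and the class
#'
#' I(F; C) = sum p(f, c) log2( p(f, c) / (p(f) p(c)) ), in bits, with the
#' usual 0 log 0 = 0 convention. Non-negative; equals H(C) when the feature
#' codes determine the class.
#'
#' @param codes Discrete feature values (any atomic vector).
#' @param labels Class labels, same length.
#' @return Mutual information in bits.
#' @examples
#' mi_score(c(0, 0, 1, 1), c("A", "A", "B", "B"))  # 1 bit
#' @export
mi_score <- function(codes, labels) {
  if (length(codes) != length(labels)) {
    abort("`codes` and `labels` must have the same length",
          class = "pairsel_error_input")
  }
  joint <- table(codes, labels)
  p <- joint / sum(joint)
  pf <- rowSums(p)
  pc <- colSums(p)
  terms <- p * log2(p / outer(pf, pc))
  sum(terms[p > 0])
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rank features by mutual information with the class
#'
#' Features are discretized (see [discretize_features()]) and scored with
#' the plug-in mutual-information estimator. This is the pre-filtering score
#' used to reduce a raw expression matrix (tens of thousands of probes) to a
#' tractable feature set before pairwise pre-evaluation.
#'
#' @inheritParams discretize_features
#' @return A `ps_ranking` tibble with columns `feature` and `score` (bits),
#'   sorted descending; ties broken by original column order.
#' @export
mi_rank <- function(data, label = "class", n_bins = 5L,
                    strategy = "equal_frequency") {
  parts <- dataset_parts(data, label)
  codes <- apply(parts$values, 2L, discretize_vector, n_bins = n_bins,
                 strategy = strategy)
  scores <- apply(codes, 2L, mi_score, labels = parts$labels)
  new_ranking(parts$features, scores, method = "mutual_information")
}

#' Keep the top-n features by mutual information
#'
#' Returns the dataset reduced to the `n` features with the highest
#' mutual-information score (ties broken by original column order), feature
#' columns reordered score-descending, label column last. The mapping from
#' retained features back to the original columns is attached as the
#' `"feature_map"` attribute (a tibble with `feature`, `score`,
#' `original_index`).
#'
#' @inheritParams mi_rank
#' @param n Number of features to keep; must not exceed the feature count.
#' @return A tibble with `n` feature columns plus the label column.
#' @export
prefilter_top_n <- function(data, n, label = "class", n_bins = 5L,
                            strategy = "equal_frequency") {
  parts <- dataset_parts(data, label)
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n > parts$n_features) {
    abort(paste0("`n` must be between 1 and the number of features (",
                 parts$n_features, ")"),
          class = "pairsel_error_input")
  }
  rk <- mi_rank(data, label, n_bins = n_bins, strategy = strategy)
  keep <- rk$feature[seq_len(n)]
  out <- validate_dataset(data, label)[c(keep, label)]
  attr(out, "feature_map") <- tibble(
    feature = keep,
    score = rk$score[seq_len(n)],
    original_index = match(keep, parts$features)
  )
  out
}
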