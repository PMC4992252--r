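#' Univariate filter rankings
#'
#' Classic filter scores computed per feature against the class labels:
#'
#' * `chi_squared_rank()`: Pearson chi-squared statistic of the
#'   binned-feature-by-class contingency table, without continuity
#'   correction. Large values mean strong feature/class association.
#' * `gain_ratio_rank()`: information gain normalised by the feature's
#'   intrinsic value, `(H(C) - H(C|F)) / H(F)` on binned codes (log base 2);
#'   defined as 0 for constant features.
#' * `relief_rank()`: deterministic ReliefF. Every instance contributes
#'   (no sampling); for each instance the `k_neighbors` nearest hits (same
#'   class) and nearest misses per other class are found with Manhattan
#'   distance on range-scaled features, miss contributions weighted by class
#'   priors renormalised over the other classes. A feature is rewarded when
#'   it separates an instance from other classes more than from its own.
#' * `fsdd_rank()`: distance-discriminant score. After z-normalising each
#'   feature, `J = sum_c p_c (mu_c - mu)^2 - beta * sum_c p_c s2_c`:
#'   between-class spread of class means penalised by the mean within-class
#'   variance.
#'
#' All scores are ranked descending; ties keep original column order.
#'
#' @inheritParams discretize_features
#' @param k_neighbors Neighbours per class for ReliefF (default 3); every
#'   class must have more members than this.
#' @param beta Within-class variance penalty for FSDD (default 2).
#' @return A `ps_ranking` tibble with columns `feature` and `score`.
#' @name filter_rankings
NULL

#' @rdname filter_rankings
#' @export
chi_squared_rank <- function(data, label = "class", n_bins = 5L,
                             strategy = "equal_frequency") {
  parts <- dataset_parts(data, label)
  scores <- apply(parts$values, 2L, function(x) {
    chi_squared_stat(discretize_vector(x, n_bins, strategy), parts$labels)
  })
  new_ranking(parts$features, scores, method = "chi_squared")
}

chi_squared_stat <- function(codes, labels) {
  obs <- table(codes, labels)
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - exp)^2 / exp, na.rm = TRUE)
}

#' @rdname filter_rankings
#' @export
gain_ratio_rank <- function(data, label = "class", n_bins = 5L,
                            strategy = "equal_frequency") {
  parts <- dataset_parts(data, label)
  hc <- entropy_bits(parts$labels)
  scores <- apply(parts$values, 2L, function(x) {
    codes <- discretize_vector(x, n_bins, strategy)
    hf <- entropy_bits(codes)
    if (hf == 0) return(0)
    (hc - conditional_entropy_bits(parts$labels, codes)) / hf
  })
  new_ranking(parts$features, scores, method = "gain_ratio")
}

# H(C | F) on discrete codes, log base 2
conditional_entropy_bits <- function(labels, codes) {
  n <- length(labels)
  sum(vapply(split(labels, codes), function(part) {
    length(part) / n * entropy_bits(part)
  }, 0))
}

#' @rdname filter_rankings
#' @export
relief_rank <- function(data, label = "class", k_neighbors = 3L) {
  parts <- dataset_parts(data, label)
  k <- as.integer(k_neighbors)
  counts <- table(parts$labels)
  if (any(counts <= k)) {
    abort(paste0("ReliefF with k = ", k, " needs more than ", k,
                 " samples per class; class '",
                 names(counts)[counts <= k][1L], "' has ", min(counts)),
          class = "pairsel_error_classes")
  }
  X <- parts$values
  n <- nrow(X)
  rng <- apply(X, 2L, function(x) max(x) - min(x))
  rng[rng == 0] <- 1  # constant feature: all diffs are 0 anyway
  Xs <- sweep(X, 2L, rng, "/")
  lab <- parts$labels
  prior <- as.numeric(counts) / n
  names(prior) <- names(counts)
  d <- as.matrix(stats::dist(Xs, method = "manhattan"))
  w <- numeric(ncol(X))
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    # nearest hits
    hits <- which(lab == lab[i])
    hits <- hits[order(di[hits], hits)][seq_len(k)]
    hit_diff <- colMeans(abs(Xs[hits, , drop = FALSE] -
                               matrix(Xs[i, ], k, ncol(X), byrow = TRUE)))
    miss_diff <- numeric(ncol(X))
    other <- setdiff(levels(lab), as.character(lab[i]))
    pw <- prior[other] / sum(prior[other])
    for (cl in other) {
      ms <- which(lab == cl)
      ms <- ms[order(di[ms], ms)][seq_len(k)]
      md <- colMeans(abs(Xs[ms, , drop = FALSE] -
                           matrix(Xs[i, ], k, ncol(X), byrow = TRUE)))
      miss_diff <- miss_diff + pw[[cl]] * md
    }
    w <- w + (miss_diff - hit_diff) / n
  }
  new_ranking(parts$features, w, method = "relief")
}

#' @rdname filter_rankings
#' @export
fsdd_rank <- function(data, label = "class", beta = 2) {
  parts <- dataset_parts(data, label)
  lab <- parts$labels
  n <- parts$n_samples
  prior <- as.numeric(table(lab)) / n
  scores <- apply(parts$values, 2L, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) s <- 1
    z <- (x - mean(x)) / s
    mu <- mean(z)
    cm <- tapply(z, lab, mean)
    cv <- tapply(z, lab, function(v) mean((v - mean(v))^2))
    sum(prior * (cm - mu)^2) - beta * sum(prior * cv)
  })
  new_ranking(parts$features, scores, method = "fsdd")
}
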