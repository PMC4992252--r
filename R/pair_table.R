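#' Build the pairwise classification table
#'
#' Scores every unordered pair of features by the cross-validated accuracy
#' of a classifier trained on exactly those two features. On a dataset with
#' N features the result has choose(N, 2) rows (499,500 for N = 1000),
#' sorted by accuracy descending with ties broken by ascending pair
#' position. The table is the pre-evaluation input of all `modified_*`
#' selection methods: a pair whose two features classify well *together*
#' ranks high even when each member is useless on its own, which is exactly
#' the interaction signal univariate filters cannot see.
#'
#' The pair enumeration is chunked and merged so the result is identical
#' whatever `workers` is.
#'
#' @param data A data frame of samples by features with a label column.
#' @param label Name of the class-label column.
#' @param config An [eval_config()]; default is the linear SVM with LOOCV.
#' @param workers Number of parallel workers (forked; use 1 on Windows).
#' @return A `ps_pair_table` tibble with columns `feature_i`, `feature_j`,
#'   `accuracy`, carrying the full feature universe as an attribute.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_samples = 40, n_univariate = 2,
#'   n_xor_pairs = 1, n_redundant = 0, n_noise = 2, seed = 1))
#' build_pair_table(sim$data, config = eval_config("knn"))
#' @export
build_pair_table <- function(data, label = "class", config = eval_config(),
                             workers = 1L) {
  parts <- dataset_parts(data, label)
  if (parts$n_features < 2L) {
    abort("at least 2 features are required to build a pair table",
          class = "pairsel_error_input")
  }
  pairs <- which(upper.tri(diag(parts$n_features)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]  # (i, j) lexicographic
  fold <- fold_assignment(parts$labels, config)
  args <- list(X = parts$values, y = as.integer(parts$labels) - 1L,
               K = nlevels(parts$labels), fold = as.integer(fold),
               cls = classifier_code(config$classifier), cost = config$cost,
               k = config$k, trees = config$n_trees, mtry = config$mtry,
               seed = as.numeric(config$seed), std = config$standardize)
  run_chunk <- function(rows) {
    pair_accuracies_cpp(args$X, args$y, args$K,
                        pairs[rows, , drop = FALSE] - 1L, args$fold,
                        args$cls, args$cost, args$k, args$trees, args$mtry,
                        args$seed, args$std)
  }
  n_pairs <- nrow(pairs)
  workers <- max(1L, as.integer(workers))
  if (workers > 1L && n_pairs > workers) {
    chunks <- split(seq_len(n_pairs), cut(seq_len(n_pairs), workers, labels = FALSE))
    acc <- unlist(parallel::mclapply(chunks, run_chunk, mc.cores = workers),
                  use.names = FALSE)
  } else {
    acc <- run_chunk(seq_len(n_pairs))
  }
  new_pair_table(
    tibble(feature_i = parts$features[pairs[, 1L]],
           feature_j = parts$features[pairs[, 2L]],
           accuracy = acc),
    features = parts$features, sort = TRUE
  )
}

# Internal constructor; optionally applies the canonical sort
# (accuracy descending, ties by ascending (i, j) position).
new_pair_table <- function(rows, features, sort = FALSE) {
  if (sort && nrow(rows) > 0L) {
    pi <- match(rows$feature_i, features)
    pj <- match(rows$feature_j, features)
    swap <- pi > pj
    if (any(swap)) {
      tmp <- rows$feature_i[swap]
      rows$feature_i[swap] <- rows$feature_j[swap]
      rows$feature_j[swap] <- tmp
      t2 <- pi[swap]; pi[swap] <- pj[swap]; pj[swap] <- t2
    }
    rows <- rows[order(-rows$accuracy, pi, pj), ]
  }
  structure(as_tibble(rows), features = features,
            class = c("ps_pair_table", class(as_tibble(rows))))
}

#' Features covered by a pair table
#' @param pt A `ps_pair_table`.
#' @return Character vector of the feature universe the table was built over.
#' @export
pair_table_features <- function(pt) {
  attr(pt, "features")
}

#' Evaluate a single feature pair
#'
#' Cross-validated accuracy of the configured classifier trained on exactly
#' features `i` and `j`. Symmetric in `(i, j)` and deterministic given the
#' configuration.
#'
#' @param data A data frame of samples by features with a label column.
#' @param i,j Feature names or positions (among the feature columns).
#' @param label Name of the class-label column.
#' @param config An [eval_config()].
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_pair <- function(data, i, j, label = "class", config = eval_config()) {
  parts <- dataset_parts(data, label)
  pi <- resolve_feature(i, parts$features)
  pj <- resolve_feature(j, parts$features)
  if (pi == pj) {
    abort("`i` and `j` must name two distinct features",
          class = "pairsel_error_input")
  }
  cv_accuracy(parts, c(pi, pj), config)
}

# feature name or position -> position; errors on unknown features
resolve_feature <- function(x, features) {
  if (is.character(x)) {
    pos <- match(x, features)
    if (anyNA(pos)) {
      abort(paste0("unknown feature: '", x[is.na(pos)][1L], "'"),
            class = "pairsel_error_input")
    }
    return(pos)
  }
  x <- as.integer(x)
  if (any(x < 1L | x > length(features))) {
    abort("feature position out of range", class = "pairsel_error_input")
  }
  x
}

#' Keep the top rows of a pair table
#'
#' @param pt A `ps_pair_table`.
#' @param n Number of rows to keep; the first `min(n, nrow(pt))` rows are
#'   returned in order.
#' @return A `ps_pair_table` over the same feature universe.
#' @export
top_pairs <- function(pt, n) {
  stopifnot(inherits(pt, "ps_pair_table"))
  if (!is.numeric(n) || length(n) != 1L || n < 0) {
    abort("`n` must be a single non-negative integer", class = "pairsel_error_input")
  }
  new_pair_table(as_tibble(pt)[seq_len(min(n, nrow(pt))), ],
                 features = attr(pt, "features"))
}

#' Write a pair table to CSV
#'
#' The file has header `feature_i,feature_j,accuracy`, pairs in canonical
#' orientation (i before j in the feature universe), rows in table order and
#' accuracies printed with 6 decimals.
#'
#' @param pt A `ps_pair_table`.
#' @param path Output path.
#' @export
write_pair_table <- function(pt, path) {
  stopifnot(inherits(pt, "ps_pair_table"))
  lines <- c("feature_i,feature_j,accuracy",
             if (nrow(pt) > 0L)
               paste0(pt$feature_i, ",", pt$feature_j, ",",
                      sprintf("%.6f", pt$accuracy)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pair table from CSV
#'
#' Inverse of [write_pair_table()]: row order and printed values are
#' reproduced exactly. The feature universe is reconstructed as the order of
#' first occurrence in the file. Malformed rows, accuracies outside
#' \[0, 1\], self-pairs and duplicate unordered pairs are errors.
#'
#' @param path Path to a pair-table CSV.
#' @return A `ps_pair_table`.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("pair table file not found: '", path, "'"),
          class = "pairsel_error_io")
  }
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "feature_i,feature_j,accuracy") {
    abort("pair table file must start with header 'feature_i,feature_j,accuracy'",
          class = "pairsel_error_io")
  }
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_pair_table(tibble(feature_i = character(), feature_j = character(),
                                 accuracy = double()),
                          features = character()))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    abort(paste0("malformed pair table row ", bad[1L] + 1L), class = "pairsel_error_io")
  }
  fi <- vapply(parts, `[[`, "", 1L)
  fj <- vapply(parts, `[[`, "", 2L)
  acc <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(acc) || any(acc < 0 | acc > 1)) {
    abort("pair table accuracies must be numbers in [0, 1]", class = "pairsel_error_io")
  }
  if (any(fi == fj)) {
    abort("pair table contains a self-pair", class = "pairsel_error_io")
  }
  key <- paste(pmin(fi, fj), pmax(fi, fj), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    abort(paste0("duplicate unordered pair: ",
                 gsub("\r", " / ", dup, fixed = TRUE)),
          class = "pairsel_error_io")
  }
  feats <- unique(as.vector(rbind(fi, fj)))
  new_pair_table(tibble(feature_i = fi, feature_j = fj, accuracy = acc),
                 features = feats)
}

#' @export
print.ps_pair_table <- function(x, ...) {
  cat("<pair table> ", nrow(x), " pairs over ",
      length(attr(x, "features")), " features\n", sep = "")
  NextMethod()
}

#' @method tidy ps_pair_table
#' @export
tidy.ps_pair_table <- function(x, ...) {
  out <- as_tibble(x)
  out$rank <- seq_len(nrow(out))
  out
}

#' @rdname build_pair_table
#' @param object,x A `ps_pair_table`.
#' @param ... Unused.
#' @method autoplot ps_pair_table
#' @export
autoplot.ps_pair_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey20") +
    ggplot2::labs(x = "pairwise classification accuracy", y = "pairs",
                  title = "Pairwise pre-evaluation table") +
    ggplot2::theme_minimal()
}
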