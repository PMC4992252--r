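#' Leave-one-out accuracy of a feature subset
#'
#' The canonical reporting evaluator: LOOCV accuracy of a classifier on
#' exactly the given feature columns, whatever `config$cv` says. The result
#' is always a multiple of 1 / n_samples.
#'
#' @inheritParams eval_subset
#' @return Accuracy in \[0, 1\].
#' @export
loocv_accuracy <- function(data, subset, label = "class",
                           config = eval_config()) {
  config$cv <- "loocv"
  eval_subset(data, subset, label = label, config = config)
}

#' Accuracy profile of feature rankings
#'
#' For each ranking, classifier and feature count, the LOOCV accuracy of
#' the classifier on the ranking's first `count` features. This mirrors the
#' standard way of comparing filter selections on expression data: a grid of
#' counts (by default 5, 10, ..., 30) per selector per classifier, with a
#' per-column maximum available via [profile_table()].
#'
#' @param data A data frame of samples by features with a label column.
#' @param rankings Named list of `ps_ranking` objects (or character vectors
#'   of feature names in rank order).
#' @param counts Integer vector of feature counts. Default
#'   `c(5, 10, 15, 20, 25, 30)`.
#' @param classifiers Named list of [eval_config()] objects, or a character
#'   vector of classifier names. Default `c("knn", "svm_linear")`.
#' @param label Name of the class-label column.
#' @return A `ps_profile` tibble with columns `selector`, `classifier`,
#'   `n_features`, `accuracy`.
#' @export
accuracy_profile <- function(data, rankings, counts = c(5L, 10L, 15L, 20L, 25L, 30L),
                             classifiers = c("knn", "svm_linear"),
                             label = "class") {
  stopifnot(is.list(rankings), length(rankings) > 0L)
  if (is.null(names(rankings)) || any(names(rankings) == "")) {
    abort("`rankings` must be a named list", class = "pairsel_error_input")
  }
  if (is.character(classifiers)) {
    classifiers <- stats::setNames(lapply(classifiers, eval_config), classifiers)
  }
  parts <- dataset_parts(data, label)
  orders <- lapply(rankings, function(r) {
    feats <- if (is.data.frame(r)) r$feature else as.character(r)
    resolve_feature(feats, parts$features)  # errors on unknown features
    feats
  })
  counts <- sort(unique(as.integer(counts)))
  short <- vapply(orders, length, 0L)
  if (any(counts > min(short))) {
    abort(paste0("count ", max(counts), " exceeds the shortest ranking (",
                 min(short), " features)"),
          class = "pairsel_error_input")
  }
  grid <- tidyr::expand_grid(selector = names(orders),
                             classifier = names(classifiers),
                             n_features = counts)
  grid$accuracy <- purrr::pmap_dbl(grid, function(selector, classifier, n_features) {
    loocv_accuracy(data, orders[[selector]][seq_len(n_features)],
                   label = label, config = classifiers[[classifier]])
  })
  structure(grid, class = c("ps_profile", class(tibble())))
}

#' Wide accuracy-profile table with MAX rows
#'
#' Reshapes an accuracy profile into the classic report layout: one row per
#' feature count, one column per selector/classifier combination, plus one
#' `MAX` row per classifier holding the column-wise maximum.
#'
#' @param profile A `ps_profile` from [accuracy_profile()].
#' @return A tibble; the `n_features` column is character so the trailing
#'   `"MAX"` rows can be included.
#' @export
profile_table <- function(profile) {
  long <- as_tibble(profile)
  maxes <- dplyr::summarise(
    dplyr::group_by(long, .data$selector, .data$classifier),
    accuracy = max(.data$accuracy), .groups = "drop")
  maxes$n_features <- "MAX"
  long$n_features <- as.character(long$n_features)
  all <- dplyr::bind_rows(long, maxes)
  tidyr::pivot_wider(all, names_from = c("selector", "classifier"),
                     values_from = "accuracy", names_sep = ".")
}

#' @rdname accuracy_profile
#' @param object A `ps_profile`.
#' @param ... Unused.
#' @method autoplot ps_profile
#' @export
autoplot.ps_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$n_features, y = .data$accuracy,
                               colour = .data$selector)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::labs(x = "number of selected features", y = "LOOCV accuracy") +
    ggplot2::theme_minimal()
}
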