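# Ranking container: a tibble (feature, score) in rank order. Scores are NA
# for derived orders (e.g. after pairwise reordering) where no single-feature
# score is meaningful.

new_ranking <- function(features, scores = NULL, method = "ranking",
                        sort = TRUE) {
  if (is.null(scores)) scores <- rep(NA_real_, length(features))
  if (sort) {
    ord <- order(-scores)  # stable: ties stay in input (original-index) order
    features <- features[ord]
    scores <- scores[ord]
  }
  structure(tibble(feature = as.character(features), score = as.numeric(scores)),
            method = method,
            class = c("ps_ranking", class(tibble())))
}

#' @export
print.ps_ranking <- function(x, ...) {
  cat("<feature ranking> method: ", attr(x, "method"), "\n", sep = "")
  NextMethod()
}

#' @method tidy ps_ranking
#' @export
tidy.ps_ranking <- function(x, ...) {
  out <- as_tibble(x)
  out$rank <- seq_len(nrow(out))
  out[c("rank", "feature", "score")]
}

#' Plot a feature ranking
#' @param object A `ps_ranking`.
#' @param top Number of leading features to show. Default 25.
#' @param ... Unused.
#' @method autoplot ps_ranking
#' @export
autoplot.ps_ranking <- function(object, top = 25L, ...) {
  d <- tidy(object)[seq_len(min(top, nrow(object))), ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature, -.data$rank),
                                  y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "score",
                  title = paste0("Feature ranking (", attr(object, "method"), ")")) +
    ggplot2::theme_minimal()
}
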