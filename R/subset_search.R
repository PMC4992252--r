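#' Cross-validated accuracy of a feature subset
#'
#' Trains the configured classifier on exactly the named feature columns and
#' returns its cross-validated accuracy. This is the wrapper evaluation
#' function behind forward search, backward elimination and all reporting.
#'
#' @param data A data frame of samples by features with a label column.
#' @param subset Feature names or positions; must be non-empty.
#' @param label Name of the class-label column.
#' @param config An [eval_config()].
#' @return Accuracy in \[0, 1\]; under LOOCV an exact multiple of
#'   1 / n_samples.
#' @export
eval_subset <- function(data, subset, label = "class", config = eval_config()) {
  parts <- dataset_parts(data, label)
  if (length(subset) == 0L) {
    abort("`subset` must contain at least one feature", class = "pairsel_error_input")
  }
  cols <- resolve_feature(subset, parts$features)
  if (anyDuplicated(cols)) {
    abort("`subset` contains duplicate features", class = "pairsel_error_input")
  }
  cv_accuracy(parts, cols, config)
}

new_selection <- function(chosen, trace, accuracy, method) {
  structure(list(chosen = chosen, trace = trace, accuracy = accuracy,
                 method = method),
            class = "ps_selection")
}

#' @export
print.ps_selection <- function(x, ...) {
  cat("<feature selection> method: ", x$method, "\n",
      "  ", length(x$chosen), " features, accuracy ",
      sprintf("%.4f", x$accuracy), "\n", sep = "")
  if (length(x$chosen) > 0L) {
    shown <- paste(head(x$chosen, 10L), collapse = ", ")
    cat("  chosen: ", shown, if (length(x$chosen) > 10L) ", ...", "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy ps_selection
#' @export
tidy.ps_selection <- function(x, ...) {
  x$trace
}

#' @method glance ps_selection
#' @export
glance.ps_selection <- function(x, ...) {
  tibble(method = x$method, n_selected = length(x$chosen),
         accuracy = x$accuracy, n_steps = nrow(x$trace))
}

#' Greedy wrapper subset searches
#'
#' `forward_search()` starts from the empty set (baseline accuracy 0) and at
#' each step adds the feature whose addition maximises the cross-validated
#' accuracy, accepting only strict improvements; it stops when no feature
#' improves the current accuracy. `backward_elimination()` starts from the
#' full set and at each step removes the feature whose removal yields the
#' highest accuracy, accepting any non-worsening removal (ties allowed, so
#' redundant features are discarded); it stops when every removal strictly
#' decreases accuracy or one feature remains. All ties among candidate
#' features break towards the lower column position.
#'
#' @inheritParams eval_subset
#' @return A `ps_selection` with elements `chosen` (feature names in
#'   selection order), `trace` (one row per accepted step) and `accuracy`.
#'   [tidy()] returns the trace, [glance()] a one-row summary.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_samples = 30, n_univariate = 2,
#'   n_xor_pairs = 0, n_redundant = 0, n_noise = 3, seed = 1))
#' forward_search(sim$data, config = eval_config("knn", k = 1))
#' @name subset_search
NULL

#' @rdname subset_search
#' @export
forward_search <- function(data, label = "class", config = eval_config()) {
  parts <- dataset_parts(data, label)
  chosen <- integer(0)
  best_acc <- 0  # empty-set baseline
  trace <- list()
  repeat {
    candidates <- setdiff(seq_len(parts$n_features), chosen)
    if (length(candidates) == 0L) break
    accs <- vapply(candidates, function(x) cv_accuracy(parts, c(chosen, x), config), 0)
    pick <- candidates[which.max(accs)]  # which.max: first max = lowest index
    if (max(accs) > best_acc) {
      chosen <- c(chosen, pick)
      best_acc <- max(accs)
      trace[[length(trace) + 1L]] <- tibble(
        step = length(trace) + 1L, action = "add",
        feature = parts$features[pick], accuracy = best_acc,
        n_features = length(chosen))
    } else {
      break
    }
  }
  new_selection(parts$features[chosen], dplyr::bind_rows(trace) %||% empty_trace(),
                best_acc, "forward_search")
}

#' @rdname subset_search
#' @export
backward_elimination <- function(data, label = "class", config = eval_config()) {
  parts <- dataset_parts(data, label)
  backward_core(parts, seq_len(parts$n_features), config, "backward_elimination")
}

# shared by backward_elimination and its pair-table-initialized variant
backward_core <- function(parts, start, config, method) {
  chosen <- sort(start)
  best_acc <- cv_accuracy(parts, chosen, config)
  trace <- list(tibble(step = 0L, action = "start", feature = NA_character_,
                       accuracy = best_acc, n_features = length(chosen)))
  while (length(chosen) > 1L) {
    accs <- vapply(chosen, function(x) cv_accuracy(parts, setdiff(chosen, x), config), 0)
    drop_idx <- which.max(accs)
    if (accs[drop_idx] >= best_acc) {
      removed <- chosen[drop_idx]
      chosen <- setdiff(chosen, removed)
      best_acc <- accs[drop_idx]
      trace[[length(trace) + 1L]] <- tibble(
        step = length(trace) - 1L + 1L, action = "remove",
        feature = parts$features[removed], accuracy = best_acc,
        n_features = length(chosen))
    } else {
      break
    }
  }
  new_selection(parts$features[chosen], dplyr::bind_rows(trace), best_acc, method)
}

empty_trace <- function() {
  tibble(step = integer(), action = character(), feature = character(),
         accuracy = double(), n_features = integer())
}

`%||%` <- function(a, b) if (is.null(a) || (is.data.frame(a) && nrow(a) == 0L)) b else a
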