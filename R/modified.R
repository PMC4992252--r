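#' Reorder a filter ranking using top-ranking feature pairs
#'
#' The pairwise modification of a filter ranking. Let P be the first `top`
#' rows of the pair table. Starting from the original ranking CHOSEN, the
#' reordered list MCHOSEN is built by repeating: pop the head feature f of
#' CHOSEN and append it to MCHOSEN; then scan P in table order and for every
#' row containing f whose partner is still in CHOSEN, append the partner to
#' MCHOSEN (and remove it from CHOSEN). The result is a permutation of the
#' input ranking in which features that classify well *together with* an
#' already-placed feature are pulled up right behind it, so pair
#' interactions -- invisible to the univariate score -- influence the order.
#' With `top = 0` the ranking is returned unchanged.
#'
#' @param base A `ps_ranking` (or tibble with a `feature` column).
#' @param pt A `ps_pair_table` built over a superset of `base`'s features.
#' @param top Number of leading pair-table rows to use. Default 1000.
#' @return A `ps_ranking`; scores are `NA` because the derived order no
#'   longer follows a single-feature score.
#' @export
pairwise_reorder <- function(base, pt, top = 1000L) {
  stopifnot(inherits(pt, "ps_pair_table"))
  chosen <- base$feature
  missing <- setdiff(chosen, attr(pt, "features"))
  if (length(missing) > 0L) {
    abort(paste0("feature '", missing[1L], "' is not covered by the pair table"),
          class = "pairsel_error_input")
  }
  p <- top_pairs(pt, top)
  mchosen <- character(0)
  # partner lookup: for each feature, its partners in table-row order
  fi <- p$feature_i
  fj <- p$feature_j
  while (length(chosen) > 0L) {
    f <- chosen[1L]
    chosen <- chosen[-1L]
    mchosen <- c(mchosen, f)
    if (nrow(p) > 0L) {
      hit <- fi == f | fj == f
      partners <- ifelse(fi[hit] == f, fj[hit], fi[hit])
      pull <- partners[partners %in% chosen]
      pull <- pull[!duplicated(pull)]
      if (length(pull) > 0L) {
        mchosen <- c(mchosen, pull)
        chosen <- setdiff(chosen, pull)
      }
    }
  }
  new_ranking(mchosen, NULL,
              method = paste0("pairwise_", attr(base, "method") %||na% "ranking"),
              sort = FALSE)
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Pair-table-modified filter ranking
#'
#' Convenience composition: compute the named filter ranking and apply
#' [pairwise_reorder()] with the given pair table.
#'
#' @inheritParams discretize_features
#' @param method One of `"chi_squared"`, `"gain_ratio"`, `"relief"`,
#'   `"fsdd"`.
#' @param pt A `ps_pair_table` covering the dataset's features.
#' @param top Number of leading pair-table rows to use.
#' @param ... Passed to the underlying filter (e.g. `n_bins`, `k_neighbors`,
#'   `beta`).
#' @return A `ps_ranking`.
#' @export
modified_filter_rank <- function(data, method, pt, top = 1000L,
                                 label = "class", ...) {
  ranker <- switch(method,
    chi_squared = chi_squared_rank,
    gain_ratio = gain_ratio_rank,
    relief = relief_rank,
    fsdd = fsdd_rank,
    abort(paste0("unknown filter method: '", method, "'"),
          class = "pairsel_error_input")
  )
  pairwise_reorder(ranker(data, label = label, ...), pt, top = top)
}

# candidate moves from the pair pool: for each pool row, the features of the
# row not yet chosen (NULL when the row is fully inside `chosen`). Distinct
# move sets only, first pool occurrence kept, so ties resolve by pool order.
pool_moves <- function(pool, chosen) {
  moves <- list()
  seen <- character(0)
  for (r in seq_len(nrow(pool))) {
    new <- setdiff(c(pool$feature_i[r], pool$feature_j[r]), chosen)
    if (length(new) == 0L) next
    key <- paste(sort(new), collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    moves[[length(moves) + 1L]] <- new
  }
  moves
}

#' Pair-table-modified forward search
#'
#' Forward search whose candidate moves are the top-ranking feature pairs
#' rather than single features: at each step, every row (i, j) of the top
#' `top` pair rows proposes adding the features of the row not yet chosen
#' (two features for a disjoint row, one for a row overlapping the current
#' set, which is how odd-sized subsets arise). The move maximising the
#' cross-validated accuracy is accepted if it strictly improves on the
#' current accuracy; otherwise the search stops. Because the very first
#' moves are whole pairs, an interacting pair whose members are individually
#' uninformative can be picked up in one step.
#'
#' @inheritParams eval_subset
#' @inheritParams modified_filter_rank
#' @return A `ps_selection`.
#' @export
modified_forward_search <- function(data, pt, top = 1000L, label = "class",
                                    config = eval_config()) {
  parts <- dataset_parts(data, label)
  pool <- top_pairs(pt, top)
  pool_feats <- intersect(unique(c(pool$feature_i, pool$feature_j)), parts$features)
  if (length(pool_feats) == 0L) {
    abort("no dataset feature occurs in the top pair rows; raise `top`",
          class = "pairsel_error_input")
  }
  chosen <- character(0)
  best_acc <- 0
  trace <- list()
  repeat {
    moves <- pool_moves(pool, chosen)
    moves <- Filter(function(m) all(m %in% parts$features), moves)
    if (length(moves) == 0L) break
    accs <- vapply(moves, function(m) {
      cv_accuracy(parts, match(c(chosen, m), parts$features), config)
    }, 0)
    best <- which.max(accs)
    if (accs[best] > best_acc) {
      chosen <- c(chosen, moves[[best]])
      best_acc <- accs[best]
      trace[[length(trace) + 1L]] <- tibble(
        step = length(trace) + 1L, action = "add",
        feature = paste(moves[[best]], collapse = "+"),
        accuracy = best_acc, n_features = length(chosen))
    } else {
      break
    }
  }
  new_selection(chosen, dplyr::bind_rows(trace) %||% empty_trace(), best_acc,
                "modified_forward_search")
}

#' Pair-table-modified backward elimination
#'
#' Backward elimination started from the union of all features occurring in
#' the top `top` pair rows instead of the full feature set. The pair pool
#' acts as an interaction-aware pre-selection (this is what collapses a
#' 1000-feature search to a few hundred candidates); ordinary backward
#' elimination then prunes the union.
#'
#' @inheritParams modified_forward_search
#' @return A `ps_selection`.
#' @export
modified_backward_elimination <- function(data, pt, top = 1000L,
                                          label = "class",
                                          config = eval_config()) {
  parts <- dataset_parts(data, label)
  pool <- top_pairs(pt, top)
  start_feats <- intersect(unique(c(pool$feature_i, pool$feature_j)),
                           parts$features)
  if (length(start_feats) == 0L) {
    abort("no dataset feature occurs in the top pair rows; raise `top`",
          class = "pairsel_error_input")
  }
  backward_core(parts, match(start_feats, parts$features), config,
                "modified_backward_elimination")
}

#' Pair-table-modified mRMR
#'
#' mRMR with the pair pool's candidate moves: each step proposes, for every
#' top pair row, the not-yet-chosen features of the row, scored by the sum
#' of the per-feature MID criteria (relevance minus mean redundancy against
#' the chosen set). The best move is always accepted -- like the original
#' mRMR there is no stopping condition -- until exactly `m` features are
#' accumulated. A final two-feature move that would overshoot `m` is
#' truncated to its higher-relevance feature. Within an accepted pair the
#' higher-relevance feature is listed first.
#'
#' @inheritParams modified_filter_rank
#' @param m Number of features to return.
#' @return A `ps_ranking` of exactly `m` features in pick order (scores are
#'   the accepted move scores).
#' @export
modified_mrmr <- function(data, pt, top = 1000L, m, label = "class",
                          n_bins = 5L, strategy = "equal_frequency") {
  parts <- dataset_parts(data, label)
  pool <- top_pairs(pt, top)
  pool_feats <- intersect(unique(c(pool$feature_i, pool$feature_j)),
                          parts$features)
  if (!is.numeric(m) || length(m) != 1L || m < 1L) {
    abort("`m` must be a positive integer", class = "pairsel_error_input")
  }
  if (m > length(pool_feats)) {
    abort(paste0("`m` = ", m, " exceeds the ", length(pool_feats),
                 " features covered by the top pair rows; raise `top`"),
          class = "pairsel_error_input")
  }
  st <- mrmr_state(parts, n_bins, strategy)
  chosen <- character(0)
  scores <- numeric(0)
  while (length(chosen) < m) {
    moves <- pool_moves(pool, chosen)
    moves <- Filter(function(mv) all(mv %in% parts$features), moves)
    if (length(moves) == 0L) {
      abort("pair pool exhausted before `m` features were accumulated; raise `top`",
            class = "pairsel_error_input")
    }
    sel_idx <- match(chosen, parts$features)
    mv_scores <- vapply(moves, function(mv) {
      sum(vapply(match(mv, parts$features), mrmr_score, 0, st = st,
                 selected = sel_idx))
    }, 0)
    best <- which.max(mv_scores)
    mv <- moves[[best]]
    # higher-relevance feature first (also the truncation order)
    mv <- mv[order(-st$relevance[match(mv, parts$features)])]
    if (length(chosen) + length(mv) > m) {
      mv <- mv[seq_len(m - length(chosen))]
    }
    chosen <- c(chosen, mv)
    scores <- c(scores, rep(mv_scores[best], length(mv)))
  }
  new_ranking(chosen, scores, method = "modified_mrmr", sort = FALSE)
}
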