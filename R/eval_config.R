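#' Configure a classifier and cross-validation scheme
#'
#' The evaluation configuration drives every accuracy computation in the
#' package: the pair table, the wrapper searches and the final
#' leave-one-out reporting. All classifiers are implemented in compiled code
#' and are fully deterministic given the configuration (the random forest
#' derives all of its randomness from `seed`).
#'
#' @param classifier One of `"svm_linear"` (default; soft-margin linear
#'   support vector classifier trained by dual coordinate descent),
#'   `"knn"`, `"naive_bayes"` (Gaussian) or `"random_forest"`.
#' @param cost SVM cost parameter C. Default 1.
#' @param k Number of neighbours for kNN. Default 3.
#' @param n_trees,mtry Random-forest size and features tried per split
#'   (`mtry = NULL` means `floor(sqrt(p))`).
#' @param cv `"loocv"` (default) or `"stratified_kfold"`.
#' @param folds Number of folds when `cv = "stratified_kfold"`. Default 5.
#' @param seed Integer seed controlling fold assignment and the random
#'   forest. Default 1.
#' @param standardize Standardize features using training-fold statistics
#'   only. Default `TRUE`.
#' @return An object of class `ps_eval_config`.
#' @export
eval_config <- function(classifier = c("svm_linear", "knn", "naive_bayes", "random_forest"),
                        cost = 1, k = 3L, n_trees = 100L, mtry = NULL,
                        cv = c("loocv", "stratified_kfold"), folds = 5L,
                        seed = 1L, standardize = TRUE) {
  classifier <- match.arg(classifier)
  cv <- match.arg(cv)
  if (!is.numeric(cost) || cost <= 0) {
    abort("`cost` must be a positive number", class = "pairsel_error_input")
  }
  if (!is.numeric(k) || k < 1) {
    abort("`k` must be a positive integer", class = "pairsel_error_input")
  }
  if (cv == "stratified_kfold" && folds < 2) {
    abort("`folds` must be at least 2", class = "pairsel_error_input")
  }
  structure(
    list(classifier = classifier, cost = as.numeric(cost), k = as.integer(k),
         n_trees = as.integer(n_trees),
         mtry = if (is.null(mtry)) 0L else as.integer(mtry),
         cv = cv, folds = as.integer(folds), seed = as.integer(seed),
         standardize = isTRUE(standardize)),
    class = "ps_eval_config"
  )
}

#' @export
print.ps_eval_config <- function(x, ...) {
  cat("<eval_config> ", x$classifier,
      if (x$classifier == "svm_linear") paste0(" (C=", x$cost, ")"),
      if (x$classifier == "knn") paste0(" (k=", x$k, ")"),
      if (x$classifier == "random_forest") paste0(" (trees=", x$n_trees, ")"),
      ", cv=", x$cv,
      if (x$cv == "stratified_kfold") paste0(" (", x$folds, " folds)"),
      ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

classifier_code <- function(classifier) {
  match(classifier, c("svm_linear", "knn", "naive_bayes", "random_forest")) - 1L
}

# Fold id per sample (0-based). LOOCV: one fold per sample. Stratified
# k-fold: within each class, a seeded shuffle then round-robin assignment.
# Uses a private RNG stream so the caller's RNG state is untouched.
fold_assignment <- function(labels, config) {
  n <- length(labels)
  if (config$cv == "loocv") {
    return(seq_len(n) - 1L)
  }
  fold <- integer(n)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(config$seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (seq_along(idx) - 1L) %% config$folds
  }
  fold
}

# Internal: cross-validated accuracy of config$classifier on the given
# feature columns (1-based positions into the values matrix).
cv_accuracy <- function(parts, cols, config) {
  cols <- sort(unique(as.integer(cols)))
  fold <- fold_assignment(parts$labels, config)
  cv_accuracy_cpp(parts$values, as.integer(parts$labels) - 1L,
                  nlevels(parts$labels), cols - 1L, as.integer(fold),
                  classifier_code(config$classifier), config$cost, config$k,
                  config$n_trees, config$mtry, as.numeric(config$seed),
                  config$standardize)
}
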