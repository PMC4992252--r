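#' Run the full pairwise-pre-evaluation pipeline
#'
#' Config-driven orchestration of pre-filtering, pair-table construction
#' (with caching), original and modified feature selection, and LOOCV
#' accuracy profiling. All artifacts are plain delimited text written to
#' `out_dir`, together with a `manifest.json` recording the package version,
#' seed, config hash and per-stage status. Re-running with an unchanged
#' config re-uses the cached pair table (the expensive stage, built once per
#' dataset); a pair table left over from a *different* config is a hard
#' error rather than a silent mix.
#'
#' @param config A list, or the path of a YAML file, with entries
#'   `dataset` (`path`, optional `label`, `delimiter`), optional `prefilter`
#'   (`n`, `bins`, `strategy`), optional `table` (`classifier`, `cv`,
#'   `workers`, classifier parameters), `select` (`methods`, `variants` =
#'   subset of `original`/`modified`, `top_pairs`, `mrmr_m`, `classifier`
#'   for the wrapper searches), optional
#'   `evaluate` (`counts`, `classifiers`), and `seed`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: '", config, "'"),
            class = "pairsel_error_io")
    }
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "pairsel",
                   version = as.character(utils::packageVersion("pairsel")),
                   seed = config$seed,
                   config_hash = hash_obj(config),
                   stages = list())

  data <- read_dataset(config$dataset$path, label = config$dataset$label,
                       delim = config$dataset$delimiter)
  label <- config$dataset$label
  manifest$dataset_md5 <- unname(tools::md5sum(config$dataset$path))

  if (!is.null(config$prefilter)) {
    data <- prefilter_top_n(data, n = config$prefilter$n, label = label,
                            n_bins = config$prefilter$bins,
                            strategy = config$prefilter$strategy)
    readr::write_csv(data, file.path(out_dir, "prefiltered.csv"))
    manifest$stages$prefilter <- "computed"
  }

  pt <- NULL
  if (!is.null(config$table)) {
    tbl_cfg <- eval_config(classifier = config$table$classifier,
                           cv = config$table$cv, cost = config$table$cost,
                           k = config$table$k, folds = config$table$folds,
                           seed = config$seed)
    table_key <- hash_obj(list(dataset = manifest$dataset_md5,
                               prefilter = config$prefilter,
                               table = config$table, seed = config$seed))
    table_path <- file.path(out_dir, "combn.csv")
    old_manifest_path <- file.path(out_dir, "manifest.json")
    cached <- FALSE
    if (file.exists(table_path)) {
      old_key <- if (file.exists(old_manifest_path)) {
        jsonlite::read_json(old_manifest_path)$table_key
      }
      if (identical(old_key, table_key)) {
        pt <- read_pair_table(table_path)
        cached <- TRUE
      } else {
        abort(paste0("cached pair table at '", table_path,
                     "' was built under a different config (hash mismatch); ",
                     "remove it or use a fresh output directory"),
              class = "pairsel_error_cache")
      }
    }
    if (!cached) {
      pt <- build_pair_table(data, label = label, config = tbl_cfg,
                             workers = config$table$workers)
      write_pair_table(pt, table_path)
    }
    manifest$table_key <- table_key
    manifest$stages$table <- if (cached) "cached" else "computed"
  }

  rankings <- list()
  for (method in config$select$methods) {
    for (variant in config$select$variants) {
      nm <- if (variant == "modified") paste0(method, "_modified") else method
      res <- run_selector(data, method, variant, pt, config, label)
      if (inherits(res, "ps_selection")) {
        readr::write_csv(tibble(feature = res$chosen),
                         file.path(out_dir, paste0("selection_", nm, ".csv")))
        readr::write_csv(res$trace,
                         file.path(out_dir, paste0("trace_", nm, ".csv")))
      } else {
        rankings[[nm]] <- res
        readr::write_csv(as_tibble(res),
                         file.path(out_dir, paste0("ranking_", nm, ".csv")))
      }
      manifest$stages[[paste0("select_", nm)]] <- "computed"
    }
  }

  if (!is.null(config$evaluate) && length(rankings) > 0L) {
    profile <- accuracy_profile(data, rankings,
                                counts = config$evaluate$counts,
                                classifiers = config$evaluate$classifiers,
                                label = label)
    readr::write_csv(profile_table(profile), file.path(out_dir, "profile.csv"))
    manifest$stages$evaluate <- "computed"
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

run_selector <- function(data, method, variant, pt, config, label) {
  top <- config$select$top_pairs
  m <- config$select$mrmr_m
  ecfg <- eval_config(classifier = config$select$classifier, seed = config$seed)
  if (variant == "original") {
    switch(method,
      chi_squared = chi_squared_rank(data, label),
      gain_ratio = gain_ratio_rank(data, label),
      relief = relief_rank(data, label),
      fsdd = fsdd_rank(data, label),
      mrmr = mrmr_rank(data, label, m = m),
      forward = forward_search(data, label, config = ecfg),
      backward = backward_elimination(data, label, config = ecfg))
  } else {
    switch(method,
      chi_squared = ,
      gain_ratio = ,
      relief = ,
      fsdd = modified_filter_rank(data, method, pt, top = top, label = label),
      mrmr = modified_mrmr(data, pt, top = top, m = m, label = label),
      forward = modified_forward_search(data, pt, top = top, label = label,
                                        config = ecfg),
      backward = modified_backward_elimination(data, pt, top = top,
                                               label = label, config = ecfg))
  }
}

# structural hash of an R object via its canonical JSON serialization
hash_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

config_field <- function(config, path, default = NULL, required = FALSE) {
  x <- config
  for (p in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    x <- x[[p]]
    if (is.null(x)) break
  }
  if (is.null(x)) {
    if (required) {
      abort(paste0("config field `", path, "` is required"),
            class = "pairsel_error_config")
    }
    return(default)
  }
  x
}

valid_methods <- c("chi_squared", "gain_ratio", "relief", "fsdd", "mrmr",
                   "forward", "backward")

validate_config <- function(config) {
  if (!is.list(config)) {
    abort("config must be a list", class = "pairsel_error_config")
  }
  out <- list()
  out$dataset <- list(
    path = config_field(config, "dataset.path", required = TRUE),
    label = config_field(config, "dataset.label", "class"),
    delimiter = config_field(config, "dataset.delimiter", ",")
  )
  if (!is.null(config$prefilter)) {
    out$prefilter <- list(
      n = config_field(config, "prefilter.n", required = TRUE),
      bins = config_field(config, "prefilter.bins", 5L),
      strategy = config_field(config, "prefilter.strategy", "equal_frequency")
    )
  }
  if (!is.null(config$table)) {
    out$table <- list(
      classifier = config_field(config, "table.classifier", "svm_linear"),
      cv = config_field(config, "table.cv", "loocv"),
      cost = config_field(config, "table.cost", 1),
      k = config_field(config, "table.k", 3L),
      folds = config_field(config, "table.folds", 5L),
      workers = config_field(config, "table.workers", 1L)
    )
    if (!out$table$classifier %in% c("svm_linear", "knn", "naive_bayes", "random_forest")) {
      abort(paste0("config field `table.classifier`: unknown classifier '",
                   out$table$classifier, "'"),
            class = "pairsel_error_config")
    }
  }
  methods <- unlist(config_field(config, "select.methods", required = TRUE))
  bad <- setdiff(methods, valid_methods)
  if (length(bad) > 0L) {
    abort(paste0("config field `select.methods`: unknown method '", bad[1L], "'"),
          class = "pairsel_error_config")
  }
  variants <- unlist(config_field(config, "select.variants", "original"))
  if (!all(variants %in% c("original", "modified"))) {
    abort("config field `select.variants` must be a subset of original/modified",
          class = "pairsel_error_config")
  }
  if ("modified" %in% variants && is.null(config$table)) {
    abort("config field `select.variants`: modified methods require a `table` stage",
          class = "pairsel_error_config")
  }
  out$select <- list(methods = methods, variants = variants,
                     top_pairs = config_field(config, "select.top_pairs", 1000L),
                     mrmr_m = config_field(config, "select.mrmr_m", 30L),
                     classifier = config_field(config, "select.classifier",
                                               "svm_linear"))
  if (!out$select$classifier %in% c("svm_linear", "knn", "naive_bayes", "random_forest")) {
    abort(paste0("config field `select.classifier`: unknown classifier '",
                 out$select$classifier, "'"),
          class = "pairsel_error_config")
  }
  if (!is.null(config$evaluate)) {
    out$evaluate <- list(
      counts = unlist(config_field(config, "evaluate.counts",
                                   c(5L, 10L, 15L, 20L, 25L, 30L))),
      classifiers = unlist(config_field(config, "evaluate.classifiers",
                                        c("knn", "svm_linear")))
    )
  }
  out$seed <- config_field(config, "seed", 1L)
  out
}
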