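#' Read a labelled feature matrix from a delimited text file
#'
#' Loads a samples-by-features table (microarray style: rows are samples,
#' columns are features plus one class-label column) and validates it as a
#' classification dataset. Validation is strict: any missing or non-numeric
#' feature cell is an error naming the offending row and column, the label
#' column must contain at least two distinct classes, and every class must
#' have at least two samples (required later by leave-one-out evaluation).
#'
#' @param path Path to a delimited text file with a header row.
#' @param label Name of the class-label column. Default `"class"`.
#' @param delim Field delimiter. Default `","`.
#' @return A tibble with all feature columns as doubles and the label column
#'   as character, in the column order of the file.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("f1,f2,class", "1,4,A", "2,3,A", "3,2,B", "4,1,B"), tf)
#' read_dataset(tf)
#' @export
read_dataset <- function(path, label = "class", delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("dataset file not found: '", path, "'"), class = "pairsel_error_io")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    abort("dataset file has no data rows", class = "pairsel_error_io")
  }
  validate_dataset(raw, label = label)
}

# Validate a data frame as a labelled feature matrix and coerce feature
# columns to double. Shared by read_dataset() and the data-frame entry points.
validate_dataset <- function(data, label = "class") {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame", class = "pairsel_error_input")
  }
  if (!label %in% names(data)) {
    abort(paste0("label column '", label, "' not found in data"),
          class = "pairsel_error_input")
  }
  feats <- setdiff(names(data), label)
  if (anyDuplicated(names(data))) {
    abort("feature names must be unique", class = "pairsel_error_input")
  }
  if (length(feats) < 1L) {
    abort("dataset has no feature columns", class = "pairsel_error_input")
  }
  out <- as_tibble(data)
  labv <- as.character(out[[label]])
  if (anyNA(labv) || any(labv == "")) {
    abort("label column contains missing values", class = "pairsel_error_input")
  }
  for (f in feats) {
    col <- out[[f]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(ifelse(col == "", NA, col)))
      bad <- which(is.na(num))
    } else {
      num <- as.numeric(col)
      bad <- which(is.na(num))
    }
    if (length(bad) > 0L) {
      abort(paste0("missing or non-numeric value in column '", f,
                   "', row ", bad[1L]),
            class = "pairsel_error_missing")
    }
    out[[f]] <- num
  }
  out[[label]] <- labv
  classes <- table(labv)
  if (length(classes) < 2L) {
    abort("fewer than 2 classes in label column", class = "pairsel_error_classes")
  }
  if (any(classes < 2L)) {
    small <- names(classes)[classes < 2L][1L]
    abort(paste0("class '", small, "' has fewer than 2 samples"),
          class = "pairsel_error_classes")
  }
  out
}

# Internal: split a validated data frame into the pieces the algorithms use.
dataset_parts <- function(data, label = "class") {
  data <- validate_dataset(data, label)
  feats <- setdiff(names(data), label)
  labels <- factor(data[[label]], levels = sort(unique(data[[label]])))
  values <- as.matrix(data[feats])
  storage.mode(values) <- "double"
  list(values = values, labels = labels, features = feats,
       n_samples = nrow(values), n_features = length(feats))
}

#' Discretize feature columns into integer bin codes
#'
#' Each feature is binned independently into `n_bins` codes `0..n_bins-1`.
#' `equal_frequency` places bin boundaries at empirical quantiles (inverse
#' ECDF, so binning is invariant to strictly monotone transforms of a
#' feature); `equal_width` splits the observed range into equal-width
#' intervals. Intervals are closed on the right, so a value equal to an
#' internal edge falls in the lower bin. Constant features map to the single
#' code 0. Needed by the mutual-information, Chi-squared, Gain-ratio and mRMR
#' machinery, which operate on discrete codes.
#'
#' @param data A data frame of samples by features with a label column.
#' @param label Name of the class-label column.
#' @param n_bins Number of bins, at least 2. Default 5.
#' @param strategy `"equal_frequency"` (default) or `"equal_width"`.
#' @return A tibble of the same shape with feature columns replaced by
#'   integer codes.
#' @export
discretize_features <- function(data, label = "class", n_bins = 5L,
                                strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2L) {
    abort("`n_bins` must be a single integer >= 2", class = "pairsel_error_input")
  }
  data <- validate_dataset(data, label)
  feats <- setdiff(names(data), label)
  for (f in feats) {
    data[[f]] <- discretize_vector(data[[f]], n_bins = n_bins, strategy = strategy)
  }
  data
}

# Internal workhorse: one numeric vector -> integer codes 0..n_bins-1.
discretize_vector <- function(x, n_bins = 5L, strategy = "equal_frequency") {
  if (length(unique(x)) == 1L) {
    return(rep(0L, length(x)))
  }
  if (strategy == "equal_frequency") {
    # type = 1 (inverse ECDF) keeps edges on data values, which makes the
    # codes invariant to strictly monotone transforms
    edges <- unname(quantile(x, probs = seq_len(n_bins - 1L) / n_bins, type = 1))
  } else {
    breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
    edges <- breaks[2:n_bins]
  }
  edges <- unique(edges)
  as.integer(findInterval(x, edges, left.open = TRUE))
}
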