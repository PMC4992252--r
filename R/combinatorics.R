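#' Size of the feature-subset search space
#'
#' Exact combinatorial bookkeeping for the motivation behind pairwise
#' pre-evaluation: a dataset with N features has `2^N` candidate subsets --
#' about 1.07e301 for N = 1000 and 1.27e30 for N = 100, far beyond
#' exhaustive search -- but only `choose(N, 2)` feature pairs (499,500 for
#' N = 1000), which *can* all be evaluated.
#'
#' `subset_space_size()` computes `2^N` by exact big-integer doubling (no
#' floating-point overflow) and reports it in scientific form.
#'
#' @param n_features Number of features N.
#' @return For [n_feature_pairs()], the pair count `choose(N, 2)`. For
#'   [subset_space_size()], a list with `mantissa` (rounded to
#'   `sig_digits` significant digits), `exponent` (power of ten) and
#'   `digits` (the full exact decimal representation as a string).
#' @examples
#' n_feature_pairs(1000)        # 499500
#' subset_space_size(1000)      # mantissa 1.07, exponent 301
#' @export
n_feature_pairs <- function(n_features) {
  choose(n_features, 2)
}

#' @rdname n_feature_pairs
#' @param sig_digits Significant digits for the reported mantissa. Default 3.
#' @export
subset_space_size <- function(n_features, sig_digits = 3L) {
  n_features <- as.integer(n_features)
  stopifnot(n_features >= 0L)
  # little-endian decimal digits of 2^n, by repeated doubling
  d <- 1L
  for (i in seq_len(n_features)) {
    d <- d * 2L
    carry <- 0L
    for (j in seq_along(d)) {
      v <- d[j] + carry
      d[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      d <- c(d, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  digits <- paste(rev(d), collapse = "")
  exponent <- nchar(digits) - 1L
  lead <- substr(digits, 1L, min(sig_digits + 2L, nchar(digits)))
  mantissa <- signif(as.numeric(lead) / 10^(nchar(lead) - 1L), sig_digits)
  list(mantissa = mantissa, exponent = exponent, digits = digits)
}
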