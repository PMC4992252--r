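#' Specify a synthetic expression dataset with known feature roles
#'
#' The generator emulates a microarray-style classification matrix with
#' planted structure so that every selector -- and specifically the
#' advantage of pairwise pre-evaluation -- can be tested without external
#' downloads. Four feature roles are planted:
#'
#' * *univariate*: unit-variance Gaussians whose class means are separated
#'   by `effect_size` standard deviations (classes placed symmetrically
#'   around 0), i.e. ordinary differentially-expressed features;
#' * *XOR pairs*: pairs of standard Gaussians whose signed product
#'   determines the class (`sign(x * y)`), the canonical interaction: each
#'   member is marginally independent of the class, so no univariate filter
#'   can see it, while the pair separates the classes almost perfectly;
#' * *redundant*: noisy copies of univariate features
#'   (`parent + N(0, redundant_sd)`), emulating co-regulated probes;
#' * *noise*: standard Gaussians independent of the class.
#'
#' Observed labels are the true classes with independent flips at rate
#' `label_noise_rate`. Output is deterministic given the spec.
#'
#' @param n_samples Number of samples. Default 100.
#' @param n_classes Number of classes (must be 2 when XOR pairs are
#'   planted). Default 2.
#' @param n_univariate Number of univariate informative features. Default 10.
#' @param effect_size Class-mean separation of univariate features in SD
#'   units. Default 1.
#' @param n_xor_pairs Number of planted XOR pairs. Default 2.
#' @param n_redundant Number of redundant copies (parents cycle through the
#'   univariate features). Default 5.
#' @param redundant_sd SD of the copy noise. Default 0.3.
#' @param n_noise Number of pure-noise features. Default 50.
#' @param label_noise_rate Label flip probability in \[0, 1). Default 0.
#' @param seed Integer seed. Default 1.
#' @return A `ps_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 100L, n_classes = 2L,
                           n_univariate = 10L, effect_size = 1,
                           n_xor_pairs = 2L, n_redundant = 5L,
                           redundant_sd = 0.3, n_noise = 50L,
                           label_noise_rate = 0, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
               n_univariate = as.integer(n_univariate),
               effect_size = as.numeric(effect_size),
               n_xor_pairs = as.integer(n_xor_pairs),
               n_redundant = as.integer(n_redundant),
               redundant_sd = as.numeric(redundant_sd),
               n_noise = as.integer(n_noise),
               label_noise_rate = as.numeric(label_noise_rate),
               seed = as.integer(seed))
  if (spec$n_samples < 2L * spec$n_classes) {
    abort("`n_samples` must allow at least 2 samples per class",
          class = "pairsel_error_input")
  }
  if (spec$n_classes < 2L) {
    abort("`n_classes` must be at least 2", class = "pairsel_error_input")
  }
  if (spec$n_xor_pairs > 0L && spec$n_classes != 2L) {
    abort("XOR pairs require exactly 2 classes", class = "pairsel_error_input")
  }
  if (spec$n_redundant > 0L && spec$n_univariate < 1L) {
    abort("redundant copies require at least one univariate feature",
          class = "pairsel_error_input")
  }
  total <- spec$n_univariate + 2L * spec$n_xor_pairs + spec$n_redundant + spec$n_noise
  if (total < 1L) {
    abort("spec plants no features", class = "pairsel_error_input")
  }
  if (spec$n_univariate > 0L && spec$effect_size <= 0) {
    abort("`effect_size` must be positive", class = "pairsel_error_input")
  }
  if (spec$label_noise_rate < 0 || spec$label_noise_rate >= 1) {
    abort("`label_noise_rate` must be in [0, 1)", class = "pairsel_error_input")
  }
  structure(spec, class = "ps_synthetic_spec")
}

#' Generate a synthetic dataset from a spec
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `ps_synthetic` with elements `data` (tibble of
#'   features plus a `class` column) and `roles` (tibble with columns
#'   `feature`, `role` in univariate/xor_member/redundant/noise, and
#'   `detail`: the XOR pair id or the parent feature).
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_samples = 20, seed = 7))
#' table(sim$roles$role)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "ps_synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed)
  n <- spec$n_samples
  K <- spec$n_classes
  true_class <- sample(rep_len(seq_len(K) - 1L, n))  # balanced, shuffled
  cols <- list()
  roles <- list()
  pad <- function(i) sprintf("%02d", i)
  for (i in seq_len(spec$n_univariate)) {
    mu <- spec$effect_size * (true_class - (K - 1) / 2)
    nm <- paste0("univ_", pad(i))
    cols[[nm]] <- rnorm(n, mean = mu, sd = 1)
    roles[[nm]] <- c("univariate", NA)
  }
  for (i in seq_len(spec$n_xor_pairs)) {
    x <- rnorm(n)
    mag <- abs(rnorm(n))
    # product sign +1 for class 1, -1 for class 0; each member marginally N(0,1)
    y <- mag * sign(x) * ifelse(true_class == 1L, 1, -1)
    na <- paste0("xorA_", pad(i))
    nb <- paste0("xorB_", pad(i))
    cols[[na]] <- x
    cols[[nb]] <- y
    roles[[na]] <- c("xor_member", as.character(i))
    roles[[nb]] <- c("xor_member", as.character(i))
  }
  univ_names <- names(cols)[seq_len(spec$n_univariate)]
  for (i in seq_len(spec$n_redundant)) {
    parent <- univ_names[(i - 1L) %% spec$n_univariate + 1L]
    nm <- paste0("red_", pad(i))
    cols[[nm]] <- cols[[parent]] + rnorm(n, sd = spec$redundant_sd)
    roles[[nm]] <- c("redundant", parent)
  }
  for (i in seq_len(spec$n_noise)) {
    nm <- paste0("noise_", pad(i))
    cols[[nm]] <- rnorm(n)
    roles[[nm]] <- c("noise", NA)
  }
  observed <- true_class
  if (spec$label_noise_rate > 0) {
    flip <- stats::runif(n) < spec$label_noise_rate
    shift <- if (K == 2L) rep(1L, n) else sample(seq_len(K - 1L), n, replace = TRUE)
    observed[flip] <- (observed[flip] + shift[flip]) %% K
  }
  data <- as_tibble(cols)
  data$class <- LETTERS[observed + 1L]
  roles_tbl <- tibble(
    feature = names(roles),
    role = vapply(roles, `[[`, "", 1L),
    detail = vapply(roles, `[[`, "", 2L)
  )
  structure(list(data = data, roles = roles_tbl, spec = spec),
            class = "ps_synthetic")
}

#' @export
print.ps_synthetic <- function(x, ...) {
  cat("<synthetic dataset> ", nrow(x$data), " samples x ",
      nrow(x$roles), " features (",
      paste(names(table(x$roles$role)), table(x$roles$role),
            sep = ": ", collapse = ", "),
      "), seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}
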