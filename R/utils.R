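#' @importFrom rlang abort warn .data
#' @importFrom stats median rnorm runif rbinom rnbinom rpois rexp rbeta
#'   pt pchisq sd quantile lm coef predict dnorm setNames
#' @importFrom utils head
NULL

# Run code with a private RNG stream so simulators are reproducible from
# their own seed without clobbering the caller's random state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# First column of a feature-by-sample tibble is the feature key; the rest
# are sample columns. Shared validation for the matrix-shaped verbs.
check_feature_matrix <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort(sprintf("`%s` must be a data frame with a feature-id column followed by at least one sample column.", arg))
  }
  if (!is.character(x[[1L]]) && !is.factor(x[[1L]])) {
    abort(sprintf("The first column of `%s` must hold feature identifiers (character).", arg))
  }
  vals <- x[, -1L, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1L)))) {
    abort(sprintf("All sample columns of `%s` must be numeric.", arg))
  }
  invisible(x)
}

feature_values <- function(x) {
  as.matrix(x[, -1L, drop = FALSE])
}

# Rebuild a feature-by-sample tibble from a plain matrix plus the key column.
feature_tibble <- function(ids, m, id_col = "feature_id") {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := as.character(ids)), out)
  out
}

signif6 <- function(x) {
  if (is.numeric(x)) signif(x, 6L) else x
}
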