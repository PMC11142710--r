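#' @importFrom rlang abort warn %||% .data :=
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows bind_cols distinct
#'   across all_of any_of rename relocate pull n row_number slice_min count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_int map_lgl map2 pmap imap
#'   list_rbind keep discard
#' @importFrom stats optim optimHess rnorm runif rbeta rgamma rmultinom
#'   quantile setNames var sd aggregate
#' @importFrom utils head tail
NULL

# Seven-rank lineage used throughout: kingdom ... species.
TAXON_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' @keywords internal
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Dirichlet sampler (one draw per row of output); base R has none.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' @keywords internal
is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

#' @keywords internal
assert_proportions <- function(p, tol = 1e-6, what = "proportions") {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort(sprintf("%s must be finite and non-negative", what))
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("%s must sum to 1 (got %.8f)", what, sum(p)))
  }
  invisible(p)
}

# Derive a stage-local seed below 2^31 from a master seed and an offset,
# so independent pipeline stages get reproducible but distinct streams.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}
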