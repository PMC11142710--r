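#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation test
#'
#' @param x A `perm_test` from [permanova()] or [permdisp()].
#' @param ... Unused.
#' @return One-row tibble: `df_between`, `df_within`, `ss_between`,
#'   `ss_within`, `ss_total`, `R2`, `statistic`, `p.value`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(df_between = x$df[["between"]], df_within = x$df[["within"]],
         ss_between = x$ss[["between"]], ss_within = x$ss[["within"]],
         ss_total = x$ss[["total"]], R2 = x$R2, statistic = x$statistic,
         p.value = x$p_value)
}

#' @rdname tidy.perm_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, R2 = x$R2, p.value = x$p_value,
         n_permutations = x$n_permutations, method = x$method)
}

#' Tidy an amplification-efficiency calibration
#'
#' @param x An `amp_calibration` from [fit_amplification_efficiencies()].
#' @param ... Unused.
#' @return Tibble with one row per species: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy amp_calibration
#' @export
tidy.amp_calibration <- function(x, ...) {
  with(x$estimates, tibble(term = species, estimate = alpha_mean,
                           std.error = alpha_se, conf.low = alpha_lo,
                           conf.high = alpha_hi))
}

#' @rdname tidy.amp_calibration
#' @method glance amp_calibration
#' @export
glance.amp_calibration <- function(x, ...) {
  tibble(reference = x$reference, n_communities = x$n_communities,
         prior_sd = x$prior_sd, converged = x$convergence == 0)
}

#' Tidy an average-diet fit
#'
#' @param x A `diet_fit` from [fit_inflated_dirichlet()].
#' @param ... Unused.
#' @return Tibble with one row per species: `term`, `estimate` (posterior
#'   mean proportion), `conf.low`, `conf.high` (central 95% interval),
#'   `present_prob`.
#' @method tidy diet_fit
#' @export
tidy.diet_fit <- function(x, ...) {
  with(x$summary, tibble(term = species, estimate = mean, median = median,
                         conf.low = lo95, conf.high = hi95,
                         present_prob = present_prob))
}

#' @rdname tidy.diet_fit
#' @method glance diet_fit
#' @export
glance.diet_fit <- function(x, ...) {
  tibble(n_crabs = x$n_crabs, n_species = length(x$species),
         phi = if (is.null(x$phi)) NA_real_ else x$phi[["mean"]],
         max_rhat = if (is.null(x$rhat)) NA_real_ else max(x$rhat, na.rm = TRUE))
}
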