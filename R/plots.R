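#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_errorbar
#'   geom_hline labs theme_minimal facet_wrap position_dodge coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot a principal-coordinates ordination
#'
#' First two positive axes, optionally coloured by a grouping vector
#' (e.g. site or site type).
#'
#' @param object A `crabdiet_pcoa` from [pcoa()].
#' @param groups Optional group labels, one per point.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crabdiet_pcoa
#' @export
autoplot.crabdiet_pcoa <- function(object, groups = NULL, ...) {
  co <- object$coordinates
  pos <- object$eigenvalues[object$eigenvalues > 0]
  rel <- 100 * pos / sum(pos)
  df <- tibble(axis1 = co[, 1],
               axis2 = if (ncol(co) > 1) co[, 2] else 0,
               label = object$labels)
  mapping <- if (is.null(groups)) {
    aes(x = .data$axis1, y = .data$axis2)
  } else {
    df$group <- groups
    aes(x = .data$axis1, y = .data$axis2, colour = .data$group)
  }
  ggplot(df, mapping) +
    geom_point(size = 2, alpha = 0.8) +
    labs(x = sprintf("PCo1 (%.1f%%)", rel[1]),
         y = if (length(rel) > 1) sprintf("PCo2 (%.1f%%)", rel[2]) else "PCo2",
         colour = NULL) +
    theme_minimal()
}

#' Plot calibrated amplification efficiencies
#'
#' Point estimates with their intervals, reference species at zero.
#'
#' @param object An `amp_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot amp_calibration
#' @export
autoplot.amp_calibration <- function(object, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = df$term[order(df$estimate)])
  ggplot(df, aes(x = .data$term, y = .data$estimate)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbar(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                  width = 0.2) +
    geom_point(size = 2) +
    coord_flip() +
    labs(x = NULL, y = "amplification-efficiency offset (per cycle)") +
    theme_minimal()
}

#' Plot an average-diet composition
#'
#' Posterior mean proportions with 95% credible intervals per species.
#'
#' @param object A `diet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diet_fit
#' @export
autoplot.diet_fit <- function(object, ...) {
  df <- tidy(object)
  df$term <- factor(df$term, levels = df$term[order(df$estimate)])
  ggplot(df, aes(x = .data$term, y = .data$estimate)) +
    geom_col(fill = "steelblue", alpha = 0.8) +
    geom_errorbar(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                  width = 0.2) +
    coord_flip() +
    labs(x = NULL, y = "mean diet proportion") +
    theme_minimal()
}

#' Stacked average-diet composition by site type
#'
#' @param summary The `summary` tibble from [average_diet_by_site_type()].
#' @return A ggplot object (stacked bars, one per site type).
#' @export
plot_diet_by_site_type <- function(summary) {
  ggplot(summary, aes(x = .data$site_type, y = .data$mean,
                      fill = .data$species)) +
    geom_col(position = "stack", width = 0.6) +
    labs(x = NULL, y = "mean diet proportion", fill = NULL) +
    theme_minimal()
}
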