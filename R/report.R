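#' Per-site prey-detection summary
#'
#' Reports, for each site, how many sequenced crabs ended up with putative
#' prey DNA after filtering, and that fraction rounded to two digits (the
#' convention used for "final N (% sequenced)" style reporting).
#'
#' @param meta Sample metadata (one row per replicate; controls ignored).
#' @param prey Prey matrix from [build_prey_matrix()], whose rows are the
#'   crabs with prey detections.
#' @return Tibble: `site`, `n_sequenced`, `n_with_prey`, `fraction`.
#' @export
prey_detection_summary <- function(meta, prey) {
  if (!"is_control" %in% names(meta)) meta$is_control <- FALSE
  crabs <- meta |>
    filter(!.data$is_control) |>
    distinct(.data$crab_id, .data$site)
  crabs$with_prey <- crabs$crab_id %in% prey$crab_id
  crabs |>
    group_by(.data$site) |>
    summarise(n_sequenced = dplyr::n(),
              n_with_prey = sum(.data$with_prey),
              .groups = "drop") |>
    mutate(fraction = detection_fraction(.data$n_with_prey, .data$n_sequenced))
}

#' Detection fraction with reporting rounding
#'
#' @param n_with_prey,n_sequenced Counts.
#' @param digits Rounding digits (default 2, the reporting convention).
#' @return `round(n_with_prey / n_sequenced, digits)`.
#' @export
detection_fraction <- function(n_with_prey, n_sequenced, digits = 2) {
  round(n_with_prey / n_sequenced, digits)
}
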