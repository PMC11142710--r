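#' Assign taxonomy to ASVs from BLAST hits (last common ancestor)
#'
#' Hits failing the search thresholds (minimum percent identity 94, maximum
#' e-value 1e-30 by default) are discarded; an ASV whose hits all fail gets
#' `rank = "unassigned"`. For an ASV with hits to a single species, the full
#' lineage is kept at species rank. For hits to multiple distinct species the
#' lineage is truncated at the deepest rank shared by all of them (the last
#' common ancestor). Identical species hit via multiple accessions collapse
#' first, so the LCA is taken over distinct species only.
#'
#' @param hits BLAST hits as from [read_blast_table()] (`qseqid`, `sseqid`,
#'   `pident`, `evalue`, ...).
#' @param taxonomy Subject-keyed lineage table as from [read_taxonomy_table()].
#' @param min_pct_identity Inclusive identity floor (percent, 0-100 scale).
#' @param max_evalue Inclusive e-value ceiling.
#' @return A tibble with one row per ASV present in `hits`: `asv_id`, the
#'   seven lineage columns, `rank`, `best_pct_identity`.
#' @export
assign_taxonomy <- function(hits, taxonomy, min_pct_identity = 94,
                            max_evalue = 1e-30) {
  stopifnot(min_pct_identity > 0, min_pct_identity <= 100)
  missing_subj <- setdiff(unique(hits$sseqid), taxonomy$subject)
  if (length(missing_subj)) {
    abort(sprintf("no taxonomy for BLAST subject(s): %s",
                  paste(head(missing_subj, 5), collapse = ", ")))
  }
  joined <- hits |>
    left_join(taxonomy, by = c(sseqid = "subject")) |>
    mutate(passes = .data$pident >= min_pct_identity & .data$evalue <= max_evalue)

  all_asvs <- unique(hits$qseqid)
  passing <- joined |> filter(.data$passes)

  assigned <- if (nrow(passing) == 0) {
    tibble(asv_id = character())
  } else {
    passing |>
      group_by(asv_id = .data$qseqid) |>
      group_lca() |>
      ungroup()
  }

  unassigned_ids <- setdiff(all_asvs, assigned$asv_id)
  if (length(unassigned_ids)) {
    blank <- tibble(asv_id = unassigned_ids)
    for (r in TAXON_RANKS) blank[[r]] <- NA_character_
    blank$rank <- "unassigned"
    blank$best_pct_identity <- NA_real_
    assigned <- bind_rows(assigned, blank)
  }
  assigned |> arrange(match(.data$asv_id, all_asvs))
}

# LCA within an already-grouped tibble of passing hits.
#' @keywords internal
group_lca <- function(grouped) {
  dplyr::group_modify(grouped, function(df, key) {
    lineages <- distinct(df[, TAXON_RANKS])
    lca <- lineages[1, , drop = FALSE]
    if (nrow(lineages) > 1) {
      for (i in seq_along(TAXON_RANKS)) {
        r <- TAXON_RANKS[i]
        vals <- unique(lineages[[r]])
        if (length(vals) > 1 || all(is.na(vals)) || any(vals == "", na.rm = TRUE)) {
          # disagreement (or emptiness) at this rank: truncate from here down
          lca[TAXON_RANKS[i:length(TAXON_RANKS)]] <- NA_character_
          break
        }
      }
    }
    lca$rank <- deepest_rank(lca)
    lca$best_pct_identity <- max(df$pident)
    lca
  })
}

#' @keywords internal
deepest_rank <- function(lineage_row) {
  vals <- unlist(lineage_row[1, TAXON_RANKS])
  nonempty <- !is.na(vals) & vals != ""
  if (!any(nonempty)) "unassigned" else TAXON_RANKS[max(which(nonempty))]
}

#' @keywords internal
taxon_label <- function(lineage_row) {
  r <- lineage_row$rank
  if (r %in% TAXON_RANKS) lineage_row[[r]] else NA_character_
}

#' Default non-target exclusion labels
#'
#' Lineage labels treated as non-target in stomach-content metabarcoding:
#' microbial kingdoms and taxa too small to be targeted prey (diatoms,
#' rotifers, unicellular algae). Matching is by equality against any of the
#' seven lineage fields.
#'
#' @return Character vector of lineage labels.
#' @export
default_nontarget_taxa <- function() {
  c("Bacteria", "Fungi", "Bacillariophyta", "Bacillariophyceae",
    "Rotifera", "Chrysophyceae", "Dinophyceae", "Cryptophyceae",
    "Apicomplexa", "Ciliophora")
}

#' Remove control, predator, and non-target ASVs
#'
#' Applies, in order: (1) removal of any ASV with at least one read in any
#' control sample (positive or negative); (2) removal of ASVs assigned to the
#' predator species, since predator and consumed-conspecific DNA cannot be
#' distinguished; (3) removal of ASVs whose lineage matches a non-target
#' exclusion label (bacteria, fungi, diatoms, rotifers, unicellular algae,
#' ...). A per-step report (ASVs and reads removed) is attached as attribute
#' `"filter_report"`.
#'
#' @param tab ASV tibble.
#' @param assignments Output of [assign_taxonomy()].
#' @param control_sample_ids Character vector of control sample columns.
#' @param predator Predator species binomial (default the European green
#'   crab, `"Carcinus maenas"`).
#' @param nontarget Lineage labels to exclude; see [default_nontarget_taxa()].
#' @return The filtered ASV tibble (control columns dropped), with attribute
#'   `"filter_report"`.
#' @export
remove_nonprey_asvs <- function(tab, assignments,
                                control_sample_ids = character(),
                                predator = "Carcinus maenas",
                                nontarget = default_nontarget_taxa()) {
  control_sample_ids <- intersect(control_sample_ids, names(tab))
  crab_cols <- setdiff(sample_columns(tab), control_sample_ids)
  if (!predator %in% c(assignments$species, assignments$genus)) {
    if (!any(vapply(assignments[TAXON_RANKS], function(x) predator %in% x, TRUE))) {
      abort(sprintf(
        "predator '%s' absent from reference lineages; check configuration",
        predator
      ))
    }
  }
  report <- list()
  note_step <- function(step, removed_tab) {
    tibble(step = step,
           n_asvs_removed = nrow(removed_tab),
           n_reads_removed = if (nrow(removed_tab)) {
             sum(as.matrix(removed_tab[, crab_cols]))
           } else 0L)
  }

  in_controls <- if (length(control_sample_ids)) {
    rowSums(as.matrix(tab[, control_sample_ids, drop = FALSE])) > 0
  } else rep(FALSE, nrow(tab))
  report$controls <- note_step("control_samples", tab[in_controls, ])
  tab <- tab[!in_controls, ]

  pred_asvs <- assignments$asv_id[!is.na(assignments$species) &
                                    assignments$species == predator]
  is_pred <- tab$asv_id %in% pred_asvs
  report$predator <- note_step("predator", tab[is_pred, ])
  tab <- tab[!is_pred, ]

  lin <- assignments[match(tab$asv_id, assignments$asv_id), TAXON_RANKS]
  is_nontarget <- apply(as.matrix(lin), 1, function(v) any(v %in% nontarget))
  report$nontarget <- note_step("nontarget", tab[is_nontarget, ])
  tab <- tab[!is_nontarget, ]

  out <- tab[, c(intersect(c("asv_id", "sequence"), names(tab)), crab_cols)]
  attr(out, "filter_report") <- list_rbind(unname(report))
  out
}

#' Collapse detections to species plus family-level add-backs, per crab
#'
#' Species-rank taxa are always retained. A genus- or family-rank taxon is
#' retained for a crab only if no retained deeper-rank taxon of that crab
#' lies within it (a retained species blocks its genus and family; a retained
#' genus blocks its family). Ranks above family are never retained.
#'
#' @param detections Tibble with one row per (crab, taxon) detection:
#'   `crab_id`, the seven lineage columns, `rank`, and a `taxon` label.
#' @return Tibble of retained (crab, taxon) rows, same columns.
#' @export
collapse_species_plus_family <- function(detections) {
  detections |>
    filter(.data$rank %in% c("species", "genus", "family")) |>
    group_by(.data$crab_id) |>
    dplyr::group_modify(function(df, key) {
      sp <- df[df$rank == "species", ]
      gen <- df[df$rank == "genus", ]
      gen <- gen[!(gen$genus %in% sp$genus[!is.na(sp$genus)]), ]
      fam <- df[df$rank == "family", ]
      blocked_fams <- unique(c(sp$family[!is.na(sp$family)],
                               gen$family[!is.na(gen$family)]))
      fam <- fam[!(fam$family %in% blocked_fams), ]
      bind_rows(sp, gen, fam)
    }) |>
    ungroup() |>
    distinct()
}

#' Decide retention of a non-native taxon
#'
#' The decision tree guarding against mis-assignment of uncatalogued native
#' taxa to non-native close relatives:
#' \itemize{
#'   \item \strong{native}: retain.
#'   \item \strong{previously detected non-native}: retain if percent
#'     identity > 95, or if <= 95 but native sister taxa are represented in
#'     the reference database; otherwise demote a species-rank identification
#'     to its genus, and remove non-species-rank identifications.
#'   \item \strong{previously undetected non-native}: retain only if percent
#'     identity > 98 \emph{and} native sisters are in the reference; otherwise
#'     demote a species-rank identification to genus when a native congener
#'     exists in the reference, else remove.
#' }
#' Boundaries are strict (`> 95`, `> 98`); the 94 floor applied upstream is
#' inclusive.
#'
#' @param status One of `native`, `nonnative_detected`, `nonnative_undetected`
#'   (vectorized).
#' @param pct_identity Best percent identity (0-100).
#' @param sister_in_reference Logical: native sister taxa represented in the
#'   reference database.
#' @param rank Assignment rank (`species`, `genus`, `family`).
#' @param detected_threshold Identity threshold (exclusive) above which a
#'   previously detected non-native is retained outright (default 95).
#' @param undetected_threshold Identity threshold (exclusive) for retaining
#'   a previously undetected non-native with sisters in the reference
#'   (default 98).
#' @return Character vector in `{retain, demote_to_genus, remove}`.
#' @export
decide_nonnative <- function(status, pct_identity, sister_in_reference, rank,
                             detected_threshold = 95,
                             undetected_threshold = 98) {
  n <- max(length(status), length(pct_identity), length(sister_in_reference),
           length(rank))
  status <- rep_len(status, n)
  pct_identity <- rep_len(pct_identity, n)
  sister_in_reference <- rep_len(sister_in_reference, n)
  rank <- rep_len(rank, n)
  if (any(!status %in% c("native", "nonnative_detected", "nonnative_undetected"))) {
    bad <- unique(status[!status %in%
                           c("native", "nonnative_detected", "nonnative_undetected")])
    abort(sprintf("native status '%s' requires curation before filtering",
                  paste(bad, collapse = ", ")))
  }
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (status[i] == "native") {
      "retain"
    } else if (status[i] == "nonnative_detected") {
      if (pct_identity[i] > detected_threshold ||
          (pct_identity[i] <= detected_threshold &&
             isTRUE(sister_in_reference[i]))) {
        "retain"
      } else if (rank[i] == "species") "demote_to_genus" else "remove"
    } else { # nonnative_undetected
      if (pct_identity[i] > undetected_threshold &&
          isTRUE(sister_in_reference[i])) {
        "retain"
      } else if (rank[i] == "species" && isTRUE(sister_in_reference[i])) {
        "demote_to_genus"
      } else "remove"
    }
  }
  out
}

#' Apply the non-native decision tree to retained taxa
#'
#' Joins the curated native-status table, decides each taxon with
#' [decide_nonnative()], and applies the decision: demoted species-rank taxa
#' are truncated to genus rank (and deduplicated against congeners already
#' retained for the same crab); removed taxa are dropped. Taxa absent from
#' the status table raise an error demanding curation.
#'
#' @param retained Per-crab retained taxa (see
#'   [collapse_species_plus_family()]), with `best_pct_identity`.
#' @param native_status Curated table from [read_native_status()].
#' @inheritParams decide_nonnative
#' @return The filtered per-crab taxon tibble, with a `decision` attribute
#'   table (taxon, status, decision).
#' @export
apply_nonnative_rules <- function(retained, native_status,
                                  detected_threshold = 95,
                                  undetected_threshold = 98) {
  st <- native_status[match(retained$taxon, native_status$taxon), ]
  missing <- unique(retained$taxon[is.na(st$status)])
  if (length(missing)) {
    abort(sprintf("native status unknown for taxa: %s; curate the status table",
                  paste(missing, collapse = ", ")))
  }
  decision <- decide_nonnative(st$status, retained$best_pct_identity,
                               st$sister_in_reference, retained$rank,
                               detected_threshold, undetected_threshold)
  decision_table <- distinct(tibble(taxon = retained$taxon, status = st$status,
                                    decision = decision))
  out <- retained
  out$decision <- decision
  out <- out[out$decision != "remove", ]
  demote <- out$decision == "demote_to_genus"
  if (any(demote)) {
    out$species[demote] <- NA_character_
    out$rank[demote] <- "genus"
    out$taxon[demote] <- out$genus[demote]
    out <- out[!(demote & is.na(out$genus)), ] # species with no genus: drop
  }
  out$decision <- NULL
  out <- distinct(out, .data$crab_id, .data$taxon, .keep_all = TRUE)
  attr(out, "decision_table") <- decision_table
  out
}

#' Build the crab-by-prey-taxon matrix
#'
#' Sums reads across technical replicates (and across the ASVs mapping to a
#' taxon) for every retained (crab, taxon) pair. Crabs whose ASVs were all
#' filtered out are excluded from the matrix but listed in the
#' `"excluded_crabs"` attribute. The presence/absence view is
#' [prey_presence()].
#'
#' @param tab Filtered ASV tibble (after [remove_nonprey_asvs()]).
#' @param assignments ASV taxonomy from [assign_taxonomy()].
#' @param retained Per-crab retained taxa (after [apply_nonnative_rules()]).
#' @param meta Sample metadata ([read_sample_meta()]).
#' @return A wide tibble: `crab_id`, `site`, `site_type`, then one integer
#'   column per retained taxon. Attributes: `"taxon_info"` (taxon, rank,
#'   lineage), `"excluded_crabs"`.
#' @export
build_prey_matrix <- function(tab, assignments, retained, meta) {
  meta <- meta[!meta$is_control, ]
  unknown <- setdiff(sample_columns(tab), meta$sample_id)
  if (length(unknown)) {
    abort(sprintf("samples in ASV table missing from metadata: %s",
                  paste(unknown, collapse = ", ")))
  }
  long <- tab |>
    tidyr::pivot_longer(all_of(intersect(sample_columns(tab), meta$sample_id)),
                        names_to = "sample_id", values_to = "reads") |>
    filter(.data$reads > 0) |>
    left_join(meta[, c("sample_id", "crab_id")], by = "sample_id")

  asv_lineage <- assignments[match(long$asv_id, assignments$asv_id), ]
  long$asv_species <- asv_lineage$species
  long$asv_genus <- asv_lineage$genus
  long$asv_family <- asv_lineage$family

  # An ASV contributes to the deepest retained taxon (for that crab) that
  # contains it: its species, else its genus, else its family.
  key <- function(crab, taxon) paste(crab, taxon, sep = "\r")
  retained_keys <- key(retained$crab_id, retained$taxon)
  hit_level <- function(crab, value) {
    !is.na(value) & key(crab, value) %in% retained_keys
  }
  tax_match <- dplyr::case_when(
    hit_level(long$crab_id, long$asv_species) ~ long$asv_species,
    hit_level(long$crab_id, long$asv_genus) ~ long$asv_genus,
    hit_level(long$crab_id, long$asv_family) ~ long$asv_family,
    .default = NA_character_
  )
  long$taxon <- tax_match
  cells <- long |>
    filter(!is.na(.data$taxon)) |>
    group_by(.data$crab_id, .data$taxon) |>
    summarise(reads = sum(.data$reads), .groups = "drop")

  taxa <- sort(unique(retained$taxon))
  crabs_meta <- distinct(meta[, c("crab_id", "site", "site_type")])
  wide <- cells |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "reads",
                       values_fill = 0L) |>
    left_join(crabs_meta, by = "crab_id") |>
    relocate(all_of(c("crab_id", "site", "site_type")))
  for (t in setdiff(taxa, names(wide))) wide[[t]] <- 0L
  wide <- wide[, c("crab_id", "site", "site_type", taxa)]

  excluded <- setdiff(unique(meta$crab_id), wide$crab_id)
  taxon_info <- retained |>
    distinct(.data$taxon, .data$rank, across(all_of(TAXON_RANKS))) |>
    distinct(.data$taxon, .keep_all = TRUE)

  out <- as_tibble(wide)
  attr(out, "taxon_info") <- taxon_info
  attr(out, "excluded_crabs") <- excluded
  out
}

#' Presence/absence view of a prey matrix
#'
#' @param prey Prey matrix from [build_prey_matrix()].
#' @return Same shape with logical cells (`reads > 0`).
#' @export
prey_presence <- function(prey) {
  taxa <- prey_taxa(prey)
  out <- prey
  out[taxa] <- lapply(out[taxa], function(x) x > 0)
  out
}

#' @keywords internal
prey_taxa <- function(prey) setdiff(names(prey), c("crab_id", "site", "site_type"))

#' Run the full prey-taxon filtering chain
#'
#' Convenience wrapper: taxonomy assignment, control/predator/non-target
#' removal, per-crab detection, species-plus-family collapse, non-native
#' rules, and prey-matrix construction, in that order. The chain is
#' idempotent: its output taxa re-enter it unchanged.
#'
#' @inheritParams assign_taxonomy
#' @inheritParams remove_nonprey_asvs
#' @param tab ASV tibble.
#' @param native_status Curated status table.
#' @param meta Sample metadata; control samples flagged with `is_control`.
#' @return List: `prey` (the prey matrix), `assignments`, `retained`,
#'   `tab` (the filtered ASV table), `report` (per-step removal counts).
#' @export
filter_prey_taxa <- function(tab, hits, taxonomy, native_status, meta,
                             predator = "Carcinus maenas",
                             nontarget = default_nontarget_taxa(),
                             min_pct_identity = 94, max_evalue = 1e-30,
                             detected_threshold = 95,
                             undetected_threshold = 98) {
  meta <- validate_sample_meta(meta)
  assignments <- assign_taxonomy(hits, taxonomy,
                                 min_pct_identity = min_pct_identity,
                                 max_evalue = max_evalue)
  controls <- meta$sample_id[meta$is_control]
  tab_f <- remove_nonprey_asvs(tab, assignments, control_sample_ids = controls,
                               predator = predator, nontarget = nontarget)
  detections <- detect_crab_taxa(tab_f, assignments, meta)
  collapsed <- collapse_species_plus_family(detections)
  final <- apply_nonnative_rules(collapsed, native_status,
                                 detected_threshold, undetected_threshold)
  prey <- build_prey_matrix(tab_f, assignments, final, meta)
  list(prey = prey, assignments = assignments, retained = final,
       tab = tab_f, report = attr(tab_f, "filter_report"))
}

# Per-crab taxon detections: any ASV of the taxon with >0 reads in any of the
# crab's replicates. Carries best identity (max over the crab's ASVs).
#' @keywords internal
detect_crab_taxa <- function(tab, assignments, meta) {
  meta <- meta[!meta$is_control, ]
  samples <- intersect(sample_columns(tab), meta$sample_id)
  long <- tab |>
    tidyr::pivot_longer(all_of(samples), names_to = "sample_id",
                        values_to = "reads") |>
    filter(.data$reads > 0) |>
    left_join(meta[, c("sample_id", "crab_id")], by = "sample_id") |>
    distinct(.data$crab_id, .data$asv_id) |>
    left_join(assignments, by = "asv_id") |>
    filter(.data$rank %in% TAXON_RANKS)
  long$taxon <- vapply(seq_len(nrow(long)), function(i) {
    long[[long$rank[i]]][i]
  }, character(1))
  long |>
    group_by(.data$crab_id, .data$taxon, .data$rank,
             across(all_of(TAXON_RANKS))) |>
    summarise(best_pct_identity = max(.data$best_pct_identity, na.rm = TRUE),
              .groups = "drop")
}
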