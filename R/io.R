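#' Read an ASV-by-sample read-count table
#'
#' Reads a tab-separated table with an `asv_id` column, an optional `sequence`
#' column, and one integer read-count column per sample. This is the entry
#' point of the pipeline: everything upstream (demultiplexing, primer
#' trimming, denoising) is assumed done.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `asv_id`, optionally `sequence`, and one
#'   non-negative integer column per sample.
#' @export
read_asv_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE, show_col_types = FALSE)
  validate_asv_table(tab, src = path)
}

#' @keywords internal
validate_asv_table <- function(tab, src = "asv table") {
  if (!"asv_id" %in% names(tab)) {
    abort(sprintf("%s: missing required column 'asv_id'", src))
  }
  if (anyDuplicated(tab$asv_id)) {
    dup <- unique(tab$asv_id[duplicated(tab$asv_id)])
    abort(sprintf("%s: duplicated asv_id: %s", src, paste(dup, collapse = ", ")))
  }
  sample_cols <- setdiff(names(tab), c("asv_id", "sequence"))
  if (length(sample_cols) == 0) {
    abort(sprintf("%s: no sample columns found", src))
  }
  for (cl in sample_cols) {
    x <- tab[[cl]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
        any(abs(x - round(x)) > 1e-8)) {
      bad <- which(!is.finite(x) | x < 0 | abs(x - round(x)) > 1e-8)[1]
      abort(sprintf(
        "%s: column '%s' row %d ('%s') is not a non-negative integer count",
        src, cl, bad, tab$asv_id[bad]
      ))
    }
    tab[[cl]] <- as.integer(round(x))
  }
  as_tibble(tab)
}

#' Write an ASV table
#'
#' Inverse of [read_asv_table()]; `write_asv_table()` then `read_asv_table()`
#' round-trips exactly.
#'
#' @param tab ASV tibble as returned by [read_asv_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @keywords internal
sample_columns <- function(tab) setdiff(names(tab), c("asv_id", "sequence"))

BLAST12 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read tabular BLAST hits (outfmt-6 dialect)
#'
#' Parses the standard 12-column tabular alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query/subject
#' coordinates, e-value, bit score), with optional appended columns (e.g.
#' subject taxonomy id or scientific name). No deduplication is performed:
#' multiple hits per query are retained for downstream last-common-ancestor
#' resolution.
#'
#' @param path Path to a headerless TSV of BLAST hits.
#' @param extra_cols Names for any columns beyond the standard 12
#'   (default: `staxids`, `sscinames`, ... as many as present).
#' @return A tibble with the 12 standard columns (percent identity on the
#'   0-100 scale, e-value as double) plus any extras.
#' @export
read_blast_table <- function(path, extra_cols = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 12) {
    abort(sprintf("%s: BLAST tabular format requires >= 12 columns, found %d",
                  path, ncol(raw)))
  }
  n_extra <- ncol(raw) - 12L
  extras <- if (n_extra > 0) {
    if (is.null(extra_cols)) paste0("extra", seq_len(n_extra)) else extra_cols[seq_len(n_extra)]
  } else character()
  names(raw) <- c(BLAST12, extras)
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore")
  for (cl in num_cols) {
    x <- suppressWarnings(as.numeric(raw[[cl]]))
    if (any(is.na(x) & !is.na(raw[[cl]]))) {
      bad <- which(is.na(x) & !is.na(raw[[cl]]))[1]
      abort(sprintf("%s: unparsable value '%s' in column %s (row %d)",
                    path, raw[[cl]][bad], cl, bad))
    }
    raw[[cl]] <- x
  }
  if (any(raw$pident < 0 | raw$pident > 100, na.rm = TRUE)) {
    abort(sprintf("%s: percent identity outside [0, 100]", path))
  }
  if (any(raw$evalue < 0, na.rm = TRUE)) {
    abort(sprintf("%s: negative e-value", path))
  }
  as_tibble(raw)
}

#' Read sample metadata
#'
#' @param path CSV with columns `sample_id`, `crab_id`, `replicate`, `site`,
#'   `site_type` (`clam_bed` or `slough`), `n_pcr_cycles` (total across both
#'   PCR steps, e.g. 40/43/47), optional `collection_month`. Control samples
#'   (PCR/extraction positives and negatives) may be listed with `crab_id`
#'   `NA` and `is_control = TRUE`.
#' @return A validated tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_meta(meta, src = path)
}

#' @keywords internal
validate_sample_meta <- function(meta, src = "sample metadata") {
  need <- c("sample_id", "crab_id", "replicate", "site", "site_type", "n_pcr_cycles")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(sprintf("%s: missing columns: %s", src, paste(missing, collapse = ", ")))
  }
  if (!"is_control" %in% names(meta)) meta$is_control <- FALSE
  meta$is_control[is.na(meta$is_control)] <- FALSE
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf("%s: duplicated sample_id", src))
  }
  crab <- meta[!meta$is_control, ]
  key <- paste(crab$crab_id, crab$replicate)
  if (anyDuplicated(key)) {
    abort(sprintf("%s: duplicated (crab_id, replicate) pair", src))
  }
  bad_type <- setdiff(unique(crab$site_type), c("clam_bed", "slough"))
  if (length(bad_type)) {
    abort(sprintf("%s: unknown site_type: %s", src, paste(bad_type, collapse = ", ")))
  }
  if (any(!is.finite(crab$n_pcr_cycles)) || any(crab$n_pcr_cycles < 1)) {
    abort(sprintf("%s: n_pcr_cycles must be >= 1", src))
  }
  as_tibble(meta)
}

#' Read a subject-keyed taxonomy table
#'
#' @param path CSV keyed by BLAST subject id (`subject`) with the seven
#'   lineage columns `kingdom` ... `species`. Lower ranks may be empty.
#' @return A tibble.
#' @export
read_taxonomy_table <- function(path) {
  tax <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("subject", TAXON_RANKS)
  missing <- setdiff(need, names(tax))
  if (length(missing)) {
    abort(sprintf("%s: missing columns: %s", path, paste(missing, collapse = ", ")))
  }
  as_tibble(tax)
}

#' Read the curated native-status table
#'
#' Native-status classification (native / previously detected non-native /
#' previously undetected non-native) is curated manually against external
#' registries, so it enters the pipeline as data: one row per taxon with its
#' status and whether native sister taxa are represented in the BLAST
#' reference database.
#'
#' @param path CSV with columns `taxon`, `status` (one of `native`,
#'   `nonnative_detected`, `nonnative_undetected`), `sister_in_reference`
#'   (logical).
#' @return A tibble.
#' @export
read_native_status <- function(path) {
  st <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("taxon", "status", "sister_in_reference")
  missing <- setdiff(need, names(st))
  if (length(missing)) {
    abort(sprintf("%s: missing columns: %s", path, paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(st$status),
                 c("native", "nonnative_detected", "nonnative_undetected"))
  if (length(bad)) {
    abort(sprintf("%s: unknown status values: %s", path, paste(bad, collapse = ", ")))
  }
  st$sister_in_reference <- as.logical(st$sister_in_reference)
  as_tibble(st)
}

#' Read mock-community design and read counts
#'
#' @param path CSV with columns `community_id`, `species`, `known_prop`
#'   (DNA proportion of the species in the community; sums to 1 within each
#'   community), `n_pcr_cycles`, `replicate`, `reads`.
#' @return A validated tibble.
#' @export
read_mock_communities <- function(path) {
  mc <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_mock_communities(mc, src = path)
}

#' @keywords internal
validate_mock_communities <- function(mc, src = "mock communities") {
  need <- c("community_id", "species", "known_prop", "n_pcr_cycles", "replicate", "reads")
  missing <- setdiff(need, names(mc))
  if (length(missing)) {
    abort(sprintf("%s: missing columns: %s", src, paste(missing, collapse = ", ")))
  }
  if (any(mc$known_prop <= 0)) {
    abort(sprintf("%s: known_prop must be > 0 for included species", src))
  }
  if (any(mc$reads < 0)) abort(sprintf("%s: negative reads", src))
  sums <- mc |>
    distinct(.data$community_id, .data$species, .data$known_prop) |>
    group_by(.data$community_id) |>
    summarise(s = sum(.data$known_prop), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-6)) {
    bad <- sums$community_id[abs(sums$s - 1) > 1e-6]
    abort(sprintf("%s: known_prop does not sum to 1 in community %s",
                  src, paste(bad, collapse = ", ")))
  }
  as_tibble(mc)
}
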