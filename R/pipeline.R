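#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. Identity thresholds are on the
#' 0-100 percent scale throughout.
#'
#' @param min_pct_identity Inclusive BLAST identity floor (default 94).
#' @param detected_nonnative_identity Exclusive retention threshold for
#'   previously detected non-natives (default 95).
#' @param undetected_nonnative_identity Exclusive retention threshold for
#'   previously undetected non-natives (default 98).
#' @param max_evalue Inclusive e-value ceiling (default 1e-30).
#' @param min_word_size Informational: BLAST search word size (default 15).
#' @param n_permutations Label permutations for the tests (default 999).
#' @param rng_seed Master seed; every stochastic stage derives its own
#'   stream from it (default 1).
#' @param reference_species Calibration reference (default Manila clam).
#' @param predator Predator species (default green crab).
#' @param count_divisor Depth divisor for the average-diet count matrix
#'   (default 100).
#' @param mcmc List: `chains`, `iter` for the diet model (defaults 4, 1500).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_pct_identity = 94,
                            detected_nonnative_identity = 95,
                            undetected_nonnative_identity = 98,
                            max_evalue = 1e-30, min_word_size = 15,
                            n_permutations = 999, rng_seed = 1,
                            reference_species = "Ruditapes philippinarum",
                            predator = "Carcinus maenas",
                            count_divisor = 100,
                            mcmc = list(chains = 4, iter = 1500)) {
  ids <- c(min_pct_identity, detected_nonnative_identity,
           undetected_nonnative_identity)
  if (any(ids <= 0) || any(ids > 100)) {
    abort("identity thresholds must lie in (0, 100]")
  }
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  if (count_divisor < 1) abort("count_divisor must be >= 1")
  if (max_evalue < 0) abort("max_evalue must be >= 0")
  structure(list(min_pct_identity = min_pct_identity,
                 detected_nonnative_identity = detected_nonnative_identity,
                 undetected_nonnative_identity = undetected_nonnative_identity,
                 max_evalue = max_evalue, min_word_size = min_word_size,
                 n_permutations = n_permutations, rng_seed = rng_seed,
                 reference_species = reference_species, predator = predator,
                 count_divisor = count_divisor, mcmc = mcmc),
            class = "pipeline_config")
}

#' @keywords internal
as_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full diet-analysis pipeline
#'
#' Executes every stage on a set of inputs (paths or in-memory tibbles):
#' prey-taxon filtering, diversity and permutation statistics,
#' mock-community calibration, per-crab DNA-proportion estimation, and the
#' average-diet model per site type. All numeric outputs are written as
#' TSV/CSV/JSON under `out_dir`; the run is byte-reproducible for a fixed
#' config, seed, and inputs. Any stage failure aborts with a stage-named
#' error.
#'
#' @param asv_table,blast,taxonomy,native_status,meta,mocks Inputs: file
#'   paths (TSV for the ASV table and BLAST hits, CSV otherwise) or tibbles
#'   in the corresponding reader's format.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results (`prey`, `diversity`,
#'   `calibration`, `calibrated`, `diet`) and `paths` of everything written.
#' @export
run_pipeline <- function(asv_table, blast, taxonomy, native_status, meta,
                         mocks, out_dir, config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  seed <- as.integer(config$rng_seed)

  inputs <- stage("read_inputs", list(
    tab = as_input(asv_table, read_asv_table),
    blast = as_input(blast, read_blast_table),
    taxonomy = as_input(taxonomy, read_taxonomy_table),
    status = as_input(native_status, read_native_status),
    meta = validate_sample_meta(as_input(meta, read_sample_meta)),
    mocks = validate_mock_communities(as_input(mocks, read_mock_communities))
  ))

  filt <- stage("taxonomy_filter", filter_prey_taxa(
    inputs$tab, inputs$blast, inputs$taxonomy, inputs$status, inputs$meta,
    predator = config$predator,
    min_pct_identity = config$min_pct_identity,
    max_evalue = config$max_evalue,
    detected_threshold = config$detected_nonnative_identity,
    undetected_threshold = config$undetected_nonnative_identity))
  prey <- filt$prey
  paths$prey_matrix <- file.path(out_dir, "prey_matrix.tsv")
  readr::write_tsv(prey, paths$prey_matrix, progress = FALSE)
  paths$filter_report <- file.path(out_dir, "filter_report.json")
  jsonlite::write_json(list(
    steps = filt$report,
    excluded_crabs = attr(prey, "excluded_crabs")
  ), paths$filter_report, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  diversity <- stage("community_stats", {
    pres <- prey_presence(prey)
    idx <- suppressWarnings(edna_index(prey))
    d_jac <- distance_matrix(pres, "jaccard")
    d_bc <- distance_matrix(idx, "bray_curtis")
    groups <- prey$site
    run_tests <- function(d, label, offs) {
      pm <- permanova(d, groups, n_perm = config$n_permutations,
                      seed = derive_seed(seed, offs))
      pd <- permdisp(d, groups, n_perm = config$n_permutations,
                     seed = derive_seed(seed, offs + 1L))
      pw <- pairwise_permanova(d, groups, n_perm = config$n_permutations,
                               seed = derive_seed(seed, offs + 2L))
      list(metric = label, permanova = pm, permdisp = pd, pairwise = pw)
    }
    list(alpha = alpha_diversity(prey),
         beta = beta_diversity_table(prey),
         jaccard = run_tests(d_jac, "jaccard", 100L),
         bray_curtis = run_tests(d_bc, "bray_curtis", 200L),
         d_jac = d_jac, d_bc = d_bc)
  })
  paths$alpha <- file.path(out_dir, "alpha_diversity.csv")
  readr::write_csv(diversity$alpha, paths$alpha, progress = FALSE)
  paths$beta <- file.path(out_dir, "beta_diversity.csv")
  readr::write_csv(diversity$beta, paths$beta, progress = FALSE)
  test_table <- list_rbind(lapply(list(diversity$jaccard, diversity$bray_curtis),
    function(x) {
      bind_rows(
        mutate(tidy(x$permanova), metric = x$metric, test = "permanova"),
        mutate(tidy(x$permdisp), metric = x$metric, test = "permdisp"))
    }))
  paths$tests <- file.path(out_dir, "permutation_tests.csv")
  readr::write_csv(test_table, paths$tests, progress = FALSE)
  pairwise_table <- list_rbind(lapply(list(diversity$jaccard, diversity$bray_curtis),
    function(x) mutate(x$pairwise, metric = x$metric, .before = 1)))
  paths$pairwise <- file.path(out_dir, "pairwise_tests.csv")
  readr::write_csv(pairwise_table, paths$pairwise, progress = FALSE)

  calib <- stage("calibration",
                 fit_amplification_efficiencies(inputs$mocks,
                                                reference = config$reference_species))
  paths$alpha_estimates <- file.path(out_dir, "amplification_efficiencies.csv")
  readr::write_csv(calib$estimates, paths$alpha_estimates, progress = FALSE)

  calibrated <- stage("calibrate_samples", {
    meta_low <- select_lowest_cycle_replicates(inputs$meta)
    reads_long <- species_replicate_reads(inputs$tab, inputs$blast,
                                          inputs$taxonomy, meta_low,
                                          species = setdiff(calib$estimates$species,
                                                            config$predator),
                                          min_pct_identity = config$min_pct_identity,
                                          max_evalue = config$max_evalue)
    # keep only crabs that made it into the filtered prey dataset
    reads_long <- reads_long[reads_long$crab_id %in% prey$crab_id, ]
    calibrate_samples(reads_long, calib, seed = derive_seed(seed, 300L))
  })
  paths$calibrated <- file.path(out_dir, "calibrated_proportions.csv")
  readr::write_csv(calibrated, paths$calibrated, progress = FALSE)

  diet <- stage("diet_composition", {
    meta_low <- select_lowest_cycle_replicates(inputs$meta)
    depths <- replicate_depths(inputs$tab, meta_low)
    counts <- build_estimated_counts(calibrated, depths,
                                     divisor = config$count_divisor)
    average_diet_by_site_type(counts, inputs$meta,
                              chains = config$mcmc$chains,
                              iter = config$mcmc$iter,
                              seed = derive_seed(seed, 400L))
  })
  paths$diet <- file.path(out_dir, "diet_composition.csv")
  readr::write_csv(diet$summary, paths$diet, progress = FALSE)

  paths$run_info <- file.path(out_dir, "run_info.json")
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("crabdiet")),
    r_version = as.character(getRversion()),
    rng_seed = seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config))
  ), paths$run_info, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(prey = prey, filter = filt, diversity = diversity,
                 calibration = calib, calibrated = calibrated, diet = diet,
                 paths = paths))
}

#' Per-species replicate read counts for calibration
#'
#' Sums reads over the ASVs assigned (at species rank) to each of a set of
#' species, per crab and technical replicate, carrying the replicate's total
#' PCR cycle count. This is the long-format input of
#' [calibrate_samples()].
#'
#' @param tab ASV tibble.
#' @param blast,taxonomy As in [assign_taxonomy()].
#' @param meta Sample metadata (typically after
#'   [select_lowest_cycle_replicates()]).
#' @param species Species to extract (e.g. the calibrated panel).
#' @inheritParams assign_taxonomy
#' @return Tibble `crab_id`, `replicate`, `species`, `reads`,
#'   `n_pcr_cycles`; zero rows are kept so replicate depth is explicit.
#' @export
species_replicate_reads <- function(tab, blast, taxonomy, meta, species,
                                    min_pct_identity = 94, max_evalue = 1e-30) {
  assignments <- assign_taxonomy(blast, taxonomy,
                                 min_pct_identity = min_pct_identity,
                                 max_evalue = max_evalue)
  meta <- meta[!meta$is_control, ]
  samples <- intersect(sample_columns(tab), meta$sample_id)
  sp_asvs <- assignments[assignments$rank == "species" &
                           assignments$species %in% species,
                         c("asv_id", "species")]
  long <- tab[tab$asv_id %in% sp_asvs$asv_id, c("asv_id", samples)] |>
    tidyr::pivot_longer(all_of(samples), names_to = "sample_id",
                        values_to = "reads") |>
    left_join(sp_asvs, by = "asv_id") |>
    left_join(meta[, c("sample_id", "crab_id", "replicate", "n_pcr_cycles")],
              by = "sample_id") |>
    group_by(.data$crab_id, .data$replicate, .data$species,
             .data$n_pcr_cycles) |>
    summarise(reads = sum(.data$reads), .groups = "drop")
  long[, c("crab_id", "replicate", "species", "reads", "n_pcr_cycles")]
}

#' Average replicate read depth per crab
#'
#' Total reads per replicate sample (all ASVs), averaged over each crab's
#' replicates; the effective multinomial size of the average-diet count
#' matrix before division.
#'
#' @param tab ASV tibble.
#' @param meta Sample metadata (after any replicate selection).
#' @return Tibble `crab_id`, `avg_depth`.
#' @export
replicate_depths <- function(tab, meta) {
  meta <- meta[!meta$is_control, ]
  samples <- intersect(sample_columns(tab), meta$sample_id)
  depths <- tibble(sample_id = samples,
                   depth = colSums(as.matrix(tab[, samples])))
  depths |>
    left_join(meta[, c("sample_id", "crab_id")], by = "sample_id") |>
    group_by(.data$crab_id) |>
    summarise(avg_depth = mean(.data$depth), .groups = "drop")
}
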