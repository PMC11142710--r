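# Synthetic-data generation: complete datasets (ASV table, BLAST hits,
# metadata, taxonomy, native status, mock communities) with known truth, so
# every pipeline stage can be tested without sequencing data. All species
# lineages and labels here are synthetic stand-ins except the mock-community
# panel, which uses the real species names so that reference-species
# conventions read naturally.

#' The calibrated-species panel with per-cycle efficiency offsets
#'
#' The ten mock-community species (reference Manila clam first) with the
#' default true per-cycle log-ratio amplification-efficiency offsets used by
#' the simulator, on the scale estimated for the BF3/BR2 COI primer pair
#' (about -0.01 to +0.09 per cycle), plus the predator.
#'
#' @return Named numeric vector of offsets (reference exactly 0).
#' @export
default_alpha_panel <- function() {
  c("Ruditapes philippinarum" = 0,
    "Zostera marina" = -0.0098,
    "Cottus asper" = 0.0360,
    "Hemigrapsus oregonensis" = 0.0402,
    "Leptocottus armatus" = 0.0478,
    "Batillaria attramentaria" = 0.0607,
    "Mya arenaria" = 0.0619,
    "Cymatogaster aggregata" = 0.0687,
    "Metacarcinus magister" = 0.0817,
    "Crangon franciscorum" = 0.0859,
    "Carcinus maenas" = 0.0896)
}

# Calibrated prey species (panel minus predator and the two species absent
# from field samples).
#' @keywords internal
calibrated_prey_species <- function() {
  setdiff(names(default_alpha_panel()),
          c("Carcinus maenas", "Zostera marina", "Cottus asper"))
}

#' @keywords internal
panel_lineages <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~species, ~kingdom, ~phylum, ~class, ~order, ~family, ~genus,
    "Ruditapes philippinarum", "Animalia", "Mollusca", "Bivalvia", "Venerida", "Veneridae", "Ruditapes",
    "Mya arenaria", "Animalia", "Mollusca", "Bivalvia", "Myida", "Myidae", "Mya",
    "Batillaria attramentaria", "Animalia", "Mollusca", "Gastropoda", "Caenogastropoda", "Batillariidae", "Batillaria",
    "Metacarcinus magister", "Animalia", "Arthropoda", "Malacostraca", "Decapoda", "Cancridae", "Metacarcinus",
    "Hemigrapsus oregonensis", "Animalia", "Arthropoda", "Malacostraca", "Decapoda", "Varunidae", "Hemigrapsus",
    "Hemigrapsus nudus", "Animalia", "Arthropoda", "Malacostraca", "Decapoda", "Varunidae", "Hemigrapsus",
    "Crangon franciscorum", "Animalia", "Arthropoda", "Malacostraca", "Decapoda", "Crangonidae", "Crangon",
    "Crangon alaskensis", "Animalia", "Arthropoda", "Malacostraca", "Decapoda", "Crangonidae", "Crangon",
    "Cymatogaster aggregata", "Animalia", "Chordata", "Actinopteri", "Perciformes", "Embiotocidae", "Cymatogaster",
    "Leptocottus armatus", "Animalia", "Chordata", "Actinopteri", "Perciformes", "Cottidae", "Leptocottus",
    "Cottus asper", "Animalia", "Chordata", "Actinopteri", "Perciformes", "Cottidae", "Cottus",
    "Zostera marina", "Plantae", "Streptophyta", "Magnoliopsida", "Alismatales", "Zosteraceae", "Zostera",
    "Carcinus maenas", "Animalia", "Arthropoda", "Malacostraca", "Decapoda", "Carcinidae", "Carcinus",
    "Macropus synthetic", "Animalia", "Chordata", "Mammalia", "Diprotodontia", "Macropodidae", "Macropus",
    "Bacterium commune", "Bacteria", "Proteobacteria", NA, NA, NA, NA,
    "Diatoma synthetica", "Chromista", "Ochrophyta", "Bacillariophyceae", "Naviculales", "Naviculaceae", "Navicula",
    "Nonnativa detecta", "Animalia", "Mollusca", "Gastropoda", "Caenogastropoda", "Nonnatividae", "Nonnativa",
    "Mixogenus exoticus", "Animalia", "Annelida", "Polychaeta", "Phyllodocida", "Mixogenidae", "Mixogenus",
    "Alienus solus", "Animalia", "Annelida", "Polychaeta", "Phyllodocida", "Alienidae", "Alienus"
  )
}

# Synthetic filler prey: Genus01 sp01 ... with nested higher ranks.
#' @keywords internal
filler_lineages <- function(n) {
  i <- seq_len(n)
  tibble(
    species = sprintf("Genus%02d sp%02d", i, i),
    kingdom = "Animalia",
    phylum = sprintf("Phylum%02d", (i - 1) %/% 16 + 1),
    class = sprintf("Class%02d", (i - 1) %/% 8 + 1),
    order = sprintf("Order%02d", (i - 1) %/% 4 + 1),
    family = sprintf("Family%02d", (i - 1) %/% 2 + 1),
    genus = sprintf("Genus%02d", i)
  )
}

#' Simulation configuration
#'
#' Default study conditions emulated by [simulate_dataset()]: 60 crabs over
#' four sites (two clam-bed, two slough), ~40 prey taxa, 8 calibrated
#' species, 3 technical replicates, replicate depths LogNormal(ln 5e4, 0.3),
#' total PCR cycles in \{40, 43, 47\} (35 first-round plus 5/8/12 indexing
#' cycles), species efficiency offsets on the estimated COI-primer scale,
#' and a site-type effect on diet composition (disable with
#' `site_effect = FALSE` for the null mode).
#'
#' @param n_crabs Number of crabs.
#' @param n_taxa Number of prey taxa (>= number of calibrated species).
#' @param n_replicates Technical replicates per crab.
#' @param site_effect Logical: do clam-bed and slough crabs have different
#'   diet distributions?
#' @param depth_meanlog,depth_sdlog Log-normal replicate depth parameters.
#' @param prob_empty Probability a crab has no prey DNA (predator reads
#'   only).
#' @param predator_share_range Range of the predator-read fraction per crab.
#' @param alpha_sd SD of filler-taxon efficiency offsets (truncated to
#'   \[-0.02, 0.09\]).
#' @return Named list of settings.
#' @export
sim_config <- function(n_crabs = 60, n_taxa = 40, n_replicates = 3,
                       site_effect = TRUE, depth_meanlog = log(5e4),
                       depth_sdlog = 0.3, prob_empty = 0.1,
                       predator_share_range = c(0.2, 0.6),
                       alpha_sd = 0.05) {
  k <- length(calibrated_prey_species())
  if (n_taxa < k) {
    abort(sprintf("n_taxa (%d) must be >= number of calibrated species (%d)",
                  n_taxa, k))
  }
  if (n_crabs < 8) abort("n_crabs must be >= 8 (two per site)")
  list(n_crabs = n_crabs, n_taxa = n_taxa, n_replicates = n_replicates,
       site_effect = site_effect, depth_meanlog = depth_meanlog,
       depth_sdlog = depth_sdlog, prob_empty = prob_empty,
       predator_share_range = predator_share_range, alpha_sd = alpha_sd)
}

#' Simulate a complete synthetic dataset with known truth
#'
#' Generates, per crab: a sparse true diet over the prey taxa (site-type
#' weighted in effect mode, taxon-exchangeable in null mode), replicate read
#' counts by multinomial sampling of the amplification forward model
#' ([forward_read_proportions()]), ASVs per taxon (1-3), a BLAST hit table
#' consistent with the taxonomy, and the supporting tables (sample metadata,
#' subject taxonomy, native-status curation, mock communities). Planted edge
#' cases exercise every filtering rule: predator ASVs in every crab, a
#' control-contaminated ASV, a sub-94-percent-identity ASV, a
#' multi-species-hit ASV (genus-level LCA), non-target (bacterial, diatom)
#' reads, and non-native taxa at identities straddling the 95/98 thresholds.
#'
#' @param config Settings from [sim_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param out_dir Optional directory; if given, all tables plus a
#'   `truth.json` are written there.
#' @return Invisibly, the truth bundle: list with `asv_table`, `meta`,
#'   `blast`, `taxonomy`, `native_status`, `mocks`, `truth` (per-crab true
#'   diets, true alpha, site assignments, seed), and `paths` when written.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1, out_dir = NULL) {
  bundle <- withr::with_seed(as.integer(seed), simulate_dataset_impl(config, seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      asv_table = file.path(out_dir, "asv_table.tsv"),
      meta = file.path(out_dir, "metadata.csv"),
      blast = file.path(out_dir, "blast_hits.tsv"),
      taxonomy = file.path(out_dir, "taxonomy.csv"),
      native_status = file.path(out_dir, "native_status.csv"),
      mocks = file.path(out_dir, "mock_communities.csv"),
      truth = file.path(out_dir, "truth.json")
    )
    write_asv_table(bundle$asv_table, paths$asv_table)
    readr::write_csv(bundle$meta, paths$meta, progress = FALSE)
    readr::write_tsv(bundle$blast, paths$blast, col_names = FALSE, progress = FALSE)
    readr::write_csv(bundle$taxonomy, paths$taxonomy, progress = FALSE)
    readr::write_csv(bundle$native_status, paths$native_status, progress = FALSE)
    readr::write_csv(bundle$mocks, paths$mocks, progress = FALSE)
    jsonlite::write_json(bundle$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    bundle$paths <- paths
  }
  invisible(bundle)
}

#' @keywords internal
simulate_dataset_impl <- function(config, seed) {
  cal_sp <- calibrated_prey_species()
  n_filler <- config$n_taxa - length(cal_sp)
  panel <- panel_lineages()
  fillers <- filler_lineages(max(n_filler, 1))[seq_len(n_filler), ]
  prey_taxa <- c(cal_sp, fillers$species,
                 "Nonnativa detecta", "Mixogenus exoticus", "Alienus solus")
  lineages <- bind_rows(panel, fillers)
  lineages <- lineages[!duplicated(lineages$species), ]

  # True efficiency offsets per species (per PCR cycle, reference = 0).
  alpha_true <- default_alpha_panel()
  extra_sp <- setdiff(lineages$species, names(alpha_true))
  a_extra <- rnorm(length(extra_sp), 0, config$alpha_sd)
  a_extra <- pmin(pmax(a_extra, -0.02), 0.09)
  alpha_true <- c(alpha_true, setNames(a_extra, extra_sp))

  # Sites: two per type; crabs allocated round-robin.
  sites <- tibble(site = c("Oysterville", "Long Beach", "Nahcotta", "Stackpole"),
                  site_type = c("clam_bed", "clam_bed", "slough", "slough"))
  crab_ids <- sprintf("CRAB%03d", seq_len(config$n_crabs))
  crab_site <- sites[rep_len(seq_len(4), config$n_crabs), ]

  # Site-type diet weights. Effect mode: calibrated species common on clam
  # beds; only three of them (plus a different filler block) at sloughs.
  # Effect mode: the two site types draw from near-disjoint taxon pools,
  # sharing only three calibrated species (the slough crabs' calibrated
  # prey); null mode is taxon-exchangeable across site types.
  shared_cal <- c("Hemigrapsus oregonensis", "Crangon franciscorum",
                  "Mya arenaria")
  half <- nrow(fillers) %/% 2
  weights_for <- function(site_type) {
    w <- setNames(rep(1, length(prey_taxa)), prey_taxa)
    if (!config$site_effect) {
      w[cal_sp] <- 3
      return(w)
    }
    w[] <- 0.02
    if (site_type == "clam_bed") {
      w[cal_sp] <- 4
      w[shared_cal] <- 2
      w[fillers$species[seq_len(half)]] <- 1.5
    } else {
      w[shared_cal] <- 5
      if (nrow(fillers) > half) {
        w[fillers$species[(half + 1):nrow(fillers)]] <- 1.5
      }
    }
    w
  }

  # Per-crab true diet (sparse; 1-3 taxa typical) and cycle counts.
  mixed_cycle_crabs <- crab_ids[seq_len(min(3, config$n_crabs))]
  diets <- list()
  crab_cycles <- list()
  for (i in seq_along(crab_ids)) {
    cid <- crab_ids[i]
    if (runif(1) < config$prob_empty) {
      diets[[cid]] <- numeric(0)
    } else {
      n_prey <- sample(1:5, 1, prob = c(0.35, 0.3, 0.2, 0.1, 0.05))
      w <- weights_for(crab_site$site_type[i])
      taxa <- sample(prey_taxa, n_prey, prob = w[prey_taxa])
      props <- as.numeric(rdirichlet(1, rep(1.5, n_prey)))
      diets[[cid]] <- setNames(props, taxa)
    }
    base_cycles <- sample(c(40, 43, 47), 1, prob = c(0.6, 0.3, 0.1))
    crab_cycles[[cid]] <- if (cid %in% mixed_cycle_crabs) {
      c(rep(43, config$n_replicates), rep(47, 2))
    } else {
      rep(base_cycles, config$n_replicates)
    }
  }

  # ASVs: 1-3 per prey taxon plus planted specials.
  asv_rows <- list()
  asv_counter <- 0
  new_asv <- function() {
    asv_counter <<- asv_counter + 1
    sprintf("ASV%04d", asv_counter)
  }
  for (sp in prey_taxa) {
    n_asv <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
    for (j in seq_len(n_asv)) {
      asv_rows[[length(asv_rows) + 1]] <-
        tibble(asv_id = new_asv(), species = sp, kind = "normal",
               weight = NA_real_)
    }
  }
  special <- function(species, kind) {
    tibble(asv_id = new_asv(), species = species, kind = kind, weight = NA_real_)
  }
  asv_rows <- c(asv_rows, list(
    special("Carcinus maenas", "predator"),
    special("Carcinus maenas", "predator"),
    special("Hemigrapsus oregonensis", "lca_genus"),   # hits both congeners
    special("Genus01 sp01", "sub94"),                   # only sub-threshold hits
    special("Genus02 sp02", "contaminated"),            # reads in NEG control
    special("Bacterium commune", "nontarget"),
    special("Diatoma synthetica", "nontarget"),
    special("Macropus synthetic", "positive_control")
  ))
  asv_map <- list_rbind(asv_rows)
  # within-taxon read split across its ASVs
  asv_map <- asv_map |>
    group_by(.data$species) |>
    mutate(weight = as.numeric(rdirichlet(1, rep(2, dplyr::n())))) |>
    ungroup()

  # Sample metadata.
  meta_rows <- list()
  for (i in seq_along(crab_ids)) {
    cid <- crab_ids[i]
    cyc <- crab_cycles[[cid]]
    meta_rows[[i]] <- tibble(
      sample_id = sprintf("%s_R%d", cid, seq_along(cyc)),
      crab_id = cid, replicate = seq_along(cyc),
      site = crab_site$site[i], site_type = crab_site$site_type[i],
      n_pcr_cycles = cyc, collection_month = sample(c("May", "Jul", "Sep"), 1),
      is_control = FALSE)
  }
  controls <- tibble(sample_id = c("POS1", "NEG1"),
                     crab_id = NA_character_, replicate = 1L,
                     site = NA_character_, site_type = NA_character_,
                     n_pcr_cycles = 40, collection_month = NA_character_,
                     is_control = TRUE)
  meta <- bind_rows(list_rbind(meta_rows), controls)

  # Read counts per sample.
  counts <- matrix(0L, nrow(asv_map), nrow(meta),
                   dimnames = list(asv_map$asv_id, meta$sample_id))
  contam_asv <- asv_map$asv_id[asv_map$kind == "contaminated"]
  pos_asv <- asv_map$asv_id[asv_map$kind == "positive_control"]
  nontarget_asvs <- asv_map$asv_id[asv_map$kind == "nontarget"]
  nontarget_species <- asv_map$species[asv_map$kind == "nontarget"]

  for (i in seq_along(crab_ids)) {
    cid <- crab_ids[i]
    diet <- diets[[cid]]
    pred_share <- runif(1, config$predator_share_range[1],
                        config$predator_share_range[2])
    other <- c("Carcinus maenas" = pred_share)
    if (runif(1) < 0.3) { # sprinkle non-target reads in some crabs
      other <- c(other, setNames(rep(0.005, length(nontarget_species)),
                                 nontarget_species))
    }
    prey_part <- if (length(diet)) diet * (1 - sum(other)) else numeric(0)
    comp <- c(prey_part, other)
    comp <- comp / sum(comp)
    cyc <- crab_cycles[[cid]]
    for (r in seq_along(cyc)) {
      depth <- round(stats::rlnorm(1, config$depth_meanlog, config$depth_sdlog))
      p_reads <- forward_read_proportions(comp, unname(alpha_true[names(comp)]),
                                          cyc[r])
      taxon_reads <- as.integer(rmultinom(1, depth, p_reads))
      sample_id <- sprintf("%s_R%d", cid, r)
      for (t in seq_along(comp)) {
        if (taxon_reads[t] == 0) next
        sub <- asv_map[asv_map$species == names(comp)[t] &
                         asv_map$kind != "positive_control", ]
        split <- as.integer(rmultinom(1, taxon_reads[t], sub$weight))
        counts[sub$asv_id, sample_id] <- counts[sub$asv_id, sample_id] + split
      }
    }
  }
  # Controls: kangaroo reads in the positive, contamination in the negative.
  counts[pos_asv, "POS1"] <- 45123L
  counts[contam_asv, "NEG1"] <- sample(5:40, length(contam_asv))

  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  asv_map <- asv_map[keep, ]
  bases <- c("A", "C", "G", "T")
  asv_table <- bind_cols(
    tibble(asv_id = rownames(counts),
           sequence = vapply(seq_len(nrow(counts)), function(i) {
             paste(sample(bases, 60, replace = TRUE), collapse = "")
           }, character(1))),
    as_tibble(counts)
  )

  # BLAST hits + subject taxonomy.
  acc_of <- setNames(sprintf("ACC%03d", seq_len(nrow(lineages))), lineages$species)
  blast_rows <- list()
  add_hit <- function(asv_id, species, pident, evalue = 1e-150, bitscore = 700) {
    blast_rows[[length(blast_rows) + 1]] <<- tibble(
      qseqid = asv_id, sseqid = acc_of[[species]], pident = pident,
      length = 418, mismatch = round(418 * (100 - pident) / 100), gapopen = 0,
      qstart = 1, qend = 418, sstart = 1, send = 418,
      evalue = evalue, bitscore = bitscore)
  }
  for (i in seq_len(nrow(asv_map))) {
    a <- asv_map$asv_id[i]
    sp <- asv_map$species[i]
    switch(asv_map$kind[i],
      normal = {
        pid <- if (sp == "Nonnativa detecta") 96.2
               else if (sp == "Mixogenus exoticus") 97.0
               else if (sp == "Alienus solus") 97.0
               else round(runif(1, 98, 100), 1)
        add_hit(a, sp, pid)
      },
      predator = add_hit(a, sp, 100),
      lca_genus = {
        add_hit(a, "Hemigrapsus oregonensis", 99.0)
        add_hit(a, "Hemigrapsus nudus", 98.6)
      },
      sub94 = add_hit(a, sp, 93.0),
      contaminated = add_hit(a, sp, round(runif(1, 98, 100), 1)),
      nontarget = add_hit(a, sp, round(runif(1, 95, 100), 1)),
      positive_control = add_hit(a, sp, 100)
    )
  }
  blast <- list_rbind(blast_rows)
  taxonomy <- tibble(subject = unname(acc_of[lineages$species])) |>
    bind_cols(lineages[, c("kingdom", "phylum", "class", "order", "family",
                           "genus", "species")])

  # Native-status curation: everything native except the three planted
  # non-natives (plus genus/family labels, which can be retained post-LCA).
  label_pool <- unique(c(lineages$species, lineages$genus, lineages$family))
  label_pool <- label_pool[!is.na(label_pool)]
  native_status <- tibble(taxon = label_pool, status = "native",
                          sister_in_reference = TRUE)
  native_status$status[native_status$taxon == "Nonnativa detecta"] <- "nonnative_detected"
  native_status$status[native_status$taxon == "Mixogenus exoticus"] <- "nonnative_undetected"
  native_status$status[native_status$taxon == "Alienus solus"] <- "nonnative_undetected"
  native_status$sister_in_reference[native_status$taxon == "Alienus solus"] <- FALSE

  mocks <- simulate_mock_communities(alpha_true, seed = derive_seed(seed, 11L))

  truth <- list(
    seed = seed,
    site_effect = config$site_effect,
    alpha = as.list(alpha_true),
    diets = lapply(diets, as.list),
    crab_sites = setNames(as.list(crab_site$site), crab_ids),
    crab_site_types = setNames(as.list(crab_site$site_type), crab_ids),
    cycles = crab_cycles
  )
  list(asv_table = asv_table, meta = meta, blast = blast, taxonomy = taxonomy,
       native_status = native_status, mocks = mocks, truth = truth,
       asv_map = asv_map)
}

#' Default mock-community designs
#'
#' Five communities over the ten-species panel (plus predator DNA in two of
#' them), including one with the reference species at a low proportion so
#' that detection of a weak amplifier is exercised.
#'
#' @return Tibble `community_id`, `species`, `known_prop`, `n_pcr_cycles`.
#' @export
default_mock_designs <- function() {
  panel <- names(default_alpha_panel())
  ten <- setdiff(panel, "Carcinus maenas")
  a <- tibble(community_id = "A", species = ten, known_prop = 1 / length(ten))
  b <- tibble(community_id = "B",
              species = c(ten[1:6], "Carcinus maenas"),
              known_prop = c(rep(0.1, 6), 0.4))
  c_ <- tibble(community_id = "C", species = calibrated_prey_species(),
               known_prop = 1 / 8)
  d <- tibble(community_id = "D",
              species = c("Ruditapes philippinarum", "Carcinus maenas",
                          "Crangon franciscorum", "Mya arenaria",
                          "Leptocottus armatus"),
              known_prop = c(0.02, 0.49, 0.2, 0.15, 0.14))
  e <- tibble(community_id = "E",
              species = c("Ruditapes philippinarum", "Zostera marina",
                          "Cottus asper", "Hemigrapsus oregonensis",
                          "Cymatogaster aggregata", "Batillaria attramentaria"),
              known_prop = c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05))
  out <- bind_rows(a, b, c_, d, e)
  out$n_pcr_cycles <- 43
  out
}

#' Simulate mock-community replicate read counts
#'
#' Applies the amplification forward model to each community's known DNA
#' proportions and draws multinomial replicate reads.
#'
#' @param alpha Named true efficiency-offset vector (see
#'   [default_alpha_panel()]).
#' @param designs Design tibble (see [default_mock_designs()]).
#' @param depth Expected replicate read depth (default 5e4).
#' @param n_replicates Replicates per community (default 3).
#' @param seed Integer seed.
#' @return Tibble in the [read_mock_communities()] format.
#' @export
simulate_mock_communities <- function(alpha, designs = default_mock_designs(),
                                      depth = 5e4, n_replicates = 3, seed = 1) {
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (cm in unique(designs$community_id)) {
      d <- designs[designs$community_id == cm, ]
      miss <- setdiff(d$species, names(alpha))
      if (length(miss)) {
        abort(sprintf("no true alpha for mock species: %s",
                      paste(miss, collapse = ", ")))
      }
      p <- forward_read_proportions(d$known_prop, unname(alpha[d$species]),
                                    d$n_pcr_cycles[1])
      for (r in seq_len(n_replicates)) {
        dep <- round(stats::rlnorm(1, log(depth), 0.2))
        reads <- as.integer(rmultinom(1, dep, p))
        out[[length(out) + 1]] <- tibble(
          community_id = cm, species = d$species, known_prop = d$known_prop,
          n_pcr_cycles = d$n_pcr_cycles[1], replicate = r, reads = reads)
      }
    }
    list_rbind(out)
  })
}

#' Small hand-enumerated filtering fixture
#'
#' A fixed miniature dataset (two crabs, a negative control, 13 ASVs) in
#' which the correct outcome of every filtering rule is enumerated by hand:
#' predator removal, control-based removal, non-target removal, sub-94
#' identity, genus-level LCA, species-blocks-genus collapse, family
#' add-back, rank-above-family drop, and all three non-native branches
#' (retain, demote-to-genus, remove). `expected` lists the truth.
#'
#' @param seed Seed for the (small, arbitrary) read counts.
#' @return List: `asv_table`, `blast`, `taxonomy`, `native_status`, `meta`,
#'   `expected` (tibble `crab_id`, `taxon` of the post-filter dataset).
#' @export
plant_filter_fixtures <- function(seed = 1) {
  withr::with_seed(as.integer(seed), {
    lineages <- bind_rows(panel_lineages(), tibble::tribble(
      ~species, ~kingdom, ~phylum, ~class, ~order, ~family, ~genus,
      "Hediste synthetica", "Animalia", "Annelida", "Polychaeta",
        "Phyllodocida", "Nereididae", "Hediste",
      "Alitta synthetica", "Animalia", "Annelida", "Polychaeta",
        "Phyllodocida", "Nereididae", "Alitta"
    ), filler_lineages(2))
    acc_of <- setNames(sprintf("FIX%03d", seq_len(nrow(lineages))),
                       lineages$species)
    hit <- function(asv, species, pident, evalue = 1e-120) {
      tibble(qseqid = asv, sseqid = unname(acc_of[species]), pident = pident,
             length = 418, mismatch = 2, gapopen = 0, qstart = 1, qend = 418,
             sstart = 1, send = 418, evalue = evalue, bitscore = 650)
    }
    blast <- bind_rows(
      hit("F01", "Carcinus maenas", 100),            # predator -> removed
      hit("F02", "Genus01 sp01", 99.1),              # reads in NEG -> removed
      hit("F03", "Bacterium commune", 99.0),         # non-target kingdom
      hit("F04", "Diatoma synthetica", 98.0),        # non-target class
      hit("F05", "Crangon franciscorum", 99.5),      # species retained, crab1
      hit("F06", "Crangon franciscorum", 98.8),      # congener pair -> genus
      hit("F06", "Crangon alaskensis", 98.2),        #   Crangon (LCA)
      hit("F07", "Mixogenus exoticus", 99.0),        # different families, same
      hit("F07", "Alienus solus", 98.4),             #   order -> above family
      hit("F08", "Hemigrapsus oregonensis", 99.3),   # species retained, crab2
      hit("F09", "Genus02 sp02", 93.0),              # below the 94 floor
      hit("F10", "Nonnativa detecta", 96.2),         # detected NN: retain
      hit("F11", "Mixogenus exoticus", 97.0),        # undetected NN + congener
      hit("F12", "Alienus solus", 97.0),             # undetected NN, no congener
      hit("F13", "Hediste synthetica", 99.0),        # species retained, crab2
      hit("F14", "Hediste synthetica", 95.2),        # two genera, one family ->
      hit("F14", "Alitta synthetica", 94.8)          #   family Nereididae (LCA)
    )
    taxonomy <- tibble(subject = unname(acc_of[lineages$species])) |>
      bind_cols(lineages[, c("kingdom", "phylum", "class", "order", "family",
                             "genus", "species")])

    samples <- c("CRAB1_R1", "CRAB1_R2", "CRAB2_R1", "CRAB2_R2", "NEG1")
    asv_ids <- sprintf("F%02d", 1:14)
    m <- matrix(0L, length(asv_ids), length(samples),
                dimnames = list(asv_ids, samples))
    put <- function(asv, sample, reads) m[asv, sample] <<- as.integer(reads)
    put("F01", "CRAB1_R1", 5000); put("F01", "CRAB2_R1", 4000)
    put("F02", "NEG1", 7); put("F02", "CRAB1_R1", 500)
    put("F03", "CRAB1_R2", 120)
    put("F04", "CRAB2_R1", 80)
    put("F05", "CRAB1_R1", 300); put("F05", "CRAB1_R2", 200)
    put("F06", "CRAB1_R1", 150)   # genus Crangon: blocked by F05 in crab1
    put("F06", "CRAB2_R2", 90)    #   ... but retained as genus in crab2
    put("F07", "CRAB1_R2", 60)
    put("F08", "CRAB2_R1", 400)
    put("F09", "CRAB1_R1", 30)
    put("F10", "CRAB1_R2", 70)
    put("F11", "CRAB2_R1", 55)
    put("F12", "CRAB2_R2", 40)
    put("F13", "CRAB2_R2", 65)
    put("F14", "CRAB1_R1", 25)    # family add-back in crab1 (no nereid species)
    put("F14", "CRAB2_R1", 20)    # blocked in crab2 by Hediste synthetica
    asv_table <- bind_cols(tibble(asv_id = asv_ids), as_tibble(m))

    meta <- tibble(
      sample_id = samples,
      crab_id = c("CRAB1", "CRAB1", "CRAB2", "CRAB2", NA),
      replicate = c(1L, 2L, 1L, 2L, 1L),
      site = c("SiteA", "SiteA", "SiteB", "SiteB", NA),
      site_type = c("clam_bed", "clam_bed", "slough", "slough", NA),
      n_pcr_cycles = 40, is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE))

    label_pool <- unique(c(lineages$species, lineages$genus, lineages$family))
    label_pool <- label_pool[!is.na(label_pool)]
    native_status <- tibble(taxon = label_pool, status = "native",
                            sister_in_reference = TRUE)
    native_status$status[native_status$taxon == "Nonnativa detecta"] <- "nonnative_detected"
    native_status$status[native_status$taxon == "Mixogenus exoticus"] <- "nonnative_undetected"
    native_status$status[native_status$taxon == "Alienus solus"] <- "nonnative_undetected"
    native_status$sister_in_reference[native_status$taxon == "Alienus solus"] <- FALSE

    # Hand-enumerated post-filter truth:
    #  CRAB1: Crangon franciscorum (F05; blocks genus Crangon from F06),
    #         Nonnativa detecta (96.2 > 95 -> retain),
    #         Nereididae (F14 family-rank add-back; no nereid species here).
    #  CRAB2: Hemigrapsus oregonensis (F08), Hediste synthetica (F13, blocks
    #         the F14 family), Crangon (F06 genus; no blocking species),
    #         Mixogenus (F11 demoted to genus: undetected NN at 97 with a
    #         native congener in the reference).
    #  Removed everywhere: F01 (predator), F02 (reads in a control),
    #  F03/F04 (non-target), F07 (above-family LCA), F09 (sub-94),
    #  F12 (undetected non-native without congener).
    expected <- tibble(
      crab_id = c("CRAB1", "CRAB1", "CRAB1",
                  "CRAB2", "CRAB2", "CRAB2", "CRAB2"),
      taxon = c("Crangon franciscorum", "Nonnativa detecta", "Nereididae",
                "Hemigrapsus oregonensis", "Hediste synthetica", "Crangon",
                "Mixogenus"))

    list(asv_table = asv_table, blast = blast, taxonomy = taxonomy,
         native_status = native_status, meta = meta, expected = expected)
  })
}
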