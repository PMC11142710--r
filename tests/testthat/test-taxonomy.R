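fixture_taxonomy <- function() {
  dplyr::bind_rows(
    tax_row("HOR", family = "Varunidae", genus = "Hemigrapsus",
            species = "Hemigrapsus oregonensis"),
    tax_row("HNU", family = "Varunidae", genus = "Hemigrapsus",
            species = "Hemigrapsus nudus"),
    tax_row("LAR", phylum = "Chordata", class = "Actinopteri",
            order = "Perciformes", family = "Cottidae",
            genus = "Leptocottus", species = "Leptocottus armatus"),
    tax_row("CMA", family = "Carcinidae", genus = "Carcinus",
            species = "Carcinus maenas")
  )
}

test_that("taxonomy assignment applies thresholds and the LCA rule", {
  tax <- fixture_taxonomy()
  hits <- dplyr::bind_rows(
    blast_row("ASVa", "HOR", 99.1), blast_row("ASVa", "HNU", 98.4),
    blast_row("ASVb", "LAR", 99.5),
    blast_row("ASVc", "HOR", 93.0)
  )
  asn <- assign_taxonomy(hits, tax)

  # congeneric species pair collapses to genus rank
  a <- asn[asn$asv_id == "ASVa", ]
  expect_equal(a$rank, "genus")
  expect_equal(a$genus, "Hemigrapsus")
  expect_true(is.na(a$species))
  expect_equal(a$best_pct_identity, 99.1)

  # single-species hit keeps the full lineage at species rank
  b <- asn[asn$asv_id == "ASVb", ]
  expect_equal(b$rank, "species")
  expect_equal(b$species, "Leptocottus armatus")

  # only sub-94 hits: unassigned (inclusive floor)
  expect_equal(asn$rank[asn$asv_id == "ASVc"], "unassigned")
  # exactly 94 passes
  asn94 <- assign_taxonomy(blast_row("ASVd", "LAR", 94.0), tax)
  expect_equal(asn94$rank, "species")

  # e-value ceiling enforced
  asn_e <- assign_taxonomy(blast_row("ASVe", "LAR", 99, evalue = 1e-10), tax)
  expect_equal(asn_e$rank, "unassigned")

  # LCA is over distinct species: accession duplicates don't truncate
  dup <- dplyr::bind_rows(blast_row("ASVf", "LAR", 99.5),
                          blast_row("ASVf", "LAR", 98.9))
  expect_equal(assign_taxonomy(dup, tax)$rank, "species")
})

test_that("control, predator, and non-target ASVs are removed in order", {
  tax <- dplyr::bind_rows(
    fixture_taxonomy(),
    tax_row("DIA", kingdom = "Chromista", phylum = "Ochrophyta",
            class = "Bacillariophyceae", order = NA, species = "Diatoma x")
  )
  hits <- dplyr::bind_rows(
    blast_row("A_ctrl", "LAR", 99), blast_row("A_pred", "CMA", 100),
    blast_row("A_diat", "DIA", 98), blast_row("A_keep", "HOR", 99)
  )
  asn <- assign_taxonomy(hits, tax)
  tab <- tibble::tibble(
    asv_id = c("A_ctrl", "A_pred", "A_diat", "A_keep"),
    C1 = c(500L, 800L, 60L, 120L), NEG = c(1L, 0L, 0L, 0L))
  out <- remove_nonprey_asvs(tab, asn, control_sample_ids = "NEG")
  expect_equal(out$asv_id, "A_keep")
  report <- attr(out, "filter_report")
  expect_equal(report$step, c("control_samples", "predator", "nontarget"))
  expect_equal(report$n_asvs_removed, c(1L, 1L, 1L))
  # control removal counts the crab-sample reads it discards
  expect_equal(report$n_reads_removed[1], 500)

  # unknown predator label is a configuration error
  expect_error(remove_nonprey_asvs(tab, asn, predator = "Nemo fishus"),
               "predator")
})

test_that("species-plus-family collapse follows the blocking rules", {
  det <- tibble::tibble(
    crab_id = c("c1", "c1", "c1", "c1", "c2"),
    kingdom = "Animalia", phylum = "Arthropoda", class = "Malacostraca",
    order = "Decapoda",
    family = c("Crangonidae", "Crangonidae", "Nereididae", "Cancridae",
               "Crangonidae"),
    genus = c("Crangon", "Crangon", NA, NA, "Crangon"),
    species = c("Crangon franciscorum", NA, NA, NA, NA),
    rank = c("species", "genus", "family", "order", "genus"),
    taxon = c("Crangon franciscorum", "Crangon", "Nereididae", "Decapoda",
              "Crangon"),
    best_pct_identity = 99)
  out <- collapse_species_plus_family(det)
  # c1: species blocks its genus; family without species/genus retained;
  # order-rank never retained
  expect_setequal(out$taxon[out$crab_id == "c1"],
                  c("Crangon franciscorum", "Nereididae"))
  # c2 has no blocking species, genus retained
  expect_equal(out$taxon[out$crab_id == "c2"], "Crangon")

  # a retained genus blocks its family
  det2 <- tibble::tibble(
    crab_id = "c3", kingdom = "Animalia", phylum = "Arthropoda",
    class = "Malacostraca", order = "Decapoda",
    family = c("Crangonidae", "Crangonidae"),
    genus = c("Crangon", NA), species = NA_character_,
    rank = c("genus", "family"), taxon = c("Crangon", "Crangonidae"),
    best_pct_identity = 99)
  expect_equal(collapse_species_plus_family(det2)$taxon, "Crangon")
})

test_that("non-native decisions match the hand-enumerated decision tree", {
  # worked cases
  expect_equal(decide_nonnative("nonnative_detected", 96.2, TRUE, "species"),
               "retain")
  expect_equal(decide_nonnative("nonnative_undetected", 97, TRUE, "species"),
               "demote_to_genus")
  expect_equal(decide_nonnative("nonnative_undetected", 97, FALSE, "species"),
               "remove")
  # boundary semantics are strictly exclusive at 95 and 98
  expect_equal(decide_nonnative("nonnative_detected", 95, FALSE, "species"),
               "demote_to_genus")
  expect_equal(decide_nonnative("nonnative_undetected", 98, TRUE, "species"),
               "demote_to_genus")

  # full grid versus the independent oracle table
  grid <- nonnative_oracle_table()
  got <- decide_nonnative(grid$status, grid$pct, grid$sister, "species")
  expect_equal(got, unname(grid$expected))

  # unknown status demands curation
  expect_error(decide_nonnative("unknown", 99, TRUE, "species"), "curation")
})

test_that("prey matrix sums replicates and reports excluded crabs", {
  tax <- fixture_taxonomy()
  hits <- blast_row("A1", "HOR", 99)
  asn <- assign_taxonomy(hits, tax)
  tab <- tibble::tibble(asv_id = "A1", c1_r1 = 10L, c1_r2 = 20L,
                        c2_r1 = 0L, c2_r2 = 0L)
  meta <- crabdiet:::validate_sample_meta(tibble::tibble(
    sample_id = c("c1_r1", "c1_r2", "c2_r1", "c2_r2"),
    crab_id = rep(c("c1", "c2"), each = 2), replicate = rep(1:2, 2),
    site = "S", site_type = "slough", n_pcr_cycles = 40))
  retained <- tibble::tibble(
    crab_id = "c1", taxon = "Hemigrapsus oregonensis", rank = "species",
    kingdom = "Animalia", phylum = "Arthropoda", class = "Malacostraca",
    order = "Decapoda", family = "Varunidae", genus = "Hemigrapsus",
    species = "Hemigrapsus oregonensis", best_pct_identity = 99)
  prey <- build_prey_matrix(tab, asn, retained, meta)
  expect_equal(prey$`Hemigrapsus oregonensis`, 30L)
  expect_equal(attr(prey, "excluded_crabs"), "c2")
  # presence view mirrors reads > 0
  expect_true(prey_presence(prey)$`Hemigrapsus oregonensis`)

  # replicate with unknown crab errors
  tab2 <- dplyr::mutate(tab, mystery = 5L)
  expect_error(build_prey_matrix(tab2, asn, retained, meta), "mystery")
})

test_that("full filter chain matches the planted fixture truth", {
  fx <- plant_filter_fixtures(seed = 1)
  res <- filter_prey_taxa(fx$asv_table, fx$blast, fx$taxonomy,
                          fx$native_status, fx$meta)
  got <- dplyr::arrange(res$retained[, c("crab_id", "taxon")],
                        crab_id, taxon)
  want <- dplyr::arrange(fx$expected, crab_id, taxon)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)

  # predator never appears among output columns
  expect_false("Carcinus maenas" %in% names(res$prey))
})

test_that("filtering is idempotent and robust to reads on removed ASVs", {
  fx <- plant_filter_fixtures(seed = 1)
  res1 <- filter_prey_taxa(fx$asv_table, fx$blast, fx$taxonomy,
                           fx$native_status, fx$meta)
  # re-running the chain on the already-filtered ASV table changes nothing
  res2 <- filter_prey_taxa(res1$tab, fx$blast, fx$taxonomy,
                           fx$native_status, fx$meta)
  expect_equal(res2$retained, res1$retained)
  expect_equal(res2$prey, res1$prey, ignore_attr = TRUE)

  # monotonicity: inflating reads of a removed ASV cannot change the result
  boosted <- fx$asv_table
  boosted$CRAB1_R1[boosted$asv_id == "F01"] <- 999999L  # predator ASV
  boosted$CRAB1_R1[boosted$asv_id == "F09"] <- 55555L   # sub-94 ASV
  res3 <- filter_prey_taxa(boosted, fx$blast, fx$taxonomy,
                           fx$native_status, fx$meta)
  expect_equal(res3$retained, res1$retained)
  expect_equal(res3$prey, res1$prey, ignore_attr = TRUE)
})

test_that("predator columns never survive filtering of simulated data", {
  b <- simulate_dataset(sim_config(n_crabs = 12, n_taxa = 12), seed = 3)
  res <- filter_prey_taxa(b$asv_table, b$blast, b$taxonomy, b$native_status,
                          b$meta)
  expect_false("Carcinus maenas" %in% names(res$prey))
  expect_false("Carcinus" %in% names(res$prey))
})
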