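# Independent oracles used across the suite. Each re-derives the expected
# behaviour by a different route than the implementation under test.

# Brute-force PCR amplification: start from template amounts and multiply
# each species' amount by its per-cycle rate, cycle by cycle, then
# renormalize. Independent of the softmax closed form.
brute_force_amplification <- function(beta, alpha, n_cycles) {
  amounts <- beta
  rates <- exp(alpha)
  for (cycle in seq_len(n_cycles)) {
    amounts <- amounts * rates
  }
  amounts / sum(amounts)
}

# Set-based Jaccard dissimilarity from first principles.
jaccard_sets <- function(a, b) {
  1 - length(intersect(a, b)) / length(union(a, b))
}

# Pseudo-F computed straight from the definition (all pairwise squared
# dissimilarities), used to enumerate exact permutation distributions.
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  ss_total <- sum(d2) / (2 * n)
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Exact two-group permutation p-value by full enumeration of the distinct
# assignments of n objects into groups of sizes (k, n - k).
exact_permanova_p <- function(d, k) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  assignments <- utils::combn(n, k)
  f_obs <- pseudo_f(d2, c(rep("A", k), rep("B", n - k)))
  fs <- apply(assignments, 2, function(idx) {
    g <- rep("B", n)
    g[idx] <- "A"
    pseudo_f(d2, g)
  })
  mean(fs >= f_obs - 1e-12)
}

# Hand-enumerated decision tree for non-native filtering, written as an
# explicit case table (species-rank identifications) rather than nested
# conditions, for the grid used in the equivalence test.
nonnative_oracle_table <- function() {
  grid <- expand.grid(
    status = c("native", "nonnative_detected", "nonnative_undetected"),
    pct = c(94.5, 95.5, 97, 98.5),
    sister = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  decide_one <- function(status, pct, sister) {
    if (status == "native") return("retain")
    if (status == "nonnative_detected") {
      if (pct > 95) return("retain")           # above threshold: keep
      if (sister) return("retain")             # sisters in reference: keep
      return("demote_to_genus")                # species-level fallback
    }
    # previously undetected non-native
    if (pct > 98 && sister) return("retain")
    if (sister) return("demote_to_genus")      # native congener available
    "remove"
  }
  grid$expected <- mapply(decide_one, grid$status, grid$pct, grid$sister)
  grid
}

# Tiny two-crab ASV tibble used by several io/taxonomy tests.
tiny_asv_tab <- function() {
  tibble::tibble(
    asv_id = c("A1", "A2"),
    S1 = c(10L, 0L), S2 = c(0L, 7L), S3 = c(5L, 0L)
  )
}

blast_row <- function(qseqid, sseqid, pident, evalue = 1e-120) {
  tibble::tibble(qseqid = qseqid, sseqid = sseqid, pident = pident,
                 length = 418, mismatch = 3, gapopen = 0, qstart = 1,
                 qend = 418, sstart = 1, send = 418, evalue = evalue,
                 bitscore = 700)
}

# Minimal taxonomy rows for ad-hoc tests.
tax_row <- function(subject, kingdom = "Animalia", phylum = "Arthropoda",
                    class = "Malacostraca", order = "Decapoda",
                    family = NA, genus = NA, species = NA) {
  tibble::tibble(subject = subject, kingdom = kingdom, phylum = phylum,
                 class = class, order = order, family = family,
                 genus = genus, species = species)
}

# Random binary community matrix with no all-zero rows.
random_presence_matrix <- function(n, p, prob = 0.4) {
  m <- matrix(stats::rbinom(n * p, 1, prob), n, p)
  zero <- rowSums(m) == 0
  m[zero, 1] <- 1
  rownames(m) <- paste0("crab", seq_len(n))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a numeric matrix as a prey tibble with metadata columns.
make_prey <- function(m, sites = NULL, taxon_info = NULL) {
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  out <- dplyr::bind_cols(
    tibble::tibble(crab_id = paste0("c", seq_len(nrow(m))),
                   site = sites %||% rep("S1", nrow(m)),
                   site_type = "slough"),
    tibble::as_tibble(m))
  attr(out, "taxon_info") <- taxon_info
  out
}

# One Dirichlet draw via normalized gammas (kept separate from the package's
# own sampler).
rdirichlet_oracle <- function(k, conc = 1) {
  g <- stats::rgamma(k, conc)
  g / sum(g)
}
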