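#' eDNA index of a prey read matrix
#'
#' The eDNA index is a within-taxon, semi-quantitative abundance index:
#' read counts are first converted to proportions within each crab (row),
#' and each taxon's proportions are then divided by that taxon's maximum
#' proportion across crabs. Values lie in \[0, 1\], each retained taxon
#' attains 1 in at least one crab, and the index is invariant to per-crab
#' sequencing depth.
#'
#' @param prey Prey matrix from [build_prey_matrix()] (reads view). Every
#'   crab row must have total reads > 0.
#' @return Tibble of the same shape with index values; taxa with zero reads
#'   everywhere are dropped with a warning (the index is undefined for them).
#' @export
edna_index <- function(prey) {
  taxa <- prey_taxa(prey)
  m <- as.matrix(prey[, taxa])
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(sprintf("crab(s) with zero total reads: %s",
                  paste(prey$crab_id[rs <= 0], collapse = ", ")))
  }
  p <- m / rs
  cmax <- apply(p, 2, max)
  dead <- cmax <= 0
  if (any(dead)) {
    warn(sprintf("dropping taxa with zero reads everywhere: %s",
                 paste(taxa[dead], collapse = ", ")))
    p <- p[, !dead, drop = FALSE]
    cmax <- cmax[!dead]
    taxa <- taxa[!dead]
  }
  idx <- sweep(p, 2, cmax, "/")
  out <- bind_cols(prey[, intersect(c("crab_id", "site", "site_type"), names(prey))],
                   as_tibble(idx))
  attr(out, "taxon_info") <- attr(prey, "taxon_info")
  out
}

# Remove genus/family-rank taxa already represented by a deeper-rank taxon
# detected in the same group (conservative subsumption used for site-level
# diversity reporting).
#' @keywords internal
subsume_taxa <- function(taxa, taxon_info) {
  info <- taxon_info[match(taxa, taxon_info$taxon), ]
  keep <- rep(TRUE, length(taxa))
  sp <- info$rank == "species"
  gen <- info$rank == "genus"
  fam <- info$rank == "family"
  keep[gen] <- !(info$genus[gen] %in% info$genus[sp])
  blocked_fams <- unique(c(info$family[sp], info$family[gen & keep]))
  keep[fam] <- !(info$family[fam] %in% blocked_fams)
  taxa[keep]
}

#' Site-level prey alpha diversity
#'
#' Counts unique prey taxa per group (site by default), conservatively
#' removing genus- or family-rank identifications already represented by a
#' species-rank (or deeper) identification detected in the same group: a
#' *Crangon* sp. record does not add to a site's diversity if any crab at
#' that site also had *Crangon franciscorum*.
#'
#' @param prey Prey matrix (reads or presence view) with `"taxon_info"`
#'   attribute.
#' @param group Metadata column to group by (default `"site"`).
#' @return Tibble with one row per group: `group`, `alpha` (integer count).
#' @export
alpha_diversity <- function(prey, group = "site") {
  taxon_info <- attr(prey, "taxon_info")
  if (is.null(taxon_info)) abort("prey matrix lacks 'taxon_info' attribute")
  taxa <- prey_taxa(prey)
  groups <- unique(prey[[group]])
  tibble(
    "{group}" := groups,
    alpha = vapply(groups, function(g) {
      sub <- prey[prey[[group]] == g, taxa, drop = FALSE]
      present <- taxa[colSums(as.matrix(sub) > 0) > 0]
      length(subsume_taxa(present, taxon_info))
    }, integer(1), USE.NAMES = FALSE)
  )
}

#' Pooled taxon set of a group, with subsumption
#' @keywords internal
pooled_site_set <- function(prey, group_value, group = "site") {
  taxon_info <- attr(prey, "taxon_info")
  taxa <- prey_taxa(prey)
  sub <- prey[prey[[group]] == group_value, taxa, drop = FALSE]
  present <- taxa[colSums(as.matrix(sub) > 0) > 0]
  subsume_taxa(present, taxon_info)
}

#' Beta diversity between two pooled site taxon sets
#'
#' Jaccard dissimilarity (1 minus intersection over union) between the
#' pooled prey-taxon sets of two sites, built with the same subsumption rule
#' as [alpha_diversity()].
#'
#' @param set_a,set_b Character vectors of taxa (or pass a prey matrix to
#'   [beta_diversity_table()] for all pairs).
#' @return Dissimilarity in \[0, 1\].
#' @export
beta_between_sites <- function(set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    abort("beta diversity undefined for an empty taxon set")
  }
  1 - length(intersect(set_a, set_b)) / length(union(set_a, set_b))
}

#' All pairwise site beta diversities
#'
#' @param prey Prey matrix with `"taxon_info"`.
#' @param group Metadata grouping column (default `"site"`).
#' @return Tibble `site_a`, `site_b`, `beta`.
#' @export
beta_diversity_table <- function(prey, group = "site") {
  groups <- sort(unique(prey[[group]]))
  pairs <- utils::combn(groups, 2)
  sets <- lapply(groups, pooled_site_set, prey = prey, group = group)
  names(sets) <- groups
  tibble(
    site_a = pairs[1, ],
    site_b = pairs[2, ],
    beta = apply(pairs, 2, function(p) beta_between_sites(sets[[p[1]]], sets[[p[2]]]))
  )
}

#' Dissimilarity matrix between crabs
#'
#' Jaccard on the presence/absence view (1 - intersection/union of prey
#' sets), or Bray-Curtis on eDNA-index rows (sum of absolute differences over
#' sum of totals). Distances are delegated to [vegan::vegdist()].
#'
#' @param data Prey presence view ([prey_presence()]) for `"jaccard"`, or
#'   eDNA index matrix ([edna_index()]) for `"bray_curtis"`.
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return A [stats::dist] object labelled by `crab_id`.
#' @export
distance_matrix <- function(data, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  taxa <- prey_taxa(data)
  m <- as.matrix(data[, taxa]) * 1.0
  rownames(m) <- data$crab_id
  if (nrow(m) < 2) abort("need at least two crabs")
  if (any(rowSums(m) == 0)) {
    abort("all-zero row(s): dissimilarity undefined")
  }
  d <- switch(metric,
    jaccard = vegan::vegdist(m, method = "jaccard", binary = TRUE),
    bray_curtis = vegan::vegdist(m, method = "bray")
  )
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-\tfrac{1}{2} D^2} and eigendecomposes it. All
#' eigenvalues are reported, including negative ones arising from
#' non-Euclidean dissimilarities (no Lingoes/Cailliez correction);
#' coordinates are returned for positive-eigenvalue axes, ordered by
#' decreasing eigenvalue and centered at the origin.
#'
#' @param d A symmetric dissimilarity (`dist` or matrix).
#' @return Object of class `crabdiet_pcoa`: list with `coordinates`
#'   (n x n_pos matrix), `eigenvalues` (all n), `neg_coordinates` (axes for
#'   negative eigenvalues, scaled by sqrt of |eigenvalue|; used for
#'   dispersion corrections), `labels`.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("dissimilarity matrix must be symmetric")
  }
  n <- nrow(m)
  labels <- rownames(m) %||% as.character(seq_len(n))
  a <- -0.5 * m^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  tol <- max(abs(vals)) * 1e-9
  pos <- vals > tol
  neg <- vals < -tol
  coords <- vecs[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), sum(pos))
  negc <- vecs[, neg, drop = FALSE] %*% diag(sqrt(abs(vals[neg])), sum(neg))
  rownames(coords) <- rownames(negc) <- labels
  structure(list(coordinates = coords, eigenvalues = vals,
                 neg_coordinates = negc, labels = labels),
            class = "crabdiet_pcoa")
}

#' @export
print.crabdiet_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d points, %d positive / %d negative eigenvalues\n",
              length(x$labels), ncol(x$coordinates), ncol(x$neg_coordinates)))
  rel <- x$eigenvalues[x$eigenvalues > 0] / sum(x$eigenvalues[x$eigenvalues > 0])
  cat(sprintf("first axes explain %s of positive inertia\n",
              paste(sprintf("%.1f%%", 100 * head(rel, 3)), collapse = ", ")))
  invisible(x)
}
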