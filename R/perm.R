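#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor pseudo-F test on a dissimilarity matrix. Sums of squares are
#' computed from squared dissimilarities (total: all pairs divided by N;
#' within: within-group pairs divided by group size); the p-value comes from
#' free permutation of group labels with the standard estimator
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}, which resolves ties
#' conservatively.
#'
#' @param d Dissimilarity (`dist` or symmetric matrix).
#' @param groups Group labels, one per object (>= 2 groups, each of size
#'   >= 2).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutation stream; global RNG
#'   state is left untouched.
#' @return An object of class `perm_test`: list with `statistic` (pseudo-F),
#'   `R2`, `df` (between, within), `p_value`, `n_permutations`, `seed`,
#'   `ss` (between/within/total sums of squares).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  groups <- as.character(groups)
  if (length(groups) != n) abort("groups length must match dissimilarity size")
  check_groups(groups)
  a <- length(unique(groups))
  ss_total <- sum(d2) / (2 * n)
  # degenerate all-coincident data: F defined as 0 so that p comes out 1
  eps <- 1e-12 * max(ss_total, 1)
  f_of <- function(ss_w) {
    ss_b <- ss_total - ss_w
    if (ss_w <= eps) {
      if (ss_b <= eps) 0 else Inf
    } else {
      (ss_b / (a - 1)) / (ss_w / (n - a))
    }
  }
  ss_w <- ss_within(d2, groups)
  ss_b <- ss_total - ss_w
  f_obs <- f_of(ss_w)
  r2 <- if (ss_total <= eps) 0 else ss_b / ss_total

  perm_f <- with_perm_stream(seed, {
    vapply(seq_len(n_perm), function(i) {
      f_of(ss_within(d2, sample(groups)))
    }, numeric(1))
  })
  p <- (1 + sum(perm_f >= f_obs)) / (1 + n_perm)

  structure(list(statistic = f_obs, R2 = r2, df = c(between = a - 1, within = n - a),
                 p_value = p, n_permutations = n_perm, seed = seed,
                 ss = c(between = ss_b, within = ss_w, total = ss_total),
                 method = "PERMANOVA"),
            class = "perm_test")
}

#' @keywords internal
check_groups <- function(groups) {
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least two groups")
  if (any(tab < 2)) {
    abort(sprintf("group(s) with fewer than 2 members: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")))
  }
  invisible(groups)
}

#' @keywords internal
ss_within <- function(d2, groups) {
  s <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

# Run expr under a locally seeded RNG stream (or the current stream if
# seed is NULL).
#' @keywords internal
with_perm_stream <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  withr::with_seed(as.integer(seed), eval.parent(substitute(expr)))
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Tests whether groups differ in their dispersion around group centroids in
#' principal-coordinate space. Distances to centroids account for
#' negative-eigenvalue axes by subtracting their squared contribution
#' (truncated at zero before the square root). The F statistic is the
#' one-way ANOVA F on those distances; the p-value comes from permutation of
#' group labels (centroids and distances recomputed each permutation).
#'
#' @inheritParams permanova
#' @return A `perm_test` object (`ss` holds the ANOVA sums of squares of the
#'   centroid distances).
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.character(groups)
  check_groups(groups)
  pc <- pcoa(d)
  z_obs <- centroid_distances(pc, groups)
  if (all(z_obs < 1e-12)) {
    abort("all points coincident: dispersion F undefined")
  }
  f_obs <- anova_f(z_obs, groups)
  perm_f <- with_perm_stream(seed, {
    vapply(seq_len(n_perm), function(i) {
      g <- sample(groups)
      anova_f(centroid_distances(pc, g), g)
    }, numeric(1))
  })
  p <- (1 + sum(perm_f >= f_obs)) / (1 + n_perm)
  a <- length(unique(groups))
  n <- length(groups)
  gm <- mean(z_obs)
  ss_total <- sum((z_obs - gm)^2)
  ss_b <- sum(tapply(z_obs, groups, function(v) length(v) * (mean(v) - gm)^2))
  structure(list(statistic = f_obs, R2 = ss_b / ss_total,
                 df = c(between = a - 1, within = n - a),
                 p_value = p, n_permutations = n_perm, seed = seed,
                 ss = c(between = ss_b, within = ss_total - ss_b, total = ss_total),
                 method = "PERMDISP"),
            class = "perm_test")
}

#' @keywords internal
centroid_distances <- function(pc, groups) {
  pos <- pc$coordinates
  neg <- pc$neg_coordinates
  z <- numeric(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cp <- colMeans(pos[idx, , drop = FALSE])
    d2 <- rowSums((pos[idx, , drop = FALSE] -
                     matrix(cp, length(idx), length(cp), byrow = TRUE))^2)
    if (ncol(neg) > 0) {
      cn <- colMeans(neg[idx, , drop = FALSE])
      d2 <- d2 - rowSums((neg[idx, , drop = FALSE] -
                            matrix(cn, length(idx), length(cn), byrow = TRUE))^2)
    }
    z[idx] <- sqrt(pmax(d2, 0))
  }
  z
}

#' @keywords internal
anova_f <- function(z, groups) {
  gm <- mean(z)
  a <- length(unique(groups))
  n <- length(z)
  ss_b <- sum(tapply(z, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(tapply(z, groups, function(v) sum((v - mean(v))^2)))
  if (ss_w <= 0) return(Inf)
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

#' Uncapped Bonferroni correction
#'
#' Multiplies raw p-values by the number of tests, deliberately without
#' capping at 1, matching common reporting of post-hoc pairwise permutation
#' tests (a corrected value above 1 simply reads "not significant").
#'
#' @param p Raw p-values.
#' @param m Number of tests.
#' @return `p * m`.
#' @export
p_adjust_uncapped <- function(p, m) {
  stopifnot(m >= 1)
  p * m
}

#' Post-hoc pairwise PERMANOVAs with Bonferroni correction
#'
#' Runs a two-group PERMANOVA for every pair of groups and corrects the raw
#' p-values with the uncapped Bonferroni multiplier.
#'
#' @inheritParams permanova
#' @param m_tests Bonferroni multiplier; defaults to the number of pairs.
#' @return Tibble: `group_a`, `group_b`, `df_between`, `df_within`,
#'   `ss_between`, `ss_total`, `R2`, `statistic`, `p_value`, `p_corrected`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL,
                               m_tests = NULL) {
  groups <- as.character(groups)
  m <- as.matrix(d)
  levs <- sort(unique(groups))
  pairs <- utils::combn(levs, 2)
  m_tests <- m_tests %||% ncol(pairs)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    pair <- pairs[, j]
    idx <- which(groups %in% pair)
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, j)
    pt <- permanova(stats::as.dist(m[idx, idx]), groups[idx],
                    n_perm = n_perm, seed = sub_seed)
    tibble(group_a = pair[1], group_b = pair[2],
           df_between = pt$df[["between"]], df_within = pt$df[["within"]],
           ss_between = pt$ss[["between"]], ss_total = pt$ss[["total"]],
           R2 = pt$R2, statistic = pt$statistic, p_value = pt$p_value)
  })
  out <- list_rbind(res)
  out$p_corrected <- p_adjust_uncapped(out$p_value, m_tests)
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: F = %.4f, R2 = %.4f, df = (%d, %d), p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$R2, x$df[["between"]], x$df[["within"]],
              x$p_value, x$n_permutations))
  invisible(x)
}
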