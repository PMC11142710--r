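#' Build the estimated-count matrix for the average-diet model
#'
#' Converts per-crab calibrated DNA proportions into integer pseudo-counts:
#' cell (c, i) is the posterior-mean proportion of species i in crab c times
#' the crab's average replicate read depth divided by `divisor` (default
#' 100), rounded to the nearest integer (ties to even). The division shrinks
#' the effective multinomial sample size, which is conservative: it leaves
#' mean composition estimates essentially unchanged while widening credible
#' intervals.
#'
#' @param calibrated Calibrated proportions from [calibrate_samples()]
#'   (`crab_id`, `species`, `beta_mean`).
#' @param depths Tibble `crab_id`, `avg_depth` (average replicate read
#'   depth, after any lowest-cycle replicate selection).
#' @param divisor Depth divisor (integer >= 1, default 100).
#' @param stat Which posterior summary to use as the multinomial
#'   probabilities: `"beta_mean"` (default) or `"beta_median"`.
#' @return Wide tibble `crab_id` + one integer column per calibrated
#'   species; attribute `"divisor"`.
#' @export
build_estimated_counts <- function(calibrated, depths, divisor = 100,
                                   stat = c("beta_mean", "beta_median")) {
  stopifnot(divisor >= 1)
  stat <- match.arg(stat)
  if (any(depths$avg_depth <= 0)) abort("avg_depth must be > 0")
  species <- sort(unique(calibrated$species))
  no_cal <- setdiff(depths$crab_id, calibrated$crab_id)
  if (length(no_cal)) {
    warn(sprintf("crab(s) lacking calibrated proportions skipped: %s",
                 paste(no_cal, collapse = ", ")))
  }
  crabs <- intersect(depths$crab_id, unique(calibrated$crab_id))
  rows <- lapply(crabs, function(cid) {
    cc <- calibrated[calibrated$crab_id == cid, ]
    beta <- setNames(rep(0, length(species)), species)
    beta[cc$species] <- cc[[stat]]
    n_c <- depths$avg_depth[depths$crab_id == cid][1] / divisor
    counts <- as.integer(round(beta * n_c))
    tibble(crab_id = cid, !!!setNames(as.list(counts), species))
  })
  out <- list_rbind(rows)
  attr(out, "divisor") <- divisor
  out
}

# log density of the Dirichlet-multinomial (multinomial coefficient dropped:
# constant in the parameters).
#' @keywords internal
ddirmult_log <- function(y, a) {
  lgamma(sum(a)) - lgamma(sum(y) + sum(a)) + sum(lgamma(y + a) - lgamma(a))
}

#' Fit the zero-and-one-inflated Dirichlet average-diet model
#'
#' Generative model for a crab's diet composition over K calibrated species:
#' each species is structurally absent from a crab with a species-level
#' inflation probability; the composition over the present species is a
#' Dirichlet draw with mean `mu` (renormalized to the present set) and
#' concentration `phi`; observed counts are multinomial given that
#' composition. A crab whose counts fall entirely on one species is a
#' one-inflated (degenerate) draw and informs only the presence
#' probabilities. Marginalizing the Dirichlet gives a Dirichlet-multinomial
#' likelihood on each crab's observed support (observed zeros are treated as
#' structural, which at the effective depths used makes sampling zeros
#' negligible). Presence probabilities get conjugate Beta posteriors;
#' `(mu, phi)` are sampled by adaptive random-walk Metropolis.
#'
#' The reported "average diet" is the posterior expectation of the
#' support-renormalized mixture: the composition of a new crab, averaging
#' over which species are present. Species with zero counts in every crab
#' are excluded from the simplex and reported as exactly 0 with a degenerate
#' interval (with a warning).
#'
#' @param counts Wide tibble from [build_estimated_counts()] (or matrix with
#'   species columns).
#' @param chains Number of MCMC chains (default 4).
#' @param iter Iterations per chain (default 1500; first half is warmup).
#' @param warmup Warmup iterations (default `iter / 2`).
#' @param seed Optional integer seed.
#' @param mu_prior_sd Normal prior SD on the softmax-parameterized mean
#'   (default 2, weakly informative).
#' @return Object of class `diet_fit`: `summary` tibble (`species`, `mean`,
#'   `median`, `lo95`, `hi95`, `lo50`, `hi50`, `present_prob`), draws,
#'   `phi` summary, split-R-hat diagnostics.
#' @export
fit_inflated_dirichlet <- function(counts, chains = 4, iter = 1500,
                                   warmup = floor(iter / 2), seed = NULL,
                                   mu_prior_sd = 2) {
  species_all <- setdiff(names(counts), c("crab_id", "site", "site_type"))
  m <- as.matrix(counts[, species_all, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) < 3) abort("need at least 3 crabs")
  empty_crabs <- rowSums(m) == 0
  if (any(empty_crabs)) {
    warn(sprintf("%d crab(s) with all-zero counts dropped", sum(empty_crabs)))
    m <- m[!empty_crabs, , drop = FALSE]
  }
  zero_sp <- colSums(m) == 0
  if (any(zero_sp)) {
    warn(sprintf("species with zero counts in every crab reported as 0: %s",
                 paste(species_all[zero_sp], collapse = ", ")))
  }
  species <- species_all[!zero_sp]
  m <- m[, !zero_sp, drop = FALSE]
  k <- length(species)
  n_crab <- nrow(m)

  present <- m > 0
  n_pres <- colSums(present)
  n_abs <- n_crab - n_pres

  if (k == 1) {
    summary <- tibble(species = species_all,
                      mean = as.numeric(!zero_sp), median = as.numeric(!zero_sp),
                      lo95 = as.numeric(!zero_sp), hi95 = as.numeric(!zero_sp),
                      lo50 = as.numeric(!zero_sp), hi50 = as.numeric(!zero_sp),
                      present_prob = as.numeric(!zero_sp))
    return(structure(list(summary = summary, species = species_all,
                          draws = NULL, phi = NULL, rhat = NULL,
                          n_crabs = n_crab), class = "diet_fit"))
  }

  # Crabs with >= 2 present species carry compositional information.
  multi <- which(rowSums(present) >= 2)
  lik_data <- lapply(multi, function(i) {
    idx <- which(present[i, ])
    list(idx = idx, y = m[i, idx])
  })

  log_post <- function(par) {
    eta <- c(0, par[seq_len(k - 1)])
    phi <- exp(par[k])
    mu <- softmax(eta)
    lp <- sum(-par[seq_len(k - 1)]^2 / (2 * mu_prior_sd^2)) -
      (par[k] - log(10))^2 / (2 * 1.5^2)
    for (d in lik_data) {
      a <- phi * mu[d$idx] / sum(mu[d$idx])
      lp <- lp + ddirmult_log(d$y, a)
    }
    lp
  }

  n_keep <- iter - warmup
  run_chain <- function(chain_id) {
    par <- c(rnorm(k - 1, 0, 0.5), log(10) + rnorm(1, 0, 0.3))
    lp <- log_post(par)
    step <- rep(0.3, k)
    acc <- 0
    draws <- matrix(NA_real_, n_keep, k)
    for (it in seq_len(iter)) {
      prop <- par + rnorm(k) * step
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
        par <- prop
        lp <- lp_prop
        acc <- acc + 1
      }
      if (it <= warmup && it %% 50 == 0) {
        rate <- acc / 50
        step <- step * exp(rate - 0.3)
        acc <- 0
      }
      if (it > warmup) draws[it - warmup, ] <- par
    }
    draws
  }

  all_draws <- with_perm_stream(seed, lapply(seq_len(chains), run_chain))
  rhat <- split_rhat(all_draws)
  if (any(rhat > 1.05, na.rm = TRUE)) {
    warn(sprintf("possible non-convergence: max split-R-hat %.3f", max(rhat)))
  }
  draws <- do.call(rbind, all_draws)
  n_draws <- nrow(draws)
  mu_draws <- t(apply(draws[, seq_len(k - 1), drop = FALSE], 1,
                      function(e) softmax(c(0, e))))
  phi_draws <- exp(draws[, k])

  # Presence probabilities: conjugate Beta(1 + n_pres, 1 + n_abs) draws.
  pres_draws <- with_perm_stream(if (is.null(seed)) NULL else derive_seed(seed, 97L), {
    matrix(rbeta(n_draws * k, rep(1 + n_pres, each = n_draws),
                 rep(1 + n_abs, each = n_draws)), n_draws, k)
  })

  # Marginal expected composition: average the support-renormalized mean
  # over the presence distribution (exact enumeration of non-empty supports).
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))[-1, , drop = FALSE]
  comp_draws <- matrix(0, n_draws, k)
  for (j in seq_len(n_draws)) {
    mu <- mu_draws[j, ]
    pr <- pres_draws[j, ]
    logw <- subsets %*% log(pr) + (1 - subsets) %*% log1p(-pr)
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    denom <- as.numeric(subsets %*% mu)
    comp_draws[j, ] <- mu * as.numeric(t(subsets) %*% (w / denom))
  }
  comp_draws <- comp_draws / rowSums(comp_draws)

  qs <- function(x, p) apply(x, 2, quantile, probs = p, names = FALSE)
  fit_summary <- tibble(
    species = species,
    mean = colMeans(comp_draws),
    median = qs(comp_draws, 0.5),
    lo95 = qs(comp_draws, 0.025), hi95 = qs(comp_draws, 0.975),
    lo50 = qs(comp_draws, 0.25), hi50 = qs(comp_draws, 0.75),
    present_prob = colMeans(pres_draws)
  )
  if (any(zero_sp)) {
    fit_summary <- bind_rows(fit_summary,
      tibble(species = species_all[zero_sp], mean = 0, median = 0,
             lo95 = 0, hi95 = 0, lo50 = 0, hi50 = 0, present_prob = 0))
  }
  fit_summary <- fit_summary[match(species_all, fit_summary$species), ]

  structure(list(summary = fit_summary, species = species_all,
                 draws = list(mu = mu_draws, phi = phi_draws,
                              presence = pres_draws, composition = comp_draws),
                 phi = c(mean = mean(phi_draws),
                         lo95 = quantile(phi_draws, 0.025, names = FALSE),
                         hi95 = quantile(phi_draws, 0.975, names = FALSE)),
                 rhat = rhat, n_crabs = n_crab),
            class = "diet_fit")
}

# Split-half potential scale reduction factor per parameter.
#' @keywords internal
split_rhat <- function(chain_list) {
  halves <- list()
  for (d in chain_list) {
    n <- nrow(d)
    halves <- c(halves, list(d[seq_len(n %/% 2), , drop = FALSE],
                             d[(n %/% 2 + 1):n, , drop = FALSE]))
  }
  k <- ncol(chain_list[[1]])
  vapply(seq_len(k), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) var(h[, j]), numeric(1))
    n <- nrow(halves[[1]])
    w <- mean(vars)
    b <- n * var(means)
    if (w <= 0) return(NA_real_)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, numeric(1))
}

#' @export
print.diet_fit <- function(x, ...) {
  cat(sprintf("Zero/one-inflated Dirichlet diet fit: %d crabs, %d species\n",
              x$n_crabs, length(x$species)))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Average diet composition per site type
#'
#' Fits the inflated-Dirichlet model independently for each site type
#' (clam-bed and slough crabs get separate models) and binds the composition
#' summaries.
#'
#' @param counts Estimated-count tibble ([build_estimated_counts()]).
#' @param meta Sample metadata (used for the crab-to-site-type map).
#' @param ... Passed to [fit_inflated_dirichlet()].
#' @return List with `summary` (tibble: `site_type`, `species`, `mean`,
#'   `median`, `lo95`, `hi95`) and `fits` (named list of `diet_fit`).
#' @export
average_diet_by_site_type <- function(counts, meta, ...) {
  if (!"is_control" %in% names(meta)) meta$is_control <- FALSE
  crab_sites <- meta |>
    filter(!.data$is_control) |>
    distinct(.data$crab_id, .data$site_type)
  counts <- left_join(counts, crab_sites, by = "crab_id")
  if (any(is.na(counts$site_type))) {
    abort("crab(s) in count matrix missing from metadata")
  }
  species <- setdiff(names(counts), c("crab_id", "site", "site_type"))
  fits <- list()
  for (st in sort(unique(counts$site_type))) {
    sub <- counts[counts$site_type == st, c("crab_id", species)]
    if (nrow(sub) < 3) abort(sprintf("site type '%s' has fewer than 3 crabs", st))
    if (sum(as.matrix(sub[, species])) == 0) {
      abort(sprintf("site type '%s' has an all-zero count matrix", st))
    }
    fits[[st]] <- fit_inflated_dirichlet(sub, ...)
  }
  summary <- list_rbind(imap(fits, function(f, st) {
    mutate(f$summary, site_type = st, .before = 1)
  }))
  list(summary = summary, fits = fits)
}
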