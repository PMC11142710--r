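#' Expected read proportions under the amplification model
#'
#' Mechanistic forward model of PCR amplification bias: species i with
#' template-DNA proportion \eqn{\beta_i} and per-cycle log-ratio
#' amplification-efficiency offset \eqn{\alpha_i} (relative to a reference
#' species with \eqn{\alpha = 0}) has expected read proportion
#' \deqn{softmax_i(\log \beta_i + n_{cycles} \alpha_i).}
#' Over \eqn{n} cycles a species amplifying \eqn{e^{\alpha}} times faster per
#' cycle gains a factor \eqn{e^{n\alpha}} relative to the reference, which is
#' exactly this softmax.
#'
#' @param beta Template DNA proportions (sum to 1, all > 0; structural zeros
#'   must be excluded before calling).
#' @param alpha Per-species efficiency offsets, same length (reference 0).
#' @param n_cycles Total PCR cycles (both steps).
#' @return Expected read proportions (sums to 1).
#' @export
forward_read_proportions <- function(beta, alpha, n_cycles) {
  if (length(beta) != length(alpha)) abort("beta and alpha lengths differ")
  if (any(beta <= 0)) {
    abort("beta must be > 0 for modeled species; exclude structural zeros first")
  }
  assert_proportions(beta, what = "beta")
  softmax(log(beta) + n_cycles * alpha)
}

#' Keep only the lowest-cycle technical replicates per crab
#'
#' For crabs whose replicates were run at multiple total PCR cycle counts
#' (e.g. re-processed samples), only the replicates at the minimum total
#' cycles are kept; crabs with uniform cycle counts are unchanged, and
#' control rows pass through untouched.
#'
#' @param meta Sample metadata tibble (columns `crab_id`, `replicate`,
#'   `n_pcr_cycles`, optional `is_control`).
#' @return Filtered metadata tibble.
#' @export
select_lowest_cycle_replicates <- function(meta) {
  if (nrow(meta) == 0) return(meta)
  if (!"is_control" %in% names(meta)) meta$is_control <- FALSE
  crabs <- meta |>
    filter(!.data$is_control) |>
    group_by(.data$crab_id) |>
    filter(.data$n_pcr_cycles == min(.data$n_pcr_cycles)) |>
    ungroup()
  bind_rows(crabs, filter(meta, .data$is_control))
}

# Internal: shared data structure for the multinomial-softmax likelihood.
# Each element: y (reads), log_beta (known template log-proportions, or NULL
# when beta is the unknown), n_cycles, alpha_idx (position of each species in
# the alpha vector).
#' @keywords internal
neg_log_posterior_alpha <- function(alpha_free, reps, free_idx, n_species, prior_sd) {
  alpha <- numeric(n_species)
  alpha[free_idx] <- alpha_free
  nll <- 0
  for (r in reps) {
    p <- softmax(r$log_beta + r$n_cycles * alpha[r$alpha_idx])
    nll <- nll - sum(r$y * log(p))
  }
  nll + sum(alpha_free^2) / (2 * prior_sd^2)
}

#' @keywords internal
grad_alpha <- function(alpha_free, reps, free_idx, n_species, prior_sd) {
  alpha <- numeric(n_species)
  alpha[free_idx] <- alpha_free
  g <- numeric(n_species)
  for (r in reps) {
    p <- softmax(r$log_beta + r$n_cycles * alpha[r$alpha_idx])
    g[r$alpha_idx] <- g[r$alpha_idx] - r$n_cycles * (r$y - sum(r$y) * p)
  }
  g[free_idx] + alpha_free / prior_sd^2
}

#' Fit species amplification efficiencies from mock communities
#'
#' Estimates the per-cycle log-ratio amplification-efficiency offsets
#' \eqn{\alpha} from mock communities of known composition, under the
#' likelihood reads ~ Multinomial(depth, [forward_read_proportions()]) per
#' community and replicate, with the reference species fixed at
#' \eqn{\alpha = 0} by parameterization and a weakly informative prior
#' \eqn{\alpha \sim N(0, 0.1)} on the others. Inference is maximum a
#' posteriori with a Laplace (normal) approximation for intervals, which at
#' mock-community read depths is essentially exact.
#'
#' @param mocks Mock-community tibble ([read_mock_communities()]).
#' @param reference Reference species (default Manila clam,
#'   `"Ruditapes philippinarum"`).
#' @param species Optional character vector of species that must be
#'   calibrated; an error lists any absent from all mocks.
#' @param prior_sd Prior standard deviation on alpha (default 0.1).
#' @param conf Central interval coverage (default 0.95).
#' @return Object of class `amp_calibration`: list with `estimates` tibble
#'   (`species`, `alpha_mean`, `alpha_se`, `alpha_lo`, `alpha_hi`),
#'   `reference`, `prior_sd`, `convergence`.
#' @export
fit_amplification_efficiencies <- function(mocks,
                                           reference = "Ruditapes philippinarum",
                                           species = NULL, prior_sd = 0.1,
                                           conf = 0.95) {
  mocks <- validate_mock_communities(mocks)
  all_species <- sort(unique(mocks$species))
  if (!reference %in% all_species) {
    abort(sprintf("reference species '%s' absent from all mock communities",
                  reference))
  }
  if (!is.null(species)) {
    absent <- setdiff(species, all_species)
    if (length(absent)) {
      abort(sprintf("species absent from all mock communities: %s",
                    paste(absent, collapse = ", ")))
    }
  }
  sp_idx <- setNames(seq_along(all_species), all_species)
  free_idx <- sp_idx[all_species != reference]

  reps <- mocks |>
    group_by(.data$community_id, .data$replicate) |>
    dplyr::group_split() |>
    lapply(function(df) {
      list(y = df$reads, log_beta = log(df$known_prop),
           n_cycles = df$n_pcr_cycles[1], alpha_idx = sp_idx[df$species])
    })

  fit <- optim(par = numeric(length(free_idx)), fn = neg_log_posterior_alpha,
               gr = grad_alpha, reps = reps, free_idx = free_idx,
               n_species = length(all_species), prior_sd = prior_sd,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    warn(sprintf("alpha optimization did not fully converge (code %d)",
                 fit$convergence))
  }
  h <- optimHess(fit$par, neg_log_posterior_alpha, grad_alpha, reps = reps,
                 free_idx = free_idx, n_species = length(all_species),
                 prior_sd = prior_sd)
  cov <- tryCatch(solve(h), error = function(e) {
    warn("Hessian singular; intervals unavailable")
    matrix(NA_real_, length(free_idx), length(free_idx))
  })
  se_free <- sqrt(pmax(diag(cov), 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)

  alpha_mean <- setNames(numeric(length(all_species)), all_species)
  alpha_se <- setNames(numeric(length(all_species)), all_species)
  alpha_mean[names(free_idx)] <- fit$par
  alpha_se[names(free_idx)] <- se_free

  est <- tibble(species = all_species,
                alpha_mean = unname(alpha_mean),
                alpha_se = unname(alpha_se),
                alpha_lo = unname(alpha_mean - z * alpha_se),
                alpha_hi = unname(alpha_mean + z * alpha_se))
  structure(list(estimates = est, reference = reference, prior_sd = prior_sd,
                 conf = conf, convergence = fit$convergence,
                 n_communities = dplyr::n_distinct(mocks$community_id)),
            class = "amp_calibration")
}

#' @export
print.amp_calibration <- function(x, ...) {
  cat(sprintf("Amplification-efficiency calibration (%d mock communities; reference: %s)\n",
              x$n_communities, x$reference))
  print(as.data.frame(x$estimates), digits = 4)
  invisible(x)
}

#' Extract the named alpha vector from a calibration
#' @param fit An `amp_calibration` object.
#' @return Named numeric vector of posterior-mean offsets.
#' @export
alpha_vector <- function(fit) {
  setNames(fit$estimates$alpha_mean, fit$estimates$species)
}

#' Calibrate crab read counts to DNA template proportions
#'
#' Inverts the amplification model per crab: with the efficiency offsets
#' \eqn{\alpha} fixed at their calibration estimates (plug-in), the template
#' proportions \eqn{\beta} over the species detected in that crab are
#' estimated from the replicate read counts, replicates sharing one
#' \eqn{\beta} (each replicate may have its own total cycle count). Species
#' with zero reads in all replicates are structural zeros: excluded from the
#' simplex, \eqn{\hat\beta = 0}. Inference is MAP with a Laplace
#' approximation; interval summaries come from Monte-Carlo draws of the
#' approximate posterior mapped through the softmax, so posterior-mean
#' proportions sum to one exactly.
#'
#' @param reads Long tibble of replicate read counts: `crab_id`,
#'   `replicate`, `species`, `reads`, `n_pcr_cycles`.
#' @param alpha Named alpha vector (see [alpha_vector()]) or an
#'   `amp_calibration` object. Every detected species must have an entry.
#' @param prior_sd Prior SD of the unconstrained log-ratio parameters
#'   (default 3).
#' @param n_draws Monte-Carlo draws for interval summaries (default 2000).
#' @param conf Central interval coverage (default 0.95).
#' @param seed Optional seed for the interval draws.
#' @return Tibble: `crab_id`, `species`, `beta_mean`, `beta_median`,
#'   `beta_lo`, `beta_hi` (one row per detected species per crab).
#' @export
calibrate_samples <- function(reads, alpha, prior_sd = 3, n_draws = 2000,
                              conf = 0.95, seed = NULL) {
  if (inherits(alpha, "amp_calibration")) alpha <- alpha_vector(alpha)
  need <- c("crab_id", "replicate", "species", "reads", "n_pcr_cycles")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols)) {
    abort(sprintf("reads table missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  detected <- reads |>
    group_by(.data$crab_id, .data$species) |>
    summarise(total = sum(.data$reads), .groups = "drop") |>
    filter(.data$total > 0)
  no_alpha <- setdiff(unique(detected$species), names(alpha))
  if (length(no_alpha)) {
    abort(sprintf("no amplification efficiency for detected species: %s",
                  paste(no_alpha, collapse = ", ")))
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)

  out <- with_perm_stream(seed, {
    lapply(unique(detected$crab_id), function(cid) {
      sp <- sort(detected$species[detected$crab_id == cid])
      k <- length(sp)
      if (k == 1) {
        return(tibble(crab_id = cid, species = sp, beta_mean = 1,
                      beta_median = 1, beta_lo = 1, beta_hi = 1))
      }
      crab_reads <- reads[reads$crab_id == cid & reads$species %in% sp, ]
      reps <- crab_reads |>
        group_by(.data$replicate) |>
        dplyr::group_split() |>
        lapply(function(df) {
          df <- df[match(sp, df$species), ]
          y <- df$reads
          y[is.na(y)] <- 0L
          list(y = y, n_cycles = df$n_pcr_cycles[!is.na(df$n_pcr_cycles)][1])
        })
      a <- unname(alpha[sp])
      nlp <- function(eta_free) {
        eta <- c(0, eta_free)
        nll <- 0
        for (r in reps) {
          p <- softmax(eta + r$n_cycles * a)
          nll <- nll - sum(r$y * log(p))
        }
        nll + sum(eta_free^2) / (2 * prior_sd^2)
      }
      grd <- function(eta_free) {
        eta <- c(0, eta_free)
        g <- numeric(k)
        for (r in reps) {
          p <- softmax(eta + r$n_cycles * a)
          g <- g - (r$y - sum(r$y) * p)
        }
        g[-1] + eta_free / prior_sd^2
      }
      fit <- optim(numeric(k - 1), nlp, grd, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
      h <- optimHess(fit$par, nlp, grd)
      cov <- tryCatch(solve(h), error = function(e) diag(1e-12, k - 1))
      ch <- tryCatch(chol(cov), error = function(e) diag(sqrt(pmax(diag(cov), 1e-16)),
                                                         k - 1))
      zdraw <- matrix(rnorm(n_draws * (k - 1)), n_draws) %*% ch
      eta_draw <- cbind(0, sweep(zdraw, 2, fit$par, "+"))
      beta_draw <- t(apply(eta_draw, 1, softmax))
      qs <- apply(beta_draw, 2, quantile, probs = probs, names = FALSE)
      tibble(crab_id = cid, species = sp,
             beta_mean = colMeans(beta_draw),
             beta_median = apply(beta_draw, 2, stats::median),
             beta_lo = qs[1, ], beta_hi = qs[2, ])
    })
  })
  list_rbind(out)
}
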