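# Five mock communities over the eight calibrated prey species (reference
# included), used by the recovery tests.
eight_species_designs <- function() {
  sp <- crabdiet:::calibrated_prey_species()
  d <- dplyr::bind_rows(
    tibble::tibble(community_id = "A", species = sp, known_prop = 1 / 8),
    tibble::tibble(community_id = "B", species = sp,
                   known_prop = c(0.4, 0.2, 0.1, 0.1, 0.05, 0.05, 0.05, 0.05)),
    tibble::tibble(community_id = "C", species = sp,
                   known_prop = c(0.02, 0.14, 0.14, 0.14, 0.14, 0.14, 0.14, 0.14)),
    tibble::tibble(community_id = "D", species = sp[1:5],
                   known_prop = c(0.05, 0.3, 0.3, 0.2, 0.15)),
    tibble::tibble(community_id = "E", species = sp[c(1, 5:8)],
                   known_prop = c(0.3, 0.25, 0.2, 0.15, 0.1))
  )
  d$n_pcr_cycles <- 43
  d
}

test_that("forward model equals the per-cycle brute-force oracle", {
  # identity limit: no efficiency differences
  expect_equal(forward_read_proportions(c(0.3, 0.7), c(0, 0), 47),
               c(0.3, 0.7))

  # worked case: 43 cycles at the predator-scale offset
  out <- forward_read_proportions(c(0.5, 0.5), c(0, 0.0896), 43)
  expect_equal(out[2], exp(43 * 0.0896) / (1 + exp(43 * 0.0896)))
  expect_equal(out[2], 0.979, tolerance = 1e-3)

  # sand-shrimp-scale offset at 40 cycles
  out2 <- forward_read_proportions(c(0.5, 0.5), c(0, 0.0859), 40)
  expect_equal(out2[2], 0.969, tolerance = 1e-3)

  # grid equivalence with the cycle-by-cycle amplification simulation
  withr::with_seed(71, {
    for (i in 1:25) {
      k <- sample(2:6, 1)
      beta <- as.numeric(crabdiet:::rdirichlet(1, rep(1, k)))
      alpha <- c(0, runif(k - 1, -0.02, 0.09))
      n <- sample(c(40, 43, 47), 1)
      expect_equal(forward_read_proportions(beta, alpha, n),
                   brute_force_amplification(beta, alpha, n),
                   tolerance = 1e-9)
    }
  })

  # structural zeros must be excluded first
  expect_error(forward_read_proportions(c(0, 1), c(0, 0), 40), "structural")
})

test_that("lowest-cycle replicate selection keeps minimum-cycle replicates", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    crab_id = c("c1", "c1", "c1", "c2", "c2"),
    replicate = c(1L, 2L, 3L, 1L, 2L),
    site = "S", site_type = "slough",
    n_pcr_cycles = c(43, 43, 47, 40, 40))
  out <- select_lowest_cycle_replicates(meta)
  expect_equal(sort(out$sample_id[out$crab_id == "c1"]), c("s1", "s2"))
  expect_equal(nrow(out[out$crab_id == "c2", ]), 2)  # uniform: unchanged
  expect_equal(nrow(select_lowest_cycle_replicates(meta[0, ])), 0)
})

test_that("mock-community calibration recovers the true efficiencies", {
  alpha_true <- default_alpha_panel()[crabdiet:::calibrated_prey_species()]
  mocks <- simulate_mock_communities(alpha_true, eight_species_designs(),
                                     depth = 5e4, n_replicates = 3, seed = 7)
  fit <- fit_amplification_efficiencies(mocks)
  est <- fit$estimates
  est <- est[match(names(alpha_true), est$species), ]

  # reference fixed at exactly zero by parameterization
  expect_identical(est$alpha_mean[est$species == "Ruditapes philippinarum"], 0)

  # point recovery within +/- 0.01 of truth
  expect_true(all(abs(est$alpha_mean - unname(alpha_true)) < 0.01))

  # interval coverage of the truth for at least 7 of 8 species
  free <- est$species != "Ruditapes philippinarum"
  covered <- alpha_true[free] >= est$alpha_lo[free] &
    alpha_true[free] <= est$alpha_hi[free]
  expect_gte(sum(covered) + 1, 7)  # reference trivially exact

  # null recovery: identical amplification gives estimates near zero
  alpha_null <- setNames(rep(0, 8), names(alpha_true))
  mocks0 <- simulate_mock_communities(alpha_null, eight_species_designs(),
                                      depth = 5e4, n_replicates = 3, seed = 8)
  fit0 <- fit_amplification_efficiencies(mocks0)
  expect_true(all(abs(fit0$estimates$alpha_mean) < 0.005))

  # species absent from all mocks is an error naming it
  expect_error(
    fit_amplification_efficiencies(mocks, species = "Octopus rubescens"),
    "Octopus rubescens")
  expect_error(
    fit_amplification_efficiencies(mocks, reference = "Octopus rubescens"),
    "reference")
})

test_that("sample calibration inverts the forward model", {
  # identical reads with identical efficiencies: an even split
  reads <- tibble::tibble(
    crab_id = "c1", replicate = c(1L, 1L), species = c("sp1", "sp2"),
    reads = c(100L, 100L), n_pcr_cycles = 43)
  cal <- calibrate_samples(reads, c(sp1 = 0, sp2 = 0), seed = 1)
  expect_equal(cal$beta_mean, c(0.5, 0.5), tolerance = 0.01)
  expect_equal(sum(cal$beta_mean), 1, tolerance = 1e-9)

  # inverse of the worked forward example
  p <- forward_read_proportions(c(0.5, 0.5), c(0, 0.0896), 43)
  reads2 <- tibble::tibble(
    crab_id = "c1", replicate = 1L, species = c("ref", "crab"),
    reads = as.integer(round(5e4 * p)), n_pcr_cycles = 43)
  cal2 <- calibrate_samples(reads2, c(ref = 0, crab = 0.0896), seed = 2)
  expect_equal(cal2$beta_mean, c(0.5, 0.5), tolerance = 0.02)

  # structural zero: undetected species excluded from the simplex
  reads3 <- dplyr::bind_rows(reads, tibble::tibble(
    crab_id = "c1", replicate = 1L, species = "sp3", reads = 0L,
    n_pcr_cycles = 43))
  cal3 <- calibrate_samples(reads3, c(sp1 = 0, sp2 = 0, sp3 = 0), seed = 1)
  expect_false("sp3" %in% cal3$species)

  # detected species without an efficiency is an error naming it
  expect_error(calibrate_samples(reads, c(sp1 = 0), seed = 1), "sp2")
})

test_that("calibration round-trips reads drawn from the forward model", {
  alpha <- c(a = 0, b = 0.03, c = 0.06, d = 0.09)
  withr::with_seed(81, {
    errs <- replicate(10, {
      beta <- as.numeric(rdirichlet_oracle(4))
      n_cyc <- sample(c(40, 43, 47), 1)
      p <- forward_read_proportions(beta, unname(alpha), n_cyc)
      reads <- tibble::tibble(
        crab_id = "c1",
        replicate = rep(1:3, each = 4),
        species = rep(names(alpha), 3),
        reads = as.integer(rmultinom(3, 5e4, p)),
        n_pcr_cycles = n_cyc)
      cal <- calibrate_samples(reads, alpha, seed = 3)
      cal <- cal[match(names(alpha), cal$species), ]
      mean(abs(cal$beta_mean - beta))
    })
    expect_lt(mean(errs), 0.02)
  })
})

test_that("calibrated proportions are depth-invariant and rank-consistent", {
  alpha <- c(ref = 0, fast = 0.08)
  reads <- tibble::tibble(
    crab_id = "c1", replicate = c(1L, 1L), species = c("ref", "fast"),
    reads = c(2000L, 8000L), n_pcr_cycles = 43)
  cal1 <- calibrate_samples(reads, alpha, seed = 5)
  reads2 <- dplyr::mutate(reads, reads = reads * 10L)
  cal2 <- calibrate_samples(reads2, alpha, seed = 5)
  expect_equal(cal1$beta_mean, cal2$beta_mean, tolerance = 1e-3)

  # a fast amplifier's calibrated share is below its read share
  read_share_fast <- 8000 / 10000
  expect_lt(cal1$beta_mean[cal1$species == "fast"], read_share_fast)
  expect_gt(cal1$beta_mean[cal1$species == "ref"], 2000 / 10000)
})
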