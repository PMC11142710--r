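# Draw an estimated-count matrix from a plain Dirichlet-multinomial with
# mean mu and concentration phi (no inflation), via the package-independent
# gamma construction.
simulate_dirmult_counts <- function(n_crabs, mu, phi, size = 200) {
  k <- length(mu)
  m <- t(vapply(seq_len(n_crabs), function(i) {
    g <- stats::rgamma(k, phi * mu)
    p <- g / sum(g)
    as.integer(rmultinom(1, size, p))
  }, integer(k)))
  colnames(m) <- paste0("sp", seq_len(k))
  dplyr::bind_cols(tibble::tibble(crab_id = sprintf("c%02d", seq_len(n_crabs))),
                   tibble::as_tibble(m))
}

test_that("estimated-count construction is plain arithmetic", {
  cal <- tibble::tibble(crab_id = "c1", species = c("a", "b"),
                        beta_mean = c(0.6, 0.4))
  depths <- tibble::tibble(crab_id = "c1", avg_depth = 20000)
  counts <- build_estimated_counts(cal, depths, divisor = 100)
  expect_equal(unlist(counts[1, c("a", "b")], use.names = FALSE), c(120L, 80L))

  # divisor changes the scale, not the composition
  c1 <- build_estimated_counts(cal, depths, divisor = 1)
  row1 <- unlist(c1[1, c("a", "b")], use.names = FALSE)
  expect_equal(row1 / sum(row1), c(0.6, 0.4), tolerance = 1e-3)

  # structural zero stays zero; crab without calibration skipped with warning
  cal2 <- dplyr::bind_rows(cal, tibble::tibble(
    crab_id = "c1", species = "c", beta_mean = 0))
  counts2 <- build_estimated_counts(cal2, depths)
  expect_equal(counts2$c, 0L)
  depths2 <- dplyr::bind_rows(depths, tibble::tibble(crab_id = "c9",
                                                     avg_depth = 1000))
  expect_warning(build_estimated_counts(cal, depths2), "c9")

  expect_error(build_estimated_counts(cal, depths, divisor = 0))
})

test_that("the average-diet model recovers a known composition", {
  mu <- c(0.4, 0.35, 0.25)
  withr::with_seed(91, {
    counts <- simulate_dirmult_counts(40, mu, phi = 30, size = 200)
  })
  fit <- fit_inflated_dirichlet(counts, chains = 4, iter = 1500, seed = 12)
  est <- fit$summary$mean
  expect_equal(sum(est), 1, tolerance = 1e-6)
  expect_true(all(abs(est - mu) < 0.05))
  # truth inside the 95% intervals
  expect_true(all(mu >= fit$summary$lo95 & mu <= fit$summary$hi95))
  # intervals contain their means and nest (50% inside 95%)
  expect_true(all(fit$summary$mean >= fit$summary$lo95 &
                    fit$summary$mean <= fit$summary$hi95))
  expect_true(all(fit$summary$lo50 >= fit$summary$lo95 &
                    fit$summary$hi50 <= fit$summary$hi95))
})

test_that("depth division is conservative: means stable, intervals wider", {
  mu <- c(0.45, 0.3, 0.25)
  withr::with_seed(92, {
    comps <- t(vapply(1:40, function(i) {
      g <- stats::rgamma(3, 30 * mu)
      g / sum(g)
    }, numeric(3)))
  })
  cal <- tibble::tibble(
    crab_id = rep(sprintf("c%02d", 1:40), each = 3),
    species = rep(paste0("sp", 1:3), 40),
    beta_mean = as.numeric(t(comps)))
  depths <- tibble::tibble(crab_id = sprintf("c%02d", 1:40), avg_depth = 20000)
  counts100 <- build_estimated_counts(cal, depths, divisor = 100)
  counts50 <- build_estimated_counts(cal, depths, divisor = 50)
  f100 <- fit_inflated_dirichlet(counts100, chains = 2, iter = 1500, seed = 5)
  f50 <- fit_inflated_dirichlet(counts50, chains = 2, iter = 1500, seed = 5)
  expect_true(all(abs(f100$summary$mean - f50$summary$mean) < 0.02))
  width <- function(f) mean(f$summary$hi95 - f$summary$lo95)
  expect_gte(width(f100), width(f50))
})

test_that("degenerate inputs are handled explicitly", {
  # every crab entirely one species
  counts <- tibble::tibble(crab_id = c("c1", "c2", "c3"),
                           sp1 = c(200L, 180L, 220L), sp2 = 0L, sp3 = 0L)
  expect_warning(fit <- fit_inflated_dirichlet(counts, seed = 1), "zero counts")
  expect_equal(fit$summary$mean, c(1, 0, 0))
  expect_equal(fit$summary$hi95[2], 0)

  expect_error(fit_inflated_dirichlet(counts[1:2, ]), "at least 3")
})

test_that("site types are fitted independently and identically", {
  withr::with_seed(93, {
    counts <- simulate_dirmult_counts(24, c(0.5, 0.3, 0.2), phi = 25,
                                      size = 150)
  })
  # two site types carrying identical data give matching estimates
  counts2 <- dplyr::bind_rows(counts,
                              dplyr::mutate(counts,
                                            crab_id = paste0(crab_id, "_b")))
  meta <- tibble::tibble(
    crab_id = counts2$crab_id,
    site_type = rep(c("clam_bed", "slough"), each = 24),
    is_control = FALSE)
  res <- average_diet_by_site_type(counts2, meta, chains = 2, iter = 1200,
                                   seed = 9)
  cb <- res$summary[res$summary$site_type == "clam_bed", ]
  sl <- res$summary[res$summary$site_type == "slough", ]
  expect_equal(cb$mean, sl$mean, tolerance = 0.03)

  # a site type below the crab minimum errors
  meta_bad <- meta
  meta_bad$site_type[1:46] <- "clam_bed"
  expect_error(average_diet_by_site_type(counts2, meta_bad, chains = 1,
                                         iter = 200), "fewer than 3")
})

test_that("95% intervals cover the truth across repeated simulations", {
  mu <- c(0.5, 0.3, 0.2)
  withr::with_seed(94, {
    seeds <- sample.int(10000, 20)
  })
  hits <- 0
  total <- 0
  for (s in seeds) {
    withr::with_seed(s, {
      counts <- simulate_dirmult_counts(30, mu, phi = 30, size = 200)
    })
    # convergence warnings from deliberately short chains are not the
    # property under test here
    fit <- suppressWarnings(
      fit_inflated_dirichlet(counts, chains = 2, iter = 800, seed = s))
    hits <- hits + sum(mu >= fit$summary$lo95 & mu <= fit$summary$hi95)
    total <- total + 3
  }
  expect_gte(hits / total, 0.85)
})
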