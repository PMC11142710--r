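test_that("PERMANOVA sums of squares decompose and F matches vegan", {
  withr::with_seed(21, {
    m <- random_presence_matrix(18, 10)
    g <- rep(c("A", "B", "C"), each = 6)
    d <- distance_matrix(make_prey(m, sites = g), "jaccard")
    pt <- permanova(d, g, n_perm = 99, seed = 4)
    expect_equal(pt$ss[["between"]] + pt$ss[["within"]], pt$ss[["total"]],
                 tolerance = 1e-9)
    expect_gte(pt$R2, 0)
    expect_lte(pt$R2, 1)
    # independent route: vegan's adonis2 on the same distances
    av <- vegan::adonis2(d ~ g, permutations = 29)
    expect_equal(pt$statistic, av$F[1], tolerance = 1e-9)
    expect_equal(pt$R2, av$R2[1], tolerance = 1e-9)
  })
})

test_that("PERMANOVA degenerate and extreme cases behave", {
  # identical multivariate positions in both groups: no between-group SS
  m <- rbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1), c(1, 0, 1))
  d <- dist(m)
  pt <- permanova(d, c("A", "A", "B", "B"), n_perm = 99, seed = 1)
  expect_equal(pt$ss[["between"]], 0, tolerance = 1e-12)
  expect_equal(pt$p_value, 1)

  # two tight, well-separated clusters: smallest attainable p (group sizes
  # large enough that no random permutation replicates the split)
  withr::with_seed(2, {
    pts <- rbind(matrix(rnorm(20, 0, 0.01), 10),
                 matrix(rnorm(20, 50, 0.01), 10))
    d2 <- dist(pts)
    g <- rep(c("A", "B"), each = 10)
    pt2 <- permanova(d2, g, n_perm = 199, seed = 3)
    expect_equal(pt2$p_value, 1 / 200)
  })

  # contract errors
  expect_error(permanova(dist(m), c("A", "A", "A", "B")), "fewer than 2")
  expect_error(permanova(dist(m), c("A", "A", "A", "A")), "two groups")
})

test_that("Monte-Carlo p agrees with full enumeration on n = 6", {
  withr::with_seed(31, {
    pts <- matrix(rnorm(12), 6, 2)
    d <- dist(pts)
    g <- rep(c("A", "B"), each = 3)
    p_exact <- exact_permanova_p(d, 3)  # all 20 distinct assignments
    pt <- permanova(d, g, n_perm = 999, seed = 8)
    expect_lt(abs(pt$p_value - p_exact), 0.05)
  })
})

test_that("PERMANOVA p-values are valid under the exchangeable null", {
  # empirical type-I error at alpha = 0.05 over 1000 seeded null datasets
  withr::with_seed(104729, {
    rejections <- vapply(seq_len(1000), function(i) {
      m <- random_presence_matrix(12, 8)
      g <- rep(c("A", "B"), each = 6)
      d <- vegan::vegdist(m, "jaccard", binary = TRUE)
      permanova(d, g, n_perm = 99)$p_value <= 0.05
    }, logical(1))
    rate <- mean(rejections)
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
  })
})

test_that("PERMDISP measures dispersion, not location", {
  # same dispersion, different centroids: permanova fires, permdisp doesn't
  withr::with_seed(41, {
    pts <- rbind(matrix(rnorm(40, 0, 1), 20), matrix(rnorm(40, 4, 1), 20))
    g <- rep(c("A", "B"), each = 20)
    d <- dist(pts)
    expect_equal(permanova(d, g, n_perm = 199, seed = 1)$p_value, 1 / 200)
    pd <- permdisp(d, g, n_perm = 199, seed = 1)
    expect_gt(pd$p_value, 0.05)

    # one group's spread tripled: permdisp fires
    pts2 <- rbind(matrix(rnorm(40, 0, 1), 20), matrix(rnorm(40, 0, 3), 20))
    pd2 <- permdisp(dist(pts2), g, n_perm = 199, seed = 1)
    expect_lt(pd2$p_value, 0.05)
  })

  # coincident points: F undefined
  m <- matrix(1, 6, 3)
  expect_error(permdisp(dist(m), rep(c("A", "B"), each = 3)), "coincident")

  # distances to centroids agree with vegan's betadisper (centroid type),
  # including the imaginary-axis correction on a non-Euclidean matrix
  withr::with_seed(42, {
    m2 <- random_presence_matrix(15, 8)
    g2 <- rep(c("A", "B", "C"), each = 5)
    d2 <- vegan::vegdist(m2, "jaccard", binary = TRUE)
    pd3 <- permdisp(d2, g2, n_perm = 49, seed = 2)
    bd <- vegan::betadisper(d2, g2, type = "centroid")
    expect_equal(pd3$statistic, anova(bd)[1, 4], tolerance = 1e-8)
  })
})

test_that("PERMDISP holds its size under the null", {
  # both groups i.i.d. from the same distribution: rejection rate near 0.05
  withr::with_seed(7919, {
    rejections <- vapply(seq_len(500), function(i) {
      pts <- matrix(rnorm(32), 16, 2)
      g <- rep(c("A", "B"), each = 8)
      permdisp(dist(pts), g, n_perm = 99)$p_value <= 0.05
    }, logical(1))
    rate <- mean(rejections)
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
  })
})

test_that("pairwise tests apply the uncapped Bonferroni correction", {
  expect_equal(p_adjust_uncapped(0.002, 6), 0.012)
  expect_equal(p_adjust_uncapped(0.201, 6), 1.206)  # deliberately above 1
  expect_equal(p_adjust_uncapped(0.3, 1), 0.3)
  # monotone
  p <- c(0.001, 0.02, 0.3, 0.9)
  expect_true(all(diff(p_adjust_uncapped(p, 6)) > 0))

  withr::with_seed(51, {
    m <- random_presence_matrix(24, 10)
    g <- rep(c("A", "B", "C", "D"), each = 6)
    d <- vegan::vegdist(m, "jaccard", binary = TRUE)
    pw <- pairwise_permanova(d, g, n_perm = 99, seed = 9)
    expect_equal(nrow(pw), 6)
    expect_equal(pw$p_corrected, pw$p_value * 6)
    # each pair's F matches a direct two-group run with the same stream
    sub <- which(g %in% c("A", "B"))
    direct <- permanova(as.dist(as.matrix(d)[sub, sub]), g[sub],
                        n_perm = 99, seed = crabdiet:::derive_seed(9, 1))
    expect_equal(pw$statistic[pw$group_a == "A" & pw$group_b == "B"],
                 direct$statistic)
    expect_equal(pw$p_value[pw$group_a == "A" & pw$group_b == "B"],
                 direct$p_value)
  })
})

test_that("permutation p-values are seed-reproducible", {
  withr::with_seed(61, {
    m <- random_presence_matrix(16, 8)
    g <- rep(c("A", "B"), each = 8)
    d <- vegan::vegdist(m, "jaccard", binary = TRUE)
  })
  p1 <- permanova(d, g, n_perm = 199, seed = 33)
  p2 <- permanova(d, g, n_perm = 199, seed = 33)
  expect_identical(p1$p_value, p2$p_value)
  # the seed argument leaves the global RNG stream untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(permanova(d, g, n_perm = 19, seed = 5))
    after <- runif(1)
  })
  expect_identical(before, after)
})
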