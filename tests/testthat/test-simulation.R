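test_that("genotype simulator is seeded, bounded and LD-structured", {
  g1 <- simulate_genotypes(50, 20, seed = 99)
  g2 <- simulate_genotypes(50, 20, seed = 99)
  expect_identical(g1$values, g2$values)
  expect_true(all(g1$values %in% 0:2))

  # empirical allele frequencies stay inside the sampling band around the MAF range
  g <- simulate_genotypes(2000, 40, maf_range = c(0.05, 0.5), seed = 100)
  f <- colMeans(g$values) / 2
  band <- 3 * sqrt(0.5 * 0.5 / (2 * 2000))
  expect_true(all(f >= 0.05 - band & f <= 0.5 + band))

  # adjacent SNPs more correlated than lag-10 SNPs under ld_decay = 0.5
  C <- cor(g$values)
  p <- ncol(C)
  lag1 <- mean(C[cbind(1:(p - 1), 2:p)])
  lag10 <- mean(C[cbind(1:(p - 10), 11:p)])
  expect_gt(lag1, lag10)
  expect_gt(lag1, 0.1)

  # ld_decay = 0 gives essentially uncorrelated SNPs
  g0 <- simulate_genotypes(2000, 40, ld_decay = 0, seed = 101)
  C0 <- cor(g0$values)
  expect_lt(mean(abs(C0[upper.tri(C0)])), 0.05)
})

test_that("effect configuration is frozen and well-formed", {
  e1 <- simulate_effects(50)
  e2 <- simulate_effects(50)
  expect_identical(e1, e2)                      # same default seed
  expect_length(e1$S_M, 10)
  expect_equal(nrow(e1$S_N), 30)
  expect_true(all(e1$alpha > 0 & e1$alpha < 0.02))
  expect_true(all(e1$beta > 0 & e1$beta < 0.02))
  expect_true(all(e1$S_N[, 1] != e1$S_N[, 2]))
  expect_error(simulate_effects(10), class = "omga_config_error")
})

test_that("scenario mean functions match their formulas", {
  X <- matrix(0, 3, 20)
  X[2, c(2, 4, 8)] <- 1
  X[3, c(1, 6)] <- c(2, 1)
  g <- toy_genotypes(X)
  expect_equal(scenario_mean(g, "null"), rep(0, 3))
  # B: zeros -> 0; ones at 2,4,8 -> 0.3 + 0.6 - 0.07
  expect_equal(scenario_mean(g, "B"), c(0, 0.83, 0))
  # A at x1 = x6 = 0 -> cos(0) exp(0) = 1
  hA <- scenario_mean(g, "A")
  expect_equal(hA[1], 1)
  expect_equal(hA[3], 0.2 * (2 - 1) + cos(1) * exp(-1 / 4))
  # C and D match direct evaluation with a known effects object
  eff <- simulate_effects(20, seed = 7)
  hC <- scenario_mean(g, "C", eff)
  hD <- scenario_mean(g, "D", eff)
  xi <- X[3, ]
  expect_equal(hD[3], 3.8 * sum(eff$alpha * xi[eff$S_M]))
  expect_equal(hC[3], 0.02 * sum(eff$alpha * xi[eff$S_M]) +
                 1.8 * sum(eff$beta * xi[eff$S_N[, 1]] * xi[eff$S_N[, 2]]))
  expect_error(scenario_mean(g, "C"), class = "omga_config_error")
  expect_error(scenario_mean(toy_genotypes(X[, 1:4]), "A"), class = "omga_config_error")
})

test_that("trait simulator produces the stated marginal and correlation structure", {
  g <- simulate_genotypes(5000, 10, seed = 50)
  sim <- simulate_traits(g, "null", d = 5, rho = 0.3, seed = 51)
  expect_equal(ncol(sim$phenotypes), 5)
  expect_named(sim$covariates, c("Z1", "Z2"))

  # residual correlation after removing the shared mean recovers rho
  mu <- 0.02 * sim$covariates$Z1 + 0.6 * sim$covariates$Z2
  E <- sim$phenotypes - mu
  R <- cor(E)
  expect_lt(max(abs(R[upper.tri(R)] - 0.3)), 0.05)
  expect_lt(abs(mean(diag(cov(E))) - 1), 0.1)

  # rho = 0: traits essentially uncorrelated
  sim0 <- simulate_traits(g, "null", d = 3, rho = 0, seed = 52)
  R0 <- cor(sim0$phenotypes - (0.02 * sim0$covariates$Z1 + 0.6 * sim0$covariates$Z2))
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.05)

  # covariate marginals
  expect_lt(abs(mean(sim$covariates$Z1) - 2), 0.1)
  expect_lt(abs(mean(sim$covariates$Z2) - 0.6), 0.05)
})

test_that("rejection-rate harness respects alpha = 0 and returns tidy rows", {
  r <- empirical_rejection_rate("null", n = 60, p = 20, d = 2, rho = 0, reps = 60,
                                alpha = 0, seed = 53)
  expect_equal(r$rate, 0)
  expect_s3_class(r, "omga_sim")
  expect_true(all(c("rate", "conf_low", "conf_high") %in% names(r)))
  expect_lte(r$conf_low, r$rate)
})

test_that("MANOVA min-p comparator agrees with stats::manova per SNP", {
  set.seed(54)
  n <- 60
  g <- simulate_genotypes(n, 8)
  sim <- simulate_traits(g, "B", d = 3, rho = 0.3)
  Y <- sim$phenotypes; Z <- sim$covariates

  oracle <- sapply(1:8, function(k) {
    x <- g$values[, k]
    fit <- stats::manova(Y ~ Z$Z1 + Z$Z2 + x)
    summary(fit, test = "Pillai")$stats["x", "Pr(>F)"]
  })
  mine <- sapply(1:8, function(k) {
    manova_minp_gene_test(omga:::subset_snps(g, k), Y, Z, adjust = "none")
  })
  expect_equal(mine, oracle, tolerance = 1e-10)

  # single-SNP gene: gene p equals that SNP's p; sidak with m = 1 identical
  expect_equal(manova_minp_gene_test(omga:::subset_snps(g, 3), Y, Z, adjust = "sidak"),
               oracle[3], tolerance = 1e-10)

  # duplicating a SNP leaves the unadjusted minimum unchanged
  gd <- toy_genotypes(cbind(g$values, g$values[, 1]))
  expect_equal(suppressWarnings(manova_minp_gene_test(gd, Y, Z, adjust = "none")),
               manova_minp_gene_test(g, Y, Z, adjust = "none"))
  expect_error(manova_minp_gene_test(g, Y[, 1, drop = FALSE], Z),
               class = "omga_input_error")
})
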