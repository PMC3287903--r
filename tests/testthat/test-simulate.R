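test_that("pair genotype sampling is deterministic and respects the LD spec", {
  spec <- ld_pair_spec(0.3, 0.1, 0.4)
  g1 <- sample_pair_genotypes(spec, 500, seed = 42)
  g2 <- sample_pair_genotypes(spec, 500, seed = 42)
  expect_identical(g1, g2)
  expect_true(all(g1 %in% 0:2))

  # perfect LD with equal MAFs: the two columns coincide
  gp <- sample_pair_genotypes(ld_pair_spec(0.2, 0.2, 1), 300, seed = 1)
  expect_identical(gp[, "tag"], gp[, "causal"])

  # independence: empirical genotype correlation near 0 at large n
  g0 <- sample_pair_genotypes(ld_pair_spec(0.3, 0.1, 0), 1e5, seed = 7)
  expect_lt(abs(cor(g0[, 1], g0[, 2])), 0.01)

  # the genotype correlation converges to the haplotype-level rho
  g <- sample_pair_genotypes(spec, 1e5, seed = 9)
  expect_equal(cor(g[, 1], g[, 2]), 0.4, tolerance = 0.02)

  # empirical MAF converges to the spec MAF (binomial 3-sigma band)
  for (j in 1:2) {
    p <- c(0.3, 0.1)[j]
    expect_lt(abs(mean(g[, j]) / 2 - p), 3 * sqrt(p * (1 - p) / (2 * 1e5)))
  }
})

test_that("gene genotype sampling realizes conditional LD structure", {
  # at rho = rho_max (tag commoner than rare), the rare minor allele rides
  # only on tag-minor haplotypes, so the rare count never exceeds the tag
  b <- rho_max(0.3, 0.02)
  gs <- gene_spec(0.3, 0.02, b)
  g <- sample_gene_genotypes(gs, 5e4, seed = 3)
  expect_true(all(g[, "rare1"] <= g[, "tag"]))
  expect_equal(cor(g[, "tag"], g[, "rare1"]), b, tolerance = 0.02)

  # independent rares: tag-burden correlation near zero
  gs0 <- gene_spec(0.3, c(0.02, 0.03, 0.01), c(0, 0, 0))
  g0 <- sample_gene_genotypes(gs0, 1e5, seed = 5)
  sc0 <- burden_scores(g0[, -1])
  expect_lt(abs(tag_burden_correlation(g0[, 1], sc0)), 0.015)

  # positive tagging of several rares: positive, reproducible correlation
  rare <- seq(0.01, 0.04, length.out = 5)
  gsp <- gene_spec(0.25, rare, 0.5 * rho_max(0.25, rare))
  ga <- sample_gene_genotypes(gsp, 1e5, seed = 11)
  gb <- sample_gene_genotypes(gsp, 1e5, seed = 11)
  expect_identical(ga, gb)
  expect_gt(tag_burden_correlation(ga[, 1], burden_scores(ga[, -1])), 0.2)

  # per-rare-locus MAFs converge to spec
  for (j in seq_along(rare)) {
    p <- rare[j]
    expect_lt(abs(mean(ga[, 1 + j]) / 2 - p),
              3 * sqrt(p * (1 - p) / (2 * 1e5)))
  }
})

test_that("covariate simulation matches its configuration", {
  expect_error(simulate_covariates(0, 1), "positive")
  cv <- simulate_covariates(1e5, seed = 2, age_range = c(30, 60),
                            smoking_prob = 0.25)
  expect_true(all(cv$age >= 30 & cv$age <= 60))
  expect_lt(abs(mean(cv$smoking) - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
  expect_identical(cv, simulate_covariates(1e5, seed = 2,
                                           age_range = c(30, 60),
                                           smoking_prob = 0.25))
})

test_that("trait simulation follows the generating model", {
  g <- sample_pair_genotypes(ld_pair_spec(0.3, 0.3, 1), 1e5, seed = 4)
  d <- replicate_data(g, c("tag", "causal"))

  # null model: mean equals the intercept, regression slope centred on 0
  tm0 <- trait_model("quantitative", beta = 0, sigma = 1, intercept = 3)
  y0 <- simulate_trait(tm0, d, seed = 8)
  expect_equal(mean(y0), 3, tolerance = 3 / sqrt(1e5))
  fit0 <- additive_linear(g[, "causal"], y0)
  expect_lt(abs(fit0$estimate), 3 * fit0$std_error)

  # consistency: OLS at the causal SNP recovers beta at large n
  tm <- trait_model("quantitative", beta = 0.5, sigma = 1)
  y <- simulate_trait(tm, d, seed = 9)
  expect_equal(additive_linear(g[, "causal"], y)$estimate, 0.5,
               tolerance = 0.02)

  # Q1-like covariate effects enter the mean
  cv <- simulate_covariates(1e5, seed = 10)
  dq <- replicate_data(g, c("tag", "causal"), covariates = cv)
  tmq <- trait_model("quantitative_with_covariates", beta = 0, sigma = 1,
                     covariate_effects = c(age = 0.1, smoking = 2))
  yq <- simulate_trait(tmq, dq, seed = 11)
  fit_age <- lm(yq ~ cv$age + cv$smoking)
  expect_equal(unname(coef(fit_age)[2]), 0.1, tolerance = 0.005)
  expect_equal(unname(coef(fit_age)[3]), 2, tolerance = 0.05)

  # binary: null case fraction follows the baseline log-odds
  tmb <- trait_model("binary", beta = 0, intercept = qlogis(0.3))
  yb <- simulate_trait(tmb, d, seed = 12)
  expect_lt(abs(mean(yb) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))

  # burden-model trait: lambda drives the score, not per-locus betas
  rare <- seq(0.01, 0.04, length.out = 5)
  gg <- sample_gene_genotypes(gene_spec(0.25, rare, rep(0.1, 5)), 5e4,
                              seed = 13)
  dg <- replicate_data(gg, c("tag", rep("rare_causal", 5)))
  tml <- trait_model("quantitative", lambda = 5, sigma = 1)
  yl <- simulate_trait(tml, dg, seed = 14)
  lam <- collapsing_regression(burden_scores(gg[, -1]), yl)
  expect_lt(abs(lam$estimate - 5), 3 * lam$std_error)
})

test_that("trait model validation and data contracts are enforced", {
  expect_error(trait_model("quantitative"), "exactly one")
  expect_error(trait_model("quantitative", beta = 1, lambda = 1),
               "exactly one")
  expect_error(trait_model("quantitative", beta = 1, sigma = 0), "sigma")
  g <- matrix(c(0, 1, 3, 2), 2)
  expect_error(replicate_data(g, c("tag", "causal")), "\\{0, 1, 2\\}")
  g2 <- matrix(c(0L, 1L, 2L, 0L), 2)
  expect_error(replicate_data(g2, c("tag", "weird")), "locus_roles")
  d <- replicate_data(g2, c("tag", "causal"))
  expect_error(simulate_trait(trait_model("quantitative", lambda = 1), d, 1),
               "rare causal")
})

test_that("missingness masking hits the configured rate and is seeded", {
  g <- matrix(1L, 1000, 20)
  gm <- mask_genotypes(g, 0.1, seed = 6)
  expect_identical(gm, mask_genotypes(g, 0.1, seed = 6))
  expect_lt(abs(mean(is.na(gm)) - 0.1), 3 * sqrt(0.1 * 0.9 / length(g)))
  expect_identical(mask_genotypes(g, 0, seed = 6), g)
})
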