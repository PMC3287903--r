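test_that("replicate records are deterministic and internally consistent", {
  cfg <- example_config("S1", seed = 123, replicates = 40)
  res1 <- run_scenario(cfg)
  res2 <- run_scenario(cfg)
  expect_identical(res1$records, res2$records)
  expect_equal(nrow(res1$records), 40)
  # any single replicate is reproducible in isolation
  row17 <- res1$records[17, ]
  rownames(row17) <- NULL
  expect_identical(run_replicate(cfg, 17L), row17)
  # selection flag consistent with the recorded p-value
  rec <- res1$records
  expect_identical(rec$selected, rec$tag_p < 0.05)
  # selection consistency with estimated_power (same records, same rule)
  expect_equal(estimated_power(rec), mean(rec$selected[rec$valid]))
})

test_that("with the causal SNP as its own tag, both stages coincide", {
  cfg <- example_config("S1", seed = 5, replicates = 25, rho = 1)
  res <- run_scenario(cfg)
  expect_equal(res$records$tag_estimate, res$records$causal_estimate,
               tolerance = 1e-12)
})

test_that("scenario constraints are enforced at configuration time", {
  rare <- c(0.01, 0.02, 0.03)
  tm <- trait_model("quantitative", lambda = 1, sigma = 1)
  expect_error(run_config("S2", n = 100, gene = gene_spec(0.04, rare,
                                                          rep(0.1, 3)),
                          trait = tm), "common tag")
  expect_error(run_config("S3", n = 100,
                          gene = gene_spec(0.10, rare, rep(0.1, 3),
                                           exclude_tag_from_burden = TRUE),
                          trait = tm), "MAF in \\[0.01, 0.05\\]")
  expect_error(run_config("S3", n = 100,
                          gene = gene_spec(0.03, rare, rep(0.1, 3)),
                          trait = tm), "exclude_tag_from_burden")
  expect_error(run_config("S1", n = 100, trait = tm), "requires a `pair`")
  expect_error(selection_rule(0), "alpha")
})

test_that("the tag SNP is excluded from the burden in scenario 3 only", {
  rare <- c(0.02, 0.03, 0.04)
  tm <- trait_model("quantitative", lambda = 1, sigma = 1)
  gene_in <- gene_spec(0.03, rare, rep(0.15, 3))
  gene_ex <- gene_spec(0.03, rare, rep(0.15, 3),
                       exclude_tag_from_burden = TRUE)
  cfg_ex <- run_config("S3", n = 400, replicates = 1, seed = 2,
                       gene = gene_ex, trait = tm)
  d <- simulate_replicate(cfg_ex, 1)
  cols_in <- wincurse:::burden_columns(list(gene = gene_in), d)
  cols_ex <- wincurse:::burden_columns(cfg_ex, d)
  expect_equal(length(cols_in), 4L)  # low-MAF tag joins the collapsing set
  expect_equal(length(cols_ex), 3L)  # ... unless explicitly excluded (S3)
  expect_false(1L %in% cols_ex)
})

test_that("null configurations select at the nominal rate", {
  cfg <- example_config("S1", seed = 99, replicates = 400, beta = 0)
  res <- run_scenario(cfg)
  band <- 3 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(estimated_power(res$records) - 0.05), band)
})

test_that("one-sided selection requires a sign-consistent estimate", {
  cfg <- example_config("S1", seed = 21, replicates = 200, beta = 0,
                        alpha = 0.025, sided = "one_sided_positive")
  rec <- run_scenario(cfg)$records
  expect_identical(rec$selected,
                   rec$tag_estimate > 0 & rec$tag_p < 0.05)
  # re-thresholding records reproduces the original selection
  rec2 <- apply_selection(rec, selection_rule(0.025, "one_sided_positive"))
  expect_identical(rec$selected, rec2$selected)
})

test_that("degenerate replicates are flagged, excluded and counted", {
  # a near-monomorphic tag at tiny n is often constant within a replicate
  cfg <- run_config("S1", n = 25, replicates = 40, seed = 3,
                    pair = ld_pair_spec(0.01, 0.3, 0),
                    trait = trait_model("quantitative", beta = 0, sigma = 1))
  res <- run_scenario(cfg)
  expect_gt(res$n_invalid, 0)
  bad <- res$records[!res$records$valid, ]
  expect_true(all(grepl("constant|too few", bad$invalid_reason)))
  expect_true(all(!bad$selected))
  expect_equal(wincurse::estimated_power(res$records),
               mean(res$records$selected[res$records$valid]))
})

test_that("threshold calibration walks the ladder correctly", {
  # effect so small that every threshold keeps power below the ceiling
  weak <- example_config("S1", seed = 41, replicates = 150, beta = 0)
  cal <- calibrate_alpha(weak, power_ceiling = 0.2)
  expect_equal(cal$alpha, 0.05)
  # effect so large that even the strictest threshold has high power
  strong <- example_config("S1", seed = 42, replicates = 60, beta = 0.4)
  expect_error(calibrate_alpha(strong, power_ceiling = 0.2), "pilot powers")
  # intermediate effect: the chosen threshold is admissible and the next
  # larger one is not
  mid <- example_config("S1", seed = 43, replicates = 250, beta = 0.124)
  calm <- calibrate_alpha(mid, power_ceiling = 0.2)
  expect_lt(calm$pilot_powers[format(calm$alpha)], 0.2)
  ladder <- c(0.05, 0.01, 0.001)
  pos <- match(calm$alpha, ladder)
  expect_gt(pos, 1)
  expect_gte(calm$pilot_powers[pos - 1], 0.2)
})
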