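test_that("genotypes follow Hardy-Weinberg proportions at the panel MAF", {
  # degenerate MAFs
  G0 <- simulate_genotypes(tiny_panel(c(rs0 = 0)), n = 500, seed = 1)
  expect_true(all(G0 == 0))
  Gh <- simulate_genotypes(tiny_panel(c(rsh = 0.5)), n = 1e5, seed = 2)
  expect_equal(mean(Gh), 1.0, tolerance = 0.01)
  # HWE class frequencies (1-p)^2, 2p(1-p), p^2 at p = 0.34
  G <- simulate_genotypes(tiny_panel(c(rs2293889 = 0.34)), n = 1e5, seed = 3)
  freqs <- as.numeric(table(factor(G, levels = 0:2)) / length(G))
  expect_equal(freqs, c(0.66^2, 2 * 0.34 * 0.66, 0.34^2), tolerance = 0.02)
})

test_that("genotype simulation validates inputs and honours site MAFs", {
  expect_error(variant_panel("rs1", maf_combined = 0.6), "MAF")
  expect_error(simulate_genotypes(tiny_panel(), n = 10,
                                  site = rep("peri-urban", 10)),
               "site")
  panel <- variant_panel("rsX", maf_combined = 0.25,
                         maf_rural = 0.05, maf_urban = 0.45)
  site <- rep(c("rural", "urban"), each = 2e4)
  G <- simulate_genotypes(panel, site = site, seed = 4)
  expect_lt(abs(mean(G[site == "rural", ]) / 2 - 0.05), 0.01)
  expect_lt(abs(mean(G[site == "urban", ]) / 2 - 0.45), 0.01)
})

test_that("covariate generator matches the profile marginals", {
  cov <- simulate_covariates(n = 10000, seed = 5)
  expect_equal(mean(cov$site == "rural"), 0.4237, tolerance = 0.015)
  expect_equal(mean(cov$age), 47.07, tolerance = 0.2)
  expect_true(all(cov$physical_activity %in% 0:3))
  # all-male profile
  prof <- default_cohort_profile()
  prof$gender_site <- c(urban_male = 0.5, rural_male = 0.5)
  cov_m <- simulate_covariates(prof, n = 50, seed = 6)
  expect_true(all(cov_m$gender == "male"))
  # invalid proportions rejected
  prof$gender_site <- c(urban_male = 0.9, rural_male = 0.9)
  expect_error(simulate_covariates(prof, n = 10), "sum to 1")
})

test_that("phenotypes are calibrated to the trait summaries", {
  set.seed(7)
  cohort <- null_cohort(n = 1e5)
  gm_tg <- exp(mean(log(cohort$tg)))
  expect_equal(gm_tg, 125.96, tolerance = 1)
  expect_equal(mean(cohort$tc), 183.68, tolerance = 0.5)
  # structural identities
  expect_equal(cohort$vldl, cohort$tg / 5)
  ok <- !is.na(cohort$ldl)
  expect_equal(cohort$ldl[ok] + cohort$hdl[ok] + cohort$vldl[ok],
               cohort$tc[ok])
  expect_true(all(cohort$tc > 0 & cohort$tg > 0 & cohort$hdl > 0))
})

test_that("a noiseless single-SNP effect makes the trait collinear with dosage", {
  n <- 300
  set.seed(8)
  cov <- simulate_covariates(n = n)
  G <- simulate_genotypes(tiny_panel(c(rs1 = 0.3)), n = n, seed = 9)
  spec <- effect_spec(data.frame(rsid = "rs1", trait = "TC", beta = 1))
  ph <- simulate_phenotypes(G, cov, spec, seed = 10)
  # genetic variance ~ 0.42 of total; correlation must match sqrt share
  r <- cor(ph$tc, G[, "rs1"])
  expect_gt(r, 0.5)
  # zero residual noise: the trait is an exact affine function of dosage
  spec0 <- effect_spec(data.frame(rsid = "rs1", trait = "TC", beta = 0.5),
                       residual_sd = 0)
  ph0 <- simulate_phenotypes(G, cov, spec0, seed = 11)
  expect_equal(cor(ph0$tc, G[, "rs1"]), 1)
})

test_that("missingness masking matches the call-rate contract", {
  G <- simulate_genotypes(tiny_panel(rep(0.2, 10) |> setNames(paste0("rs", 1:10))),
                          n = 20000, seed = 12)
  expect_identical(apply_missingness(G, 1), G)
  Gm <- apply_missingness(G, 0.95, seed = 13)
  expect_equal(unname(call_rate(Gm)), rep(0.95, 10), tolerance = 0.005)
  expect_error(apply_missingness(G, 0), "call_rate")
  # masked values only: surviving entries are unchanged
  keep <- !is.na(Gm)
  expect_identical(Gm[keep], G[keep])
  # binomial count check at call_rate 0.5
  Gs <- simulate_genotypes(tiny_panel(), n = 10, seed = 14)
  masked <- sum(is.na(apply_missingness(Gs, 0.5, seed = 15)))
  expect_gt(masked, qbinom(0.0005, 20, 0.5))
  expect_lt(masked, qbinom(0.9995, 20, 0.5))
})

test_that("fixing the seed fixes the whole cohort bit for bit", {
  a <- simulate_cohort(n = 200, seed = 42)
  b <- simulate_cohort(n = 200, seed = 42)
  expect_identical(a, b)
  c <- simulate_cohort(n = 200, seed = 43)
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("simulated genotypes pass the HWE test at the nominal rate", {
  # HWE holds by construction: rejection rate at alpha should be ~alpha
  set.seed(16)
  alpha <- 0.05
  pvals <- replicate(400, {
    g <- rbinom(500, 2, 0.3)
    hwe_test(g, method = "chisq")$p
  })
  rate <- mean(pvals < alpha)
  expect_lt(abs(rate - alpha), 0.03)
})
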