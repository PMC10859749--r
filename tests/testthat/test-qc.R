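test_that("call rate is observed over total per variant", {
  G <- matrix(0, 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(call_rate(G)), c(1, 1))
  G[1:5, 2] <- NA
  expect_equal(unname(call_rate(G)), c(1, 0.95))
  expect_error(call_rate(G[0, , drop = FALSE]), "no samples")
})

test_that("MAF estimation reflects and reports allele swaps", {
  expect_equal(estimate_maf(genotype_counts(25, 50, 25))$maf, 0.5)
  expect_equal(estimate_maf(genotype_counts(100, 0, 0))$maf, 0)
  # relabelling the homozygotes leaves the oriented MAF unchanged
  a <- estimate_maf(genotype_counts(70, 20, 10))
  b <- estimate_maf(genotype_counts(10, 20, 70))
  expect_equal(a$maf, b$maf)
  expect_false(a$swapped)
  expect_true(b$swapped)
  expect_error(estimate_maf(genotype_counts(0, 0, 0)), "no observed")
  # sampling check at a bundled-panel frequency
  g <- simulate_genotypes(tiny_panel(c(rs174546 = 0.14)), n = 1e5, seed = 21)
  expect_lt(abs(estimate_maf(g[, 1])$maf - 0.14), 0.005)
})

test_that("chi-square HWE statistic equals the hand-computed Pearson form", {
  perfect <- hwe_test(genotype_counts(25, 50, 25), method = "chisq")
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p, 1)
  # all homozygotes at p = 0.5: expected (25, 50, 25), X2 = 25 + 50 + 25
  extreme <- hwe_test(genotype_counts(50, 0, 50), method = "chisq")
  expect_equal(extreme$statistic, 100)
  expect_equal(extreme$p, pchisq(100, 1, lower.tail = FALSE))
  expect_lt(extreme$p, 2e-23)
  expect_warning(res <- hwe_test(genotype_counts(80, 0, 0)), "monomorphic")
  expect_equal(res$p, 1)
})

test_that("exact HWE test matches brute-force enumeration on small counts", {
  # independent oracle: enumerate heterozygote counts with plain factorials
  exact_oracle <- function(n_AA, n_Aa, n_aa) {
    n <- n_AA + n_Aa + n_aa
    n_minor <- 2 * n_aa + n_Aa
    hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
    prob <- sapply(hets, function(h) {
      n_mm <- (n_minor - h) / 2
      n_MM <- n - n_mm - h
      2^h * factorial(n) / (factorial(n_MM) * factorial(h) * factorial(n_mm)) *
        factorial(n_minor) * factorial(2 * n - n_minor) / factorial(2 * n)
    })
    p_obs <- prob[hets == n_Aa]
    sum(prob[prob <= p_obs + 1e-12])
  }
  cases <- list(c(12, 6, 2), c(5, 10, 5), c(15, 2, 3), c(8, 0, 12),
                c(18, 1, 1))
  for (cs in cases) {
    got <- hwe_test(genotype_counts(cs[1], cs[2], cs[3]), method = "exact")$p
    expect_equal(got, exact_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
})

test_that("chi-square and exact tests agree for large balanced counts", {
  set.seed(22)
  # expected counts >= 200 in every genotype class
  for (maf in c(0.3, 0.4, 0.5)) {
    g <- rbinom(3000, 2, maf)
    counts <- count_genotypes(g)
    p_chi <- hwe_test(counts, method = "chisq")$p
    p_ex <- hwe_test(counts, method = "exact")$p
    expect_lt(abs(p_chi - p_ex), 0.1 * max(p_chi, p_ex))
  }
})

test_that("Sidak threshold follows the closed form", {
  expect_equal(sidak_threshold(0.05, 1), 0.05)
  expect_equal(sidak_threshold(0.05, 12), 1 - 0.95^(1 / 12))
  expect_equal(sidak_threshold(0.05, 12), 0.004265318, tolerance = 1e-6)
  expect_error(sidak_threshold(0.05, 0), "m must be")
  expect_identical(paper_hwe_threshold(), 0.0018)
})

test_that("qc_filter retains compliant variants and drops violators", {
  sim <- simulate_cohort(n = 2117, seed = 23)
  qc <- qc_filter(sim$genotypes, sim$panel, site = sim$cohort$site)
  expect_setequal(qc$retained, sim$panel$rsid)
  # low call rate excluded
  G <- sim$genotypes
  G[sample(2117, 250), "rs174546"] <- NA
  qc2 <- qc_filter(G, sim$panel, site = sim$cohort$site)
  expect_false("rs174546" %in% qc2$retained)
  expect_true(qc2$report$pass_hwe[qc2$report$rsid == "rs174546"])
  # heterozygote deficit (inbreeding F = 0.5) excluded by the HWE filter
  set.seed(24)
  f <- 0.5; p <- 0.3
  inbred <- sample(0:2, 2117, replace = TRUE,
                   prob = c((1 - p)^2 + f * p * (1 - p),
                            2 * p * (1 - p) * (1 - f),
                            p^2 + f * p * (1 - p)))
  G3 <- cbind(sim$genotypes, rs_bad = inbred)
  panel3 <- rbind(as.data.frame(sim$panel),
                  data.frame(rsid = "rs_bad", locus = NA, chrom_pos = NA,
                             major_allele = NA, minor_allele = NA,
                             maf_combined = p, maf_rural = p, maf_urban = p,
                             risk_is_major = FALSE))
  qc3 <- qc_filter(G3, panel3, site = sim$cohort$site)
  expect_false("rs_bad" %in% qc3$retained)
})

test_that("under true HWE the rejection rate matches the threshold", {
  set.seed(25)
  thr <- 0.05
  rej <- mean(replicate(1000, {
    hwe_test(rbinom(400, 2, 0.25), method = "chisq")$p < thr
  }))
  expect_lt(abs(rej - thr), 0.02)
})
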