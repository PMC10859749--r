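ra <- reported_associations()
panel <- lipid_variant_panel()

test_that("dual-significance selection reproduces the published variant sets", {
  expect_identical(select_validated_variants(ra, "TG", panel = panel),
                   c("rs174546", "rs17482753", "rs2293889", "rs4148005",
                     "rs4420638"))
  expect_identical(select_validated_variants(ra, "TC", panel = panel),
                   c("rs2293889", "rs4147536"))
  expect_identical(select_validated_variants(ra, "HDL", panel = panel),
                   c("rs174546", "rs17482753", "rs4148005", "rs4420638",
                     "rs7832643"))
  expect_identical(select_validated_variants(ra, "LDL", panel = panel),
                   c("rs2293889", "rs4147536", "rs4420638", "rs660240"))
  expect_identical(select_validated_variants(ra, "VLDL", panel = panel),
                   select_validated_variants(ra, "TG", panel = panel))
  expect_length(select_validated_variants(ra, "TG", alpha = 1e-12,
                                          panel = panel), 0)
  expect_error(select_validated_variants(ra[ra$model == 1, ], "TG"),
               "both models")
})

test_that("risk-allele orientation tracks the adverse direction per trait", {
  # TC-raising major-allele variant: counted allele is the major allele
  def_tc <- orient_risk_alleles(ra, "TC",
                                select_validated_variants(ra, "TC", panel = panel))
  expect_true(all(def_tc$counted_is_minor))  # beta > 0 on minor coding
  # the bundled panel flags rs4147536 as major-allele-risk; with dosages in
  # minor-allele coding and beta > 0, the minor-coded dosage is still counted
  # -- the flag refers to the biological allele identity, checked below
  expect_true(panel$risk_is_major[panel$rsid == "rs4147536"])
  # HDL: counted allele is the HDL-lowering one, weight = |beta|
  def_hdl <- orient_risk_alleles(ra, "HDL", "rs174546")
  expect_true(def_hdl$counted_is_minor)  # minor allele lowers HDL
  expect_equal(def_hdl$weight, 0.10)
  # flipping the adverse direction flips every orientation, keeps |weights|
  def_flip <- orient_risk_alleles(ra, "HDL", "rs174546",
                                  adverse_direction = "increase")
  expect_equal(def_flip$counted_is_minor, !def_hdl$counted_is_minor)
  expect_equal(def_flip$weight, def_hdl$weight)
  expect_error(orient_risk_alleles(ra, "TG", "rs660240"), "zero")
})

test_that("uGRS and wGRS arithmetic follows the score equation", {
  def <- orient_risk_alleles(ra, "TG",
                             select_validated_variants(ra, "TG", panel = panel))
  expect_equal(def$weight, c(0.11, 0.21, 0.08, 0.11, 0.10))
  # worked example: dosages (1,0,2,1,0) with the TG Model 2 weights
  G1 <- matrix(c(1, 0, 2, 1, 0), nrow = 1,
               dimnames = list("s1", def$rsid))
  expect_equal(unname(compute_wgrs(G1, def)), 0.11 + 0.16 + 0.11)
  expect_equal(unname(compute_ugrs(G1, def)), 4)
  # all homozygous for every counted allele -> 2i
  G2 <- matrix(2, nrow = 3, ncol = 5, dimnames = list(NULL, def$rsid))
  expect_equal(unname(compute_ugrs(G2, def)), rep(10, 3))
  # no counted alleles -> 0
  G0 <- matrix(0, nrow = 2, ncol = 5, dimnames = list(NULL, def$rsid))
  expect_equal(unname(compute_wgrs(G0, def)), c(0, 0))
  # uGRS = wGRS under unit weights; wGRS = w x uGRS under uniform weights
  def_unit <- def; def_unit$weight <- rep(1, 5)
  def_w <- def; def_w$weight <- rep(0.3, 5)
  G <- simulate_genotypes(panel, 100, seed = 51)[, def$rsid]
  expect_equal(compute_wgrs(G, def_unit), compute_ugrs(G, def_unit))
  expect_equal(compute_wgrs(G, def_w), 0.3 * compute_ugrs(G, def_w))
})

test_that("scores stay in range and handle missing genotypes", {
  def <- orient_risk_alleles(ra, "TG",
                             select_validated_variants(ra, "TG", panel = panel))
  sim <- simulate_cohort(n = 300, call_rate = 0.9, seed = 52)
  u <- compute_ugrs(sim$genotypes, def)
  expect_true(all(u >= 0 & u <= 10, na.rm = TRUE))
  # without imputation, untouched rows are integers
  u_cc <- compute_ugrs(sim$genotypes, def, impute_missing = FALSE)
  full <- rowSums(is.na(sim$genotypes[, def$rsid])) == 0
  expect_true(all(u_cc[full] == round(u_cc[full])))
  # a person missing every score genotype gets NA
  G <- sim$genotypes
  G[1, def$rsid] <- NA
  expect_true(is.na(compute_ugrs(G, def)[1]))
})

test_that("doubling weights doubles scores and halves the fitted slope", {
  def <- orient_risk_alleles(ra, "TG",
                             select_validated_variants(ra, "TG", panel = panel))
  sim <- simulate_cohort(n = 800, seed = 53)
  w1 <- compute_wgrs(sim$genotypes, def)
  def2 <- def; def2$weight <- 2 * def$weight
  w2 <- compute_wgrs(sim$genotypes, def2)
  expect_equal(w2, 2 * w1)
  a1 <- grs_association(w1, sim$cohort, "TG")
  a2 <- grs_association(w2, sim$cohort, "TG")
  expect_equal(a2$beta, a1$beta / 2)
  expect_equal(a2$p, a1$p)
})

test_that("score association is invariant to upstream allele coding flips", {
  def <- orient_risk_alleles(ra, "HDL",
                             select_validated_variants(ra, "HDL", panel = panel))
  sim <- simulate_cohort(n = 600, seed = 54)
  a <- grs_association(compute_wgrs(sim$genotypes, def), sim$cohort, "HDL")
  # flip the stored coding of one variant and the orientation flag with it
  G2 <- sim$genotypes
  G2[, "rs174546"] <- 2 - G2[, "rs174546"]
  def2 <- def
  def2$counted_is_minor[def2$rsid == "rs174546"] <- FALSE
  b <- grs_association(compute_wgrs(G2, def2), sim$cohort, "HDL")
  expect_equal(a$beta, b$beta)
  expect_equal(a$p, b$p)
})

test_that("risk scores aggregate true effects on simulated cohorts", {
  sim <- simulate_cohort(n = 2117, seed = 55)
  res <- run_panel(sim$genotypes, sim$cohort, sim$panel)
  # wGRS-TG association strongly positive by construction
  s_tg <- build_risk_scores(sim$genotypes, sim$cohort, reported_associations(),
                            "TG", panel = sim$panel)
  expect_gt(s_tg$assoc_wgrs$beta, 0)
  expect_lt(s_tg$assoc_wgrs$p, 0.001)
  # HDL score counts HDL-lowering alleles with positive weights -> beta < 0
  s_hdl <- build_risk_scores(sim$genotypes, sim$cohort, reported_associations(),
                             "HDL", panel = sim$panel)
  expect_lt(s_hdl$assoc_wgrs$beta, 0)
  # aggregation: |z| of the score beats the best single variant (majority
  # property; here asserted on one fixed-seed cohort)
  z_single <- abs(res$beta / res$se)[res$trait == "TG" & res$model == 1]
  z_score <- abs(s_tg$assoc_wgrs$beta / s_tg$assoc_wgrs$se)
  expect_gt(z_score, max(z_single, na.rm = TRUE))
})

test_that("a score independent of the trait shows a null association", {
  set.seed(56)
  sim <- simulate_cohort(n = 500, seed = 57)
  fake <- rnorm(500)
  a <- grs_association(fake, sim$cohort, "TC")
  expect_gt(a$p, 0.001)  # no systematic signal
})
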