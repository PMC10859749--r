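#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Minor-allele dosages at each variant are drawn as Binomial(2, MAF) with
#' the site-specific MAF from the panel, independently across variants (the
#' bundled panel's 12 variants sit on 9 chromosomes, so no linkage
#' disequilibrium is simulated; supply a correlated generator externally if
#' LD matters).
#'
#' @param panel A [variant_panel].
#' @param n Number of samples (>= 1); ignored when `site` is given.
#' @param site Per-sample site labels, `"rural"` or `"urban"`, selecting the
#'   matching MAF column; `NULL` uses `maf_combined` for all samples.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer matrix n x variants of dosages in \{0, 1, 2\}, with rsIDs
#'   as column names.
#' @export
simulate_genotypes <- function(panel, n, site = NULL, seed = NULL) {
  panel <- validate_panel(as.data.frame(panel))
  if (!is.null(site)) {
    site <- as.character(site)
    if (!all(site %in% c("rural", "urban"))) {
      stop("site labels must be 'rural' or 'urban'")
    }
    n <- length(site)
  }
  if (n < 1) stop("simulate_genotypes: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(0L, nrow = n, ncol = nrow(panel),
              dimnames = list(NULL, panel$rsid))
  for (j in seq_len(nrow(panel))) {
    maf <- if (is.null(site)) {
      rep(panel$maf_combined[j], n)
    } else {
      ifelse(site == "rural", panel$maf_rural[j], panel$maf_urban[j])
    }
    G[, j] <- stats::rbinom(n, 2L, maf)
  }
  G
}

#' Default covariate profile of the emulated cohort
#'
#' Marginal distributions matching the source cohort (n = 2,117): joint
#' gender x site counts (urban male 565, urban female 655, rural male 393,
#' rural female 504), age 47.07 (12.99) years, BMI 24.91 (5.25) kg/m^2, fat
#' intake 31.09 (5.05) g/day, physical activity categories
#' (inactive/low/moderate/high) at 11.5/52.7/25.3/10.5%, alcohol 23.9%,
#' smoking 23.5%, diabetes 8.0%, hypertension 18.9%.
#'
#' @return A list consumed by [simulate_covariates].
#' @export
default_cohort_profile <- function() {
  pa <- c(0.1150, 0.5273, 0.2526, 0.1050)
  list(
    gender_site = c(urban_male = 565, urban_female = 655,
                    rural_male = 393, rural_female = 504) / 2117,
    age = c(mean = 47.07, sd = 12.99),
    bmi = c(mean = 24.91, sd = 5.25),
    fat_intake = c(mean = 31.09, sd = 5.05),
    physical_activity = pa / sum(pa),
    alcohol = 0.2390, smoking = 0.2352,
    diabetes = 0.0798, hypertension = 0.1890,
    ranges = list(age = c(18, 90), bmi = c(13, 60), fat_intake = c(5, 60))
  )
}

#' Simulate cohort covariates from marginal summaries
#'
#' Continuous covariates are Normal(mean, SD) truncated (clipped) to
#' plausible ranges; categorical covariates follow the stated proportions.
#' Gender and site are drawn jointly from the profile's cross-tabulation;
#' all other covariates are independent (the emulated study reports only
#' marginals).
#'
#' @param profile A profile list as from [default_cohort_profile].
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `age`, `gender`, `site`, `bmi`,
#'   `fat_intake`, `physical_activity` (integer 0-3), `alcohol`, `smoking`,
#'   `diabetes`, `hypertension` (0/1).
#' @export
simulate_covariates <- function(profile = default_cohort_profile(), n,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gs <- profile$gender_site
  check_props <- c(list(gs, profile$physical_activity),
                   profile[c("alcohol", "smoking", "diabetes", "hypertension")])
  for (pr in check_props) {
    if (any(pr < 0 | pr > 1)) stop("proportions must lie in [0, 1]")
  }
  if (abs(sum(gs) - 1) > 1e-6 || abs(sum(profile$physical_activity) - 1) > 1e-6) {
    stop("category proportions must sum to 1")
  }
  cell <- sample(names(gs), n, replace = TRUE, prob = gs)
  rtrunc <- function(par, range) {
    pmin(pmax(stats::rnorm(n, par[["mean"]], par[["sd"]]), range[1]), range[2])
  }
  data.frame(
    age = rtrunc(profile$age, profile$ranges$age),
    gender = ifelse(grepl("female", cell), "female", "male"),
    site = ifelse(grepl("urban", cell), "urban", "rural"),
    bmi = rtrunc(profile$bmi, profile$ranges$bmi),
    fat_intake = rtrunc(profile$fat_intake, profile$ranges$fat_intake),
    physical_activity = sample(0:3, n, replace = TRUE,
                               prob = profile$physical_activity),
    alcohol = stats::rbinom(n, 1, profile$alcohol),
    smoking = stats::rbinom(n, 1, profile$smoking),
    diabetes = stats::rbinom(n, 1, profile$diabetes),
    hypertension = stats::rbinom(n, 1, profile$hypertension),
    stringsAsFactors = FALSE
  )
}

#' Define true effects for the phenotype simulator
#'
#' @param betas `data.frame` with columns `rsid`, `trait`, `beta`: per
#'   minor-allele effects on the standardized (trait or log-trait) scale.
#'   Only TC, TG and HDL are simulated directly; LDL follows by Friedewald
#'   and VLDL as TG/5.
#' @param trait_summaries Named list of [trait_summary] objects giving each
#'   simulated trait's location/scale (defaults to
#'   [default_trait_summaries]).
#' @param covariate_effects Optional named list per trait of named numeric
#'   vectors of effects (z-scale per unit) for numeric covariate columns;
#'   default none.
#' @param residual_sd Optional residual SD on the latent z-scale: a scalar or
#'   a vector named by trait. The default (`NULL`) completes the latent
#'   variance to 1 so the standardized-trait calibration holds; 0 gives a
#'   noiseless trait.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(betas, trait_summaries = default_trait_summaries(),
                        covariate_effects = NULL, residual_sd = NULL) {
  stopifnot(is.data.frame(betas),
            all(c("rsid", "trait", "beta") %in% names(betas)))
  need <- c("TC", "TG", "HDL")
  if (!all(need %in% names(trait_summaries))) {
    stop("trait_summaries must cover TC, TG and HDL")
  }
  if (!is.null(residual_sd) && any(residual_sd < 0)) {
    stop("residual_sd must be non-negative")
  }
  structure(list(betas = betas, trait_summaries = trait_summaries,
                 covariate_effects = covariate_effects,
                 residual_sd = residual_sd),
            class = "effect_spec")
}

#' Effect specification calibrated to the published estimates
#'
#' Uses the fully adjusted (Model 2 by default) standardized per-allele
#' estimates from [reported_associations] as the true simulated effects for
#' TC, TG and HDL, with the bundled trait summaries.
#'
#' @param model Source model for the true effects (1 or 2).
#' @return An [effect_spec].
#' @export
default_effect_spec <- function(model = 2) {
  rep_assoc <- reported_associations()
  betas <- rep_assoc[rep_assoc$model == model &
                       rep_assoc$trait %in% c("TC", "TG", "HDL") &
                       grepl("^rs", rep_assoc$rsid),
                     c("rsid", "trait", "beta")]
  effect_spec(betas)
}

#' Simulate lipid phenotypes under the additive model
#'
#' For each of TC, TG and HDL a standardized latent trait is built as the
#' sum of per-allele effects times dosage, plus any covariate terms, plus
#' Normal noise with variance chosen so the latent variance is 1. Normal
#' traits are rescaled to (mean, SD); log traits are exponentiated from
#' log(GM) + log(GSD) x latent. VLDL-C is TG/5 exactly and LDL-C comes from
#' the per-person Friedewald equation, so the derived-trait identities hold
#' by construction. Missing dosages contribute their expected value
#' (2 x observed allele frequency) to the genetic component.
#'
#' @param G Dosage matrix from [simulate_genotypes] (may contain `NA`).
#' @param covariates Covariate `data.frame` from [simulate_covariates].
#' @param spec An [effect_spec].
#' @param seed Optional integer seed.
#' @return `covariates` with lipid columns `tc`, `tg`, `hdl`, `ldl`, `vldl`
#'   (mg/dL) appended.
#' @export
simulate_phenotypes <- function(G, covariates, spec = default_effect_spec(),
                                seed = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  G <- as.matrix(G)
  n <- nrow(G)
  if (nrow(covariates) != n) stop("G and covariates disagree on sample count")
  Gfill <- G
  if (anyNA(Gfill)) {
    for (j in seq_len(ncol(Gfill))) {
      miss <- is.na(Gfill[, j])
      if (any(miss)) Gfill[miss, j] <- mean(Gfill[!miss, j])
    }
  }
  cohort <- covariates
  latent <- list()
  for (tr in c("TC", "TG", "HDL")) {
    b <- spec$betas[spec$betas$trait == tr, ]
    b <- b[b$rsid %in% colnames(Gfill), ]
    genetic <- if (nrow(b) > 0) {
      drop(Gfill[, b$rsid, drop = FALSE] %*% b$beta)
    } else {
      numeric(n)
    }
    fixed <- genetic
    ce <- spec$covariate_effects[[tr]]
    if (!is.null(ce)) {
      for (cv in names(ce)) {
        col <- covariates[[cv]]
        if (is.null(col)) stop("missing covariate column: ", cv)
        fixed <- fixed + ce[[cv]] * as.numeric(col)
      }
    }
    rsd <- spec$residual_sd
    resid_sd <- if (is.null(rsd)) {
      sqrt(max(1 - stats::var(fixed), 0.05))
    } else if (!is.null(names(rsd))) {
      if (is.na(rsd[tr])) sqrt(max(1 - stats::var(fixed), 0.05)) else rsd[[tr]]
    } else {
      rsd
    }
    z <- fixed - mean(fixed) + stats::rnorm(n, 0, resid_sd)
    latent[[tr]] <- z
  }
  ts <- spec$trait_summaries
  to_scale <- function(z, s) {
    if (s$scale == "normal") pmax(s$mean + s$sd * z, 1) else exp(log(s$gm) + log(s$gsd) * z)
  }
  cohort$tc <- to_scale(latent$TC, ts$TC)
  cohort$tg <- to_scale(latent$TG, ts$TG)
  cohort$hdl <- to_scale(latent$HDL, ts$HDL)
  cohort$vldl <- vldl_from_tg(cohort$tg)
  cohort$ldl <- as.numeric(friedewald_ldl(cohort$tc, cohort$hdl, cohort$tg))
  cohort
}

#' Mask genotypes at random to emulate an imperfect call rate
#'
#' Each genotype is independently set to `NA` with probability
#' 1 - `call_rate`.
#'
#' @param G Dosage matrix.
#' @param call_rate Fraction of calls retained, in (0, 1].
#' @param seed Optional integer seed.
#' @return `G` with missing entries.
#' @export
apply_missingness <- function(G, call_rate, seed = NULL) {
  if (call_rate <= 0 || call_rate > 1) {
    stop("apply_missingness: call_rate must be in (0, 1]")
  }
  if (call_rate == 1) return(G)
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(stats::runif(length(G)) > call_rate, nrow = nrow(G))
  G[mask] <- NA
  G
}

#' Simulate a complete study cohort
#'
#' Convenience wrapper chaining [simulate_covariates], [simulate_genotypes]
#' (with site-specific MAFs), [simulate_phenotypes] and [apply_missingness].
#' Defaults reproduce the emulated study's conditions: n = 2,117, the bundled
#' 12-variant panel, the published fully adjusted effect sizes as truth, and
#' a 95% call rate.
#'
#' @param panel A [variant_panel].
#' @param n Cohort size.
#' @param profile Covariate profile (see [default_cohort_profile]).
#' @param spec An [effect_spec].
#' @param call_rate Genotype call rate in (0, 1].
#' @param seed Integer seed governing every random draw.
#' @return List with `genotypes` (dosage matrix with missingness), `cohort`
#'   (covariates + lipids) and `panel`.
#' @export
simulate_cohort <- function(panel = lipid_variant_panel(), n = 2117,
                            profile = default_cohort_profile(),
                            spec = default_effect_spec(),
                            call_rate = 0.98, seed = 1L) {
  set.seed(seed)
  covariates <- simulate_covariates(profile, n)
  G <- simulate_genotypes(panel, n, site = covariates$site)
  cohort <- simulate_phenotypes(G, covariates, spec)
  G <- apply_missingness(G, call_rate)
  list(genotypes = G, cohort = cohort, panel = panel)
}
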