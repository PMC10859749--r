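MODIFIERS <- c("gender", "site", "obesity", "fat_intake", "physical_activity")

# Numeric modifier vector and the covariate column it derives from.
build_modifier <- function(cohort, modifier, bmi_threshold = 25) {
  switch(modifier,
    gender = list(m = as.numeric(cohort$gender == "female"), source = "gender"),
    site = list(m = as.numeric(cohort$site == "urban"), source = "site"),
    obesity = list(m = as.numeric(cohort$bmi >= bmi_threshold), source = "bmi"),
    fat_intake = list(m = z_standardize(cohort$fat_intake),
                      source = "fat_intake"),
    physical_activity = list(m = as.numeric(cohort$physical_activity),
                             source = "physical_activity"),
    stop("unknown modifier: ", modifier)
  )
}

#' Stratified association analysis
#'
#' Runs the additive-model fit separately within each level of a stratifying
#' covariate (gender or site), dropping that covariate from the adjustment
#' set. Strata smaller than `min_n` are skipped with a flag.
#'
#' @param G Dosage matrix.
#' @param cohort Cohort `data.frame`.
#' @param panel A [variant_panel].
#' @param trait Trait label.
#' @param stratum_var `"gender"` or `"site"`.
#' @param model Adjustment model (default 2, fully adjusted).
#' @param min_n Minimum stratum size (default 100).
#' @param transform Trait transform rule (see [prepare_trait]).
#' @return `data.frame` of association rows with a `stratum` column; skipped
#'   strata appear with `note = "stratum_too_small"`.
#' @export
stratified_association <- function(G, cohort, panel, trait,
                                   stratum_var = c("gender", "site"),
                                   model = 2, min_n = 100,
                                   transform = "auto") {
  stratum_var <- match.arg(stratum_var)
  G <- as.matrix(G)
  panel <- validate_panel(as.data.frame(panel))
  levels_ <- sort(unique(as.character(cohort[[stratum_var]])))
  drop_cov <- function(dat) dat[, setdiff(names(dat), stratum_var), drop = FALSE]
  out <- list()
  for (lev in levels_) {
    keep <- cohort[[stratum_var]] == lev
    if (sum(keep) < min_n) {
      out[[length(out) + 1L]] <- data.frame(
        stratum = lev, rsid = panel$rsid, trait = trait, model = model,
        beta = NA_real_, se = NA_real_, p = NA_real_, n_used = sum(keep),
        note = "stratum_too_small", stringsAsFactors = FALSE)
      next
    }
    sub <- droplevels(drop_cov(cohort[keep, , drop = FALSE]))
    z <- prepare_trait(sub, trait, transform = transform)
    cov_sub <- sub
    # the stratifier is constant within the stratum; fit without it
    for (v in intersect(panel$rsid, colnames(G))) {
      res <- fit_additive_model_drop(z, G[keep, v], cov_sub, model,
                                     drop = stratum_var)
      out[[length(out) + 1L]] <- cbind(
        data.frame(stratum = lev, rsid = v, trait = trait, model = model,
                   stringsAsFactors = FALSE),
        res)
    }
  }
  do.call(rbind, out)
}

# fit_additive_model with named covariates removed from the model's set.
fit_additive_model_drop <- function(trait_z, dosage, covariates, model, drop) {
  cols <- setdiff(model_covariates(model), drop)
  cv <- covariates[, intersect(cols, names(covariates)), drop = FALSE]
  dat <- data.frame(.y = as.numeric(trait_z), .dosage = as.numeric(dosage))
  if (ncol(cv) > 0) {
    for (nm in c("gender", "site")) {
      if (nm %in% names(cv)) cv[[nm]] <- factor(cv[[nm]])
    }
    dat <- cbind(dat, cv)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$.dosage)) < 2L) {
    return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                      n_used = nrow(dat), note = "monomorphic",
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  data.frame(beta = cf[".dosage", "Estimate"],
             se = cf[".dosage", "Std. Error"],
             p = cf[".dosage", "Pr(>|t|)"],
             n_used = nrow(dat), note = "", stringsAsFactors = FALSE)
}

#' SNP x modifier interaction test
#'
#' OLS of the standardized trait on dosage, modifier, their product, and the
#' fully adjusted covariate set; the reported estimate is the product-term
#' coefficient only. Modifiers: `gender` (female = 1), `site` (urban = 1),
#' `obesity` (indicator BMI >= `bmi_threshold`, default 25 kg/m^2 reflecting
#' Asian-Indian cut-offs), `fat_intake` (z-standardized continuous),
#' `physical_activity` (ordinal 0-3). The covariate the modifier derives
#' from is dropped from the adjustment set to avoid collinearity with the
#' modifier main effect.
#'
#' @param dosage Minor-allele dosages.
#' @param cohort Cohort `data.frame`.
#' @param trait Trait label.
#' @param modifier One of `"gender"`, `"site"`, `"obesity"`, `"fat_intake"`,
#'   `"physical_activity"`.
#' @param model Adjustment model for the covariate set (default 2).
#' @param bmi_threshold BMI cut-off defining obesity.
#' @param transform Trait transform rule.
#' @return One-row `data.frame`: `modifier`, interaction `beta`, `se`, `p`,
#'   main-effect estimates `beta_dosage` and `beta_modifier`, `n_used`.
#' @export
interaction_test <- function(dosage, cohort, trait, modifier, model = 2,
                             bmi_threshold = 25, transform = "auto") {
  modifier <- match.arg(modifier, MODIFIERS)
  mod <- build_modifier(cohort, modifier, bmi_threshold)
  if (length(unique(mod$m[!is.na(mod$m)])) < 2L) {
    stop("modifier '", modifier, "' is constant in this cohort")
  }
  z <- prepare_trait(cohort, trait, transform = transform)
  cols <- setdiff(model_covariates(model), c(mod$source))
  cv <- cohort[, intersect(cols, names(cohort)), drop = FALSE]
  for (nm in c("gender", "site")) {
    if (nm %in% names(cv)) cv[[nm]] <- factor(cv[[nm]])
  }
  dat <- cbind(data.frame(.y = as.numeric(z), .dosage = as.numeric(dosage),
                          .modifier = mod$m), cv)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- stats::lm(.y ~ .dosage * .modifier + ., data = dat)
  cf <- summary(fit)$coefficients
  term <- ".dosage:.modifier"
  if (!term %in% rownames(cf)) {
    stop("interaction term collinear with main effects")
  }
  data.frame(modifier = modifier,
             beta = cf[term, "Estimate"],
             se = cf[term, "Std. Error"],
             p = cf[term, "Pr(>|t|)"],
             beta_dosage = cf[".dosage", "Estimate"],
             beta_modifier = cf[".modifier", "Estimate"],
             n_used = nrow(dat), stringsAsFactors = FALSE)
}

#' Interaction screen over variants and modifiers
#'
#' Applies [interaction_test] to every (variant, modifier) pair for a trait.
#' No multiplicity correction is applied, mirroring the validation design;
#' the number of tests performed is attached as attribute `"n_tests"`.
#'
#' @param G Dosage matrix.
#' @param cohort Cohort `data.frame`.
#' @param panel A [variant_panel].
#' @param trait Trait label.
#' @param modifiers Modifiers to screen (default all five).
#' @inheritParams interaction_test
#' @return `data.frame` with one row per (rsid, modifier).
#' @export
interaction_screen <- function(G, cohort, panel, trait,
                               modifiers = MODIFIERS, model = 2,
                               bmi_threshold = 25, transform = "auto") {
  G <- as.matrix(G)
  panel <- validate_panel(as.data.frame(panel))
  out <- list()
  for (v in intersect(panel$rsid, colnames(G))) {
    for (md in modifiers) {
      row <- interaction_test(G[, v], cohort, trait, md, model,
                              bmi_threshold, transform)
      out[[length(out) + 1L]] <- cbind(
        data.frame(rsid = v, trait = trait, stringsAsFactors = FALSE), row)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_tests") <- nrow(res)
  res
}
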