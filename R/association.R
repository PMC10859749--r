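TRAIT_COLUMNS <- c(TC = "tc", TG = "tg", HDL = "hdl", LDL = "ldl", VLDL = "vldl")

# Traits fitted on the log scale by the study's published choice.
LOG_TRAITS <- c("TG", "VLDL")

#' Covariate sets of the two adjustment models
#'
#' Model 1 is the minimal adjustment (age, gender, site); Model 2 adds fat
#' intake, physical activity (ordinal 0-3), BMI, alcohol, smoking,
#' hypertension and diabetes. Model 1's covariates are a subset of Model 2's.
#'
#' @param model 1 or 2.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model) {
  m1 <- c("age", "gender", "site")
  switch(as.character(model),
         "1" = m1,
         "2" = c(m1, "fat_intake", "physical_activity", "bmi",
                 "alcohol", "smoking", "hypertension", "diabetes"),
         stop("model must be 1 or 2"))
}

#' Prepare a lipid trait for association analysis
#'
#' Looks up the trait column, applies the natural-log transform when the
#' sample skewness exceeds `skew_threshold` (TG and VLDL under the default
#' calibration; forceable per trait), then z-standardizes.
#'
#' @param cohort Cohort `data.frame` with lipid columns `tc`, `tg`, `hdl`,
#'   `ldl`, `vldl` in mg/dL.
#' @param trait One of `"TC"`, `"TG"`, `"HDL"`, `"LDL"`, `"VLDL"`.
#' @param transform `"auto"` (skewness rule), `"log"` or `"none"`.
#' @param skew_threshold Skewness cut-off for the automatic rule.
#' @return z-scored trait vector with attribute `"transformed"`.
#' @export
prepare_trait <- function(cohort, trait, transform = "auto",
                          skew_threshold = 1) {
  col <- TRAIT_COLUMNS[[match.arg(trait, names(TRAIT_COLUMNS))]]
  x <- cohort[[col]]
  if (is.null(x)) stop("cohort lacks trait column: ", col)
  lt <- log_transform_if_skewed(
    x, skew_threshold = skew_threshold,
    force = if (identical(transform, "auto")) NULL else transform
  )
  z <- z_standardize(lt$values)
  attr(z, "transformed") <- lt$transformed
  z
}

#' Additive-model association of one variant with one trait
#'
#' Ordinary least squares of a standardized trait on the per-person
#' minor-allele dosage (0/1/2) plus the covariates of the chosen adjustment
#' model, on complete cases. The reported `beta` is the dosage coefficient in
#' trait-SD units per allele; the p-value comes from the t reference with
#' residual degrees of freedom. Factors are indicator-coded; physical
#' activity enters as an ordinal 0-3 score.
#'
#' A monomorphic dosage cannot be fitted: the result row is returned with
#' `NA` estimates and `note = "monomorphic"`.
#'
#' @param trait_z Standardized trait values (may contain `NA`).
#' @param dosage Minor-allele dosages in \{0, 1, 2, NA\}.
#' @param covariates Covariate `data.frame` (or `NULL` for the crude model).
#' @param model Adjustment model 1 or 2, selecting columns via
#'   [model_covariates]; ignored when `covariates` is `NULL`.
#' @return One-row `data.frame`: `beta`, `se`, `p`, `n_used`, `note`.
#' @export
fit_additive_model <- function(trait_z, dosage, covariates = NULL, model = 2) {
  dat <- data.frame(.y = as.numeric(trait_z), .dosage = as.numeric(dosage))
  if (!is.null(covariates)) {
    cols <- model_covariates(model)
    miss <- setdiff(cols, names(covariates))
    if (length(miss) > 0) stop("covariates lack columns: ",
                               paste(miss, collapse = ", "))
    cv <- covariates[, cols, drop = FALSE]
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
  if (nrow(dat) <= ncol(dat) + 1L) {
    stop("fit_additive_model: too few complete cases for the design")
  }
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  data.frame(beta = cf[".dosage", "Estimate"],
             se = cf[".dosage", "Std. Error"],
             p = cf[".dosage", "Pr(>|t|)"],
             n_used = nrow(dat), note = "",
             stringsAsFactors = FALSE)
}

#' Run the association panel: every variant x trait x model
#'
#' Produces one association row per combination, in deterministic order
#' (panel order x trait order x model order). Traits are prepared once per
#' (trait, transform) via [prepare_trait].
#'
#' @param G Dosage matrix (samples x variants; `NA` = uncalled).
#' @param cohort Cohort `data.frame` with lipid and covariate columns.
#' @param panel A [variant_panel]; only its variants present in `G` are fit.
#' @param traits Trait labels to analyse.
#' @param models Adjustment models to fit.
#' @param transform Per-trait transform rule passed to [prepare_trait]:
#'   `"auto"` or a named character vector like `c(TG = "log")`.
#' @return `data.frame` with columns `rsid`, `trait`, `model`, `beta`, `se`,
#'   `p`, `n_used`, `note`.
#' @export
run_panel <- function(G, cohort, panel, traits = names(TRAIT_COLUMNS),
                      models = c(1, 2), transform = "auto") {
  G <- as.matrix(G)
  panel <- validate_panel(as.data.frame(panel))
  rsids <- intersect(panel$rsid, colnames(G))
  traits <- match.arg(traits, names(TRAIT_COLUMNS), several.ok = TRUE)
  zs <- lapply(stats::setNames(traits, traits), function(tr) {
    tf <- if (length(transform) == 1L && is.null(names(transform))) {
      transform
    } else {
      if (is.na(transform[tr])) "auto" else transform[[tr]]
    }
    prepare_trait(cohort, tr, transform = tf)
  })
  out <- list()
  for (v in rsids) {
    for (tr in traits) {
      for (m in models) {
        res <- fit_additive_model(zs[[tr]], G[, v], cohort, model = m)
        out[[length(out) + 1L]] <- cbind(
          data.frame(rsid = v, trait = tr, model = m,
                     stringsAsFactors = FALSE),
          res)
      }
    }
  }
  do.call(rbind, out)
}
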