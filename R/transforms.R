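#' Friedewald estimate of LDL cholesterol
#'
#' LDL-C = TC - HDL-C - TG/5 with all quantities in mg/dL. The equation is
#' invalid at high triglycerides; values at or above `tg_ceiling` (default
#' 400 mg/dL) yield `NA` and are flagged in the `"invalid"` attribute.
#' Non-positive derived LDL-C is likewise flagged.
#'
#' @param tc,hdl,tg Total cholesterol, HDL-C and triglycerides in mg/dL;
#'   recycled to a common length. All must be positive.
#' @param tg_ceiling Triglyceride validity ceiling in mg/dL.
#' @return Numeric vector of LDL-C (mg/dL), `NA` where invalid, with a
#'   logical attribute `"invalid"` marking the excluded entries.
#' @examples
#' friedewald_ldl(200, 50, 100)  # 130
#' @export
friedewald_ldl <- function(tc, hdl, tg, tg_ceiling = 400) {
  n <- max(length(tc), length(hdl), length(tg))
  tc <- rep_len(tc, n); hdl <- rep_len(hdl, n); tg <- rep_len(tg, n)
  ok <- !is.na(tc) & !is.na(hdl) & !is.na(tg)
  if (any(tc[ok] <= 0) || any(hdl[ok] <= 0) || any(tg[ok] <= 0)) {
    stop("friedewald_ldl: all lipid inputs must be positive")
  }
  ldl <- tc - hdl - tg / 5
  invalid <- ok & (tg >= tg_ceiling | ldl <= 0)
  ldl[invalid] <- NA_real_
  attr(ldl, "invalid") <- invalid
  ldl
}

#' VLDL cholesterol from triglycerides
#'
#' The Friedewald convention VLDL-C = TG/5 (mg/dL).
#'
#' @param tg Triglycerides in mg/dL, positive.
#' @return VLDL-C in mg/dL.
#' @export
vldl_from_tg <- function(tg) {
  if (any(tg[!is.na(tg)] <= 0)) stop("vldl_from_tg: tg must be positive")
  tg / 5
}

#' Sample skewness (method-of-moments)
#'
#' @param x Numeric vector; `NA`s dropped.
#' @return The third standardized moment m3 / m2^(3/2).
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Log-transform a trait if its distribution is right-skewed
#'
#' Applies the natural-log transform when the sample skewness exceeds
#' `skew_threshold` (or when forced), recording the decision. This mirrors
#' the usual lipid-trait practice where triglycerides and VLDL-C are
#' log-normal while the cholesterol fractions are near-normal.
#'
#' @param x Numeric values; must be strictly positive if the transform fires.
#' @param skew_threshold Skewness above which the log transform is applied.
#' @param force `NULL` for the automatic rule, otherwise `"log"` or `"none"`.
#' @return List with `values` (possibly transformed) and `transformed`
#'   (logical flag).
#' @export
log_transform_if_skewed <- function(x, skew_threshold = 1, force = NULL) {
  do_log <- if (is.null(force)) {
    sample_skewness(x) > skew_threshold
  } else {
    force <- match.arg(force, c("log", "none"))
    force == "log"
  }
  if (do_log) {
    if (any(x[!is.na(x)] <= 0)) {
      stop("log transform triggered but values are not all positive")
    }
    list(values = log(x), transformed = TRUE)
  } else {
    list(values = x, transformed = FALSE)
  }
}

#' z-standardize a vector
#'
#' Centers and scales to sample mean 0 and sample SD 1 (n - 1 denominator),
#' ignoring `NA`s (which are preserved in place).
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return z-scores of `x`.
#' @export
z_standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("z_standardize: input is constant")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Summarize a trait on its analysis scale
#'
#' @param trait Trait label (e.g. "TC", "TG").
#' @param scale `"normal"` (summarized by arithmetic mean/SD) or `"log"`
#'   (geometric mean and geometric SD, natural logs).
#' @param mean,sd Mean and SD in mg/dL (normal scale).
#' @param gm,gsd Geometric mean (mg/dL) and geometric SD (dimensionless > 1).
#' @return A list of class `trait_summary`.
#' @export
trait_summary <- function(trait, scale = c("normal", "log"),
                          mean = NULL, sd = NULL, gm = NULL, gsd = NULL) {
  scale <- match.arg(scale)
  if (scale == "normal") {
    stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  } else {
    stopifnot(is.numeric(gm), is.numeric(gsd), gm > 0, gsd > 1)
  }
  structure(list(trait = trait, scale = scale, mean = mean, sd = sd,
                 gm = gm, gsd = gsd),
            class = "trait_summary")
}

#' Estimate a trait_summary from data
#'
#' @param x Positive trait values (mg/dL).
#' @inheritParams trait_summary
#' @return A [trait_summary].
#' @export
summarize_trait <- function(x, trait = "trait", scale = c("normal", "log")) {
  scale <- match.arg(scale)
  x <- x[!is.na(x)]
  if (scale == "normal") {
    trait_summary(trait, "normal", mean = mean(x), sd = stats::sd(x))
  } else {
    lx <- log(x)
    trait_summary(trait, "log", gm = exp(mean(lx)), gsd = exp(stats::sd(lx)))
  }
}

#' Default trait summaries for the emulated cohort
#'
#' Cohort-level lipid distributions: TC 183.68 (40.35), HDL-C 46.97 (12.26),
#' LDL-C 108.10 (33.13) mg/dL as mean (SD); TG geometric mean 125.96 with
#' geometric SD 1.60, and VLDL-C = TG/5 so geometric mean 25.19 with the same
#' geometric SD.
#'
#' @return Named list of [trait_summary] objects for TC, TG, HDL, LDL, VLDL.
#' @export
default_trait_summaries <- function() {
  list(
    TC   = trait_summary("TC", "normal", mean = 183.68, sd = 40.35),
    TG   = trait_summary("TG", "log", gm = 125.96, gsd = 1.60),
    HDL  = trait_summary("HDL", "normal", mean = 46.97, sd = 12.26),
    LDL  = trait_summary("LDL", "normal", mean = 108.10, sd = 33.13),
    VLDL = trait_summary("VLDL", "log", gm = 25.19, gsd = 1.60)
  )
}

#' Convert a standardized effect back to interpretable units
#'
#' Association models are fitted on z-standardized (possibly log) traits, so
#' coefficients are in trait-SD units. For a normal-scale trait the per-unit
#' effect in mg/dL is `beta_std * SD`. For a log-scale trait one z-unit is
#' one log-SD, so the per-unit effect is the multiplicative fold-change
#' `GSD^beta_std = exp(beta_std * log(GSD))`; it is returned as a
#' fold-change, not an additive mg/dL difference.
#'
#' @param beta_std Effect per unit exposure on the z-scale.
#' @param summary A [trait_summary] for the trait on its fitted scale.
#' @return Named number: `mg_per_dl` for normal traits, `fold_change` for
#'   log traits.
#' @examples
#' effect_in_original_units(0.21, trait_summary("TG", "log", gm = 125.96, gsd = 1.6))
#' @export
effect_in_original_units <- function(beta_std, summary) {
  if (!inherits(summary, "trait_summary")) {
    stop("summary must be a trait_summary")
  }
  if (summary$scale == "normal") {
    c(mg_per_dl = beta_std * summary$sd)
  } else {
    c(fold_change = exp(beta_std * log(summary$gsd)))
  }
}
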