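#' Dual-significance variant selection
#'
#' A variant enters a trait's risk score only if it is associated with that
#' trait at `alpha` in both adjustment models (minimal and fully adjusted).
#' Variants are returned in the order of `panel` when supplied, else in the
#' order they first appear in `results`.
#'
#' @param results Association table with columns `rsid`, `trait`, `model`,
#'   `p` (e.g. from [run_panel] or [reported_associations]).
#' @param trait Trait label.
#' @param alpha Per-test significance level (no multiplicity correction, as
#'   the candidates are established loci under validation).
#' @param panel Optional [variant_panel] fixing the output order.
#' @return Character vector of rsIDs.
#' @export
select_validated_variants <- function(results, trait, alpha = 0.05,
                                      panel = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  rows <- results[results$trait == trait & grepl("^rs", results$rsid), ]
  if (!all(c(1, 2) %in% rows$model)) {
    stop("results must contain both models for trait ", trait)
  }
  sig <- function(m) unique(rows$rsid[rows$model == m & !is.na(rows$p) &
                                        rows$p < alpha])
  hits <- intersect(sig(1), sig(2))
  ord <- if (!is.null(panel)) panel$rsid else unique(rows$rsid)
  ord[ord %in% hits]
}

#' Orient variants to their risk alleles and extract weights
#'
#' The counted (risk) allele for a variant is the allele whose per-allele
#' effect moves the trait in the adverse direction: an increase for TC, TG,
#' LDL and VLDL, a decrease for HDL. When the minor-allele effect points the
#' other way the major allele is counted instead (its dosage is 2 minus the
#' minor-allele dosage). Weights are the absolute effect sizes from the
#' chosen source model, so they are strictly positive.
#'
#' @param results Association table (`rsid`, `trait`, `model`, `beta`, `p`).
#' @param trait Trait label.
#' @param variants rsIDs to orient (e.g. from [select_validated_variants]).
#' @param weight_model Model whose estimates provide the weights (default 2,
#'   the fully adjusted model).
#' @param adverse_direction `"increase"` or `"decrease"`; defaults by trait
#'   (decrease for HDL).
#' @return A `data.frame` of class `score_definition`: `rsid`,
#'   `counted_is_minor`, `weight`, with attributes `trait` and
#'   `weight_model`.
#' @export
orient_risk_alleles <- function(results, trait, variants,
                                weight_model = 2,
                                adverse_direction = NULL) {
  if (is.null(adverse_direction)) {
    adverse_direction <- if (trait == "HDL") "decrease" else "increase"
  }
  adverse_direction <- match.arg(adverse_direction, c("increase", "decrease"))
  sign_adverse <- if (adverse_direction == "increase") 1 else -1
  rows <- results[results$trait == trait & results$model == weight_model, ]
  idx <- match(variants, rows$rsid)
  if (anyNA(idx)) {
    stop("no ", trait, " model-", weight_model, " estimate for: ",
         paste(variants[is.na(idx)], collapse = ", "))
  }
  beta <- rows$beta[idx]
  if (any(is.na(beta) | beta == 0)) {
    stop("risk-allele orientation undefined for zero/missing effects: ",
         paste(variants[is.na(beta) | beta == 0], collapse = ", "))
  }
  def <- data.frame(rsid = variants,
                    counted_is_minor = sign(beta) == sign_adverse,
                    weight = abs(beta),
                    stringsAsFactors = FALSE)
  structure(def, trait = trait, weight_model = weight_model,
            class = c("score_definition", "data.frame"))
}

# Dosages of the counted allele for every score variant; missing genotypes
# imputed at the expected oriented dosage (2 x counted-allele frequency)
# unless impute_missing = FALSE, which leaves them NA.
oriented_dosages <- function(G, definition, impute_missing = TRUE) {
  G <- as.matrix(G)
  miss <- setdiff(definition$rsid, colnames(G))
  if (length(miss) > 0) stop("genotypes lack score variants: ",
                             paste(miss, collapse = ", "))
  D <- G[, definition$rsid, drop = FALSE]
  for (k in seq_len(nrow(definition))) {
    d <- D[, k]
    if (!definition$counted_is_minor[k]) d <- 2 - d
    if (impute_missing && anyNA(d)) {
      freq <- mean(d, na.rm = TRUE) / 2
      d[is.na(d)] <- 2 * freq
    }
    D[, k] <- d
  }
  D
}

#' Unweighted genetic risk score
#'
#' Sum of counted (risk) allele dosages over the score's variants; lies in
#' \[0, 2i\] for i variants and is integer-valued where no genotypes are
#' missing. Missing genotypes are imputed at the expected oriented dosage by
#' default; a person missing every score genotype gets `NA`.
#'
#' @param G Dosage matrix (minor-allele coding; the orientation in
#'   `definition` is applied internally).
#' @param definition A `score_definition` from [orient_risk_alleles].
#' @param impute_missing Impute missing genotypes at the expected dosage
#'   (default) instead of complete-case `NA` propagation.
#' @return Per-person numeric score.
#' @export
compute_ugrs <- function(G, definition, impute_missing = TRUE) {
  if (nrow(definition) == 0L) stop("empty score definition")
  D <- oriented_dosages(G, definition, impute_missing)
  score <- rowSums(D)
  all_missing <- rowSums(!is.na(as.matrix(G)[, definition$rsid, drop = FALSE])) == 0
  score[all_missing] <- NA_real_
  score
}

#' Weighted genetic risk score
#'
#' The weighted sum w1 a1 + ... + wi ai of counted-allele dosages, with
#' strictly positive weights (absolute effect sizes from the source model).
#' The raw sum is reported by default; `rescale = "count_normalized"`
#' multiplies by i / sum(w) so the score is on the allele-count scale.
#'
#' @inheritParams compute_ugrs
#' @param rescale `"none"` (raw weighted sum) or `"count_normalized"`.
#' @return Per-person numeric score.
#' @export
compute_wgrs <- function(G, definition, impute_missing = TRUE,
                         rescale = c("none", "count_normalized")) {
  rescale <- match.arg(rescale)
  if (nrow(definition) == 0L) stop("empty score definition")
  if (any(definition$weight <= 0)) stop("weights must be strictly positive")
  D <- oriented_dosages(G, definition, impute_missing)
  score <- drop(D %*% definition$weight)
  if (rescale == "count_normalized") {
    score <- score * nrow(definition) / sum(definition$weight)
  }
  all_missing <- rowSums(!is.na(as.matrix(G)[, definition$rsid, drop = FALSE])) == 0
  score[all_missing] <- NA_real_
  score
}

#' Association of a risk score with its trait
#'
#' OLS of the standardized trait on the raw score plus the minimal (Model 1)
#' covariates: the per-unit-score effect in trait-SD units.
#'
#' @param score Per-person score from [compute_ugrs] or [compute_wgrs].
#' @param cohort Cohort `data.frame`.
#' @param trait Trait label.
#' @param model Adjustment model for the score regression (default 1).
#' @param transform Trait transform rule (see [prepare_trait]).
#' @return One-row association `data.frame` (`beta`, `se`, `p`, `n_used`).
#' @export
grs_association <- function(score, cohort, trait, model = 1,
                            transform = "auto") {
  z <- prepare_trait(cohort, trait, transform = transform)
  fit_additive_model(z, score, cohort, model = model)
}

#' Build both risk scores for a trait and test their associations
#'
#' Chains [select_validated_variants], [orient_risk_alleles],
#' [compute_ugrs]/[compute_wgrs] and [grs_association].
#'
#' @param G Dosage matrix.
#' @param cohort Cohort `data.frame`.
#' @param results Association table supplying selection p-values and weights.
#' @param trait Trait label.
#' @param alpha Dual-significance selection level.
#' @param weight_model Source model for weights.
#' @param panel Optional [variant_panel] fixing variant order.
#' @return List with `definition`, `ugrs`, `wgrs`, `assoc_ugrs`,
#'   `assoc_wgrs`.
#' @export
build_risk_scores <- function(G, cohort, results, trait, alpha = 0.05,
                              weight_model = 2, panel = NULL) {
  variants <- select_validated_variants(results, trait, alpha, panel)
  if (length(variants) == 0L) {
    return(list(definition = NULL, ugrs = NULL, wgrs = NULL,
                assoc_ugrs = NULL, assoc_wgrs = NULL))
  }
  def <- orient_risk_alleles(results, trait, variants, weight_model)
  ugrs <- compute_ugrs(G, def)
  wgrs <- compute_wgrs(G, def)
  list(definition = def,
       ugrs = ugrs, wgrs = wgrs,
       assoc_ugrs = grs_association(ugrs, cohort, trait),
       assoc_wgrs = grs_association(wgrs, cohort, trait))
}
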