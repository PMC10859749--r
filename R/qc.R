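#' Genotype counts for one variant
#'
#' @param n_major_hom,n_het,n_minor_hom Non-negative genotype class counts
#'   (major homozygote, heterozygote, minor homozygote).
#' @param n_missing Number of uncalled genotypes.
#' @return A list of class `genotype_counts`.
#' @export
genotype_counts <- function(n_major_hom, n_het, n_minor_hom, n_missing = 0L) {
  counts <- c(n_major_hom, n_het, n_minor_hom, n_missing)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  structure(list(n_major_hom = as.integer(n_major_hom),
                 n_het = as.integer(n_het),
                 n_minor_hom = as.integer(n_minor_hom),
                 n_missing = as.integer(n_missing)),
            class = "genotype_counts")
}

#' Tabulate dosages into genotype counts
#'
#' @param dosage Vector of minor-allele dosages in \{0, 1, 2, NA\}.
#' @return A [genotype_counts].
#' @export
count_genotypes <- function(dosage) {
  ok <- !is.na(dosage)
  if (any(!dosage[ok] %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  genotype_counts(sum(dosage[ok] == 0), sum(dosage[ok] == 1),
                  sum(dosage[ok] == 2), sum(!ok))
}

#' Per-variant call rate
#'
#' @param G Genotype matrix (samples x variants) of dosages with `NA` for
#'   uncalled genotypes.
#' @return Named vector of observed/total fractions per variant.
#' @export
call_rate <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) == 0L) stop("call_rate: genotype matrix has no samples")
  colMeans(!is.na(G))
}

#' Estimate the minor allele frequency from genotype counts
#'
#' The allele frequency of the designated "minor" allele is
#' (2 n_minor_hom + n_het) / (2 n_observed). If it exceeds 0.5 the allele
#' labels are swapped and the frequency reflected, so the returned `maf` is
#' always in \[0, 0.5\].
#'
#' @param counts A [genotype_counts] (or a dosage vector, which is tabulated
#'   first).
#' @return List with `maf` and `swapped` (`TRUE` if the labelled minor allele
#'   was in fact the major one).
#' @export
estimate_maf <- function(counts) {
  if (!inherits(counts, "genotype_counts")) counts <- count_genotypes(counts)
  n_obs <- counts$n_major_hom + counts$n_het + counts$n_minor_hom
  if (n_obs < 1L) stop("estimate_maf: no observed genotypes")
  f <- (2 * counts$n_minor_hom + counts$n_het) / (2 * n_obs)
  if (f > 0.5) list(maf = 1 - f, swapped = TRUE) else list(maf = f, swapped = FALSE)
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts against the HWE expectations p^2, 2pq, q^2
#' at the estimated allele frequency. `"chisq"` is the 1-df Pearson test;
#' `"exact"` is the heterozygote-conditional exact test (full enumeration of
#' heterozygote counts given the allele counts), optionally with the mid-p
#' adjustment. `"auto"` (default) uses the exact test when the expected
#' minor-homozygote count is below 5 and the chi-square test otherwise.
#'
#' A monomorphic variant carries no HWE information: the test returns
#' statistic 0, p = 1 and `monomorphic = TRUE`.
#'
#' @param counts A [genotype_counts] or dosage vector.
#' @param method `"auto"`, `"chisq"` or `"exact"`.
#' @param midp Use the mid-p variant of the exact test.
#' @return List with `statistic` (chi-square statistic, `NA` for the exact
#'   test), `p`, `method` used, and `monomorphic` flag.
#' @export
hwe_test <- function(counts, method = c("auto", "chisq", "exact"), midp = FALSE) {
  method <- match.arg(method)
  if (!inherits(counts, "genotype_counts")) counts <- count_genotypes(counts)
  n_obs <- counts$n_major_hom + counts$n_het + counts$n_minor_hom
  if (n_obs < 1L) stop("hwe_test: no observed genotypes")
  n_minor <- 2L * counts$n_minor_hom + counts$n_het
  if (n_minor == 0L || n_minor == 2L * n_obs) {
    warning("monomorphic variant: HWE test not informative")
    return(list(statistic = 0, p = 1, method = method, monomorphic = TRUE))
  }
  p_minor <- n_minor / (2 * n_obs)
  if (method == "auto") {
    method <- if (n_obs * p_minor^2 < 5) "exact" else "chisq"
  }
  if (method == "chisq") {
    expected <- n_obs * c((1 - p_minor)^2, 2 * p_minor * (1 - p_minor), p_minor^2)
    observed <- c(counts$n_major_hom, counts$n_het, counts$n_minor_hom)
    stat <- sum((observed - expected)^2 / expected)
    list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chisq", monomorphic = FALSE)
  } else {
    p <- hwe_exact_p(counts$n_het, n_minor, n_obs, midp = midp)
    list(statistic = NA_real_, p = p, method = "exact", monomorphic = FALSE)
  }
}

# Exact HWE p-value conditional on the minor-allele count: enumerate every
# feasible heterozygote count, compute its probability under random mating
# via log factorials, and sum probabilities <= that of the observed count.
hwe_exact_p <- function(n_het_obs, n_minor, n_obs, midp = FALSE) {
  hets <- seq.int(n_minor %% 2L, min(n_minor, 2L * n_obs - n_minor), by = 2L)
  log_prob <- vapply(hets, function(h) {
    n_mm <- (n_minor - h) / 2            # minor homozygotes
    n_MM <- n_obs - n_mm - h             # major homozygotes
    h * log(2) + lfactorial(n_obs) -
      (lfactorial(n_MM) + lfactorial(h) + lfactorial(n_mm)) +
      lfactorial(n_minor) + lfactorial(2 * n_obs - n_minor) -
      lfactorial(2 * n_obs)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  p_obs <- prob[hets == n_het_obs]
  tol <- 1e-12
  p <- sum(prob[prob <= p_obs + tol])
  if (midp) p <- p - 0.5 * p_obs
  min(1, p)
}

#' Sidak-corrected significance threshold
#'
#' For m independent tests, the per-test level preserving family-wise level
#' `alpha` is 1 - (1 - alpha)^(1/m).
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of tests, >= 1.
#' @return Per-test threshold.
#' @examples
#' sidak_threshold(0.05, 12)  # 0.004265...
#' @export
sidak_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("sidak_threshold: m must be >= 1")
  1 - (1 - alpha)^(1 / m)
}

#' HWE p-value threshold used by the source study
#'
#' The study filtered variants at a Sidak-corrected HWE significance of
#' p < 0.0018. That literal value is not the Sidak threshold for 12 tests at
#' alpha = 0.05 (which is 0.00427, see [sidak_threshold]); it is exposed here
#' verbatim so the printed filter can be reproduced without guessing the
#' family size behind it.
#'
#' @return 0.0018
#' @export
paper_hwe_threshold <- function() 0.0018

#' Variant-level QC filter
#'
#' A variant is retained iff its call rate is at least `min_call_rate` and
#' its HWE p-value is at least `hwe_threshold` in every configured stratum
#' (by default rural, urban and the combined sample, each tested separately).
#'
#' @param G Genotype matrix (samples x variants), `NA` = uncalled.
#' @param panel A [variant_panel] covering the columns of `G`.
#' @param site Optional per-sample site labels (`"rural"`/`"urban"`); when
#'   `NULL`, only the combined stratum is tested.
#' @param min_call_rate Minimum acceptable call rate.
#' @param hwe_threshold Minimum acceptable HWE p-value
#'   (default [paper_hwe_threshold()]).
#' @param method HWE test method passed to [hwe_test].
#' @return List with `retained` (character vector of rsIDs, panel order) and
#'   `report` (per-variant data.frame: call rate, MAF, per-stratum HWE p,
#'   pass flags).
#' @export
qc_filter <- function(G, panel, site = NULL, min_call_rate = 0.95,
                      hwe_threshold = paper_hwe_threshold(),
                      method = "auto") {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            hwe_threshold > 0, hwe_threshold <= 1)
  G <- as.matrix(G)
  panel <- validate_panel(as.data.frame(panel))
  rsids <- intersect(panel$rsid, colnames(G))
  if (length(rsids) == 0L) stop("qc_filter: no panel variants found in G")
  strata <- list(combined = rep(TRUE, nrow(G)))
  if (!is.null(site)) {
    site <- as.character(site)
    for (s in c("rural", "urban")) strata[[s]] <- site == s
  }
  cr <- call_rate(G[, rsids, drop = FALSE])
  rows <- lapply(rsids, function(v) {
    maf <- tryCatch(estimate_maf(G[, v])$maf, error = function(e) NA_real_)
    hwe_p <- vapply(strata, function(keep) {
      suppressWarnings(hwe_test(G[keep, v], method = method)$p)
    }, numeric(1))
    data.frame(rsid = v, call_rate = cr[[v]], maf = maf,
               t(stats::setNames(hwe_p, paste0("hwe_p_", names(strata)))),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$pass_call_rate <- report$call_rate >= min_call_rate
  hwe_cols <- grep("^hwe_p_", names(report))
  report$pass_hwe <- apply(report[, hwe_cols, drop = FALSE] >= hwe_threshold, 1, all)
  report$retained <- report$pass_call_rate & report$pass_hwe
  list(retained = report$rsid[report$retained], report = report)
}
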