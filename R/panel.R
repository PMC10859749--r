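#' Construct and validate a variant panel
#'
#' A variant panel describes the candidate SNPs under study: identifiers,
#' locus labels, alleles under the minor-allele convention, and site-specific
#' minor allele frequencies. Frequencies must lie in \[0, 0.5\]: the "minor"
#' allele is by definition the less common one.
#'
#' @param rsid Character vector of unique SNP identifiers.
#' @param locus Gene or locus labels (informational).
#' @param chrom_pos Character "chr:pos" strings (informational).
#' @param major_allele,minor_allele Single-character allele codes.
#' @param maf_combined,maf_rural,maf_urban Minor allele frequencies in
#'   \[0, 0.5\] for the combined sample and for each recruitment site.
#' @param risk_is_major Logical; `TRUE` where the trait-raising (risk) allele
#'   is the major allele rather than the minor one.
#' @return A `data.frame` of class `variant_panel`, one row per variant.
#' @examples
#' variant_panel("rs174546", "FADS1", "11:61802358", "C", "T",
#'               0.14, 0.12, 0.15)
#' @export
variant_panel <- function(rsid, locus = NA_character_, chrom_pos = NA_character_,
                          major_allele = NA_character_, minor_allele = NA_character_,
                          maf_combined, maf_rural = maf_combined,
                          maf_urban = maf_combined, risk_is_major = FALSE) {
  panel <- data.frame(
    rsid = as.character(rsid),
    locus = locus,
    chrom_pos = chrom_pos,
    major_allele = major_allele,
    minor_allele = minor_allele,
    maf_combined = as.numeric(maf_combined),
    maf_rural = as.numeric(maf_rural),
    maf_urban = as.numeric(maf_urban),
    risk_is_major = as.logical(risk_is_major),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  required <- c("rsid", "maf_combined", "maf_rural", "maf_urban")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0L) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$rsid)) {
    stop("rsid values must be unique within a panel")
  }
  mafs <- unlist(panel[, c("maf_combined", "maf_rural", "maf_urban")])
  if (any(!is.finite(mafs)) || any(mafs < 0) || any(mafs > 0.5)) {
    stop("all MAFs must lie in [0, 0.5] (minor-allele convention)")
  }
  if (is.null(panel$risk_is_major)) panel$risk_is_major <- FALSE
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

#' The bundled 12-variant lipid panel
#'
#' Twelve established GWAS variants for serum lipid levels, with the minor
#' alleles and site-specific minor allele frequencies observed in a North
#' Indian rural-urban cohort (n = 2,117). `risk_is_major` flags the three
#' variants whose lipid-raising allele is the major allele.
#'
#' @return A [variant_panel] with 12 rows.
#' @export
lipid_variant_panel <- function() {
  path <- system.file("extdata", "variant_panel.csv", package = "lipidgrs",
                      mustWork = TRUE)
  validate_panel(read_panel(path))
}

#' Read / write a variant panel CSV
#'
#' @param path Path to a CSV with at least columns `rsid`, `maf_combined`,
#'   `maf_rural`, `maf_urban`; allele and locus columns are carried through.
#' @return `read_panel()` returns a validated [variant_panel];
#'   `write_panel()` returns `path` invisibly.
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(panel)
}

#' @rdname read_panel
#' @param panel A [variant_panel].
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published per-variant association estimates for the bundled panel
#'
#' The standardized per-minor-allele regression estimates (beta, SE, p) for
#' the 12 bundled variants against five lipid traits under two covariate
#' models, plus the unweighted (`GRS`) and weighted (`wGRS`) risk-score rows,
#' as reported for the source cohort. These serve as inputs for
#' dual-significance selection, risk-score weights, and as true effects for
#' the synthetic-cohort generator. p-values reported only as "< 0.001" are
#' stored as 0.0005; they are only ever compared against thresholds well
#' above that.
#'
#' @return A `data.frame` with columns `rsid`, `trait`
#'   (`TC`/`TG`/`HDL`/`LDL`/`VLDL`), `model` (1 or 2), `beta`, `se`, `p`.
#' @export
reported_associations <- function() {
  path <- system.file("extdata", "reported_associations.csv",
                      package = "lipidgrs", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
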