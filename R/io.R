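#' Read genotypes from CSV or VCF
#'
#' The canonical interchange format is a CSV with a `sample_id` column and
#' one column per rsID holding minor-allele dosages in \{0, 1, 2\} or empty/NA
#' for uncalled genotypes. VCF is supported read-only (requires the `vcfR`
#' package): GT fields are converted to alternate-allele dosage and then
#' re-oriented so the counted allele is the minor allele by observed
#' frequency; multi-allelic records are skipped with a warning.
#'
#' @param path File path.
#' @param format `"csv"` or `"vcf"` (default guessed from the extension).
#' @return Numeric matrix samples x variants with sample IDs as row names,
#'   rsIDs as column names and `NA` for missing calls.
#' @export
read_genotypes <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv"
  }
  format <- match.arg(format, c("csv", "vcf"))
  if (format == "vcf") return(read_genotypes_vcf(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(tab)) stop("genotype CSV needs a sample_id column")
  ids <- tab$sample_id
  tab$sample_id <- NULL
  if (anyDuplicated(names(tab))) stop("rsIDs must be unique")
  G <- as.matrix(tab)
  storage.mode(G) <- "numeric"
  bad <- which(!is.na(G) & !(G %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("dosage outside {0,1,2,NA} at row %d, column '%s'",
                 bad[1, 1], colnames(G)[bad[1, 2]]))
  }
  rownames(G) <- ids
  G
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  ids <- fix$ID[!multi]
  alt_dose <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  G <- t(apply(gt, 1, function(row) vapply(row, alt_dose, numeric(1))))
  rownames(G) <- ids
  G <- t(G)
  # orient each variant to its minor allele by observed frequency
  for (j in seq_len(ncol(G))) {
    f <- mean(G[, j], na.rm = TRUE) / 2
    if (!is.na(f) && f > 0.5) G[, j] <- 2 - G[, j]
  }
  G
}

#' @rdname read_genotypes
#' @param G Dosage matrix (samples x variants).
#' @export
write_genotypes <- function(G, path) {
  G <- as.matrix(G)
  ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(G)))
  out <- data.frame(sample_id = ids, G, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a phenotype + covariate table
#'
#' @param path CSV path. Lipids are expected in mg/dL columns `tc`, `tg`,
#'   `hdl`, `ldl`, `vldl`; covariates as produced by [simulate_covariates].
#' @return `read_cohort()` returns a `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_cohort
#' @param cohort Cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' QC thresholds (call rate 0.95, HWE p [paper_hwe_threshold()]), the
#' skewness rule and per-trait overrides, the two covariate models,
#' dual-significance selection level, weight-source model, score rescaling,
#' obesity BMI cut-off, and the seed for any simulation.
#'
#' @param genotypes,phenotypes,panel Input file paths (CSV); when all three
#'   are `NULL`, [run_pipeline] simulates a cohort with [simulate_cohort].
#' @param out_dir Output directory for the report bundle.
#' @param n Cohort size when simulating.
#' @param call_rate Simulated genotype call rate.
#' @param min_call_rate,hwe_threshold,hwe_method QC settings.
#' @param skew_threshold,transform Trait transformation settings.
#' @param traits,models Association surfaces to fit.
#' @param alpha Dual-significance selection level.
#' @param weight_model Source model for wGRS weights.
#' @param rescale wGRS rescaling mode.
#' @param bmi_threshold Obesity cut-off (kg/m^2).
#' @param modifiers Interaction modifiers to screen.
#' @param precision `"machine"` (full precision) or `"report"` (2 dp, the
#'   presentation rounding).
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, phenotypes = NULL, panel = NULL,
                            out_dir = tempfile("lipidgrs_run_"),
                            n = 2117, call_rate = 0.98,
                            min_call_rate = 0.95,
                            hwe_threshold = paper_hwe_threshold(),
                            hwe_method = "auto",
                            skew_threshold = 1, transform = "auto",
                            traits = c("TC", "TG", "HDL", "LDL", "VLDL"),
                            models = c(1, 2), alpha = 0.05,
                            weight_model = 2,
                            rescale = "none", bmi_threshold = 25,
                            modifiers = MODIFIERS,
                            precision = c("machine", "report"),
                            seed = 1L) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1,
            hwe_threshold > 0, hwe_threshold <= 1,
            alpha > 0, alpha < 1, bmi_threshold > 0)
  precision <- match.arg(precision)
  structure(as.list(environment()), class = "pipeline_config")
}

format_report <- function(df, precision) {
  if (precision == "machine") return(df)
  num <- vapply(df, is.numeric, logical(1)) &
    !(names(df) %in% c("model", "n_used"))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "f", digits = 2))
  df
}

write_tsv <- function(df, path, precision = "machine") {
  utils::write.table(format_report(df, precision), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains the stages simulate/load -> QC -> transform -> associate -> risk
#' scores -> interactions and writes a report bundle to `config$out_dir`:
#' `cohort_summary.tsv` (trait summaries), `qc_report.tsv`,
#' `associations.tsv` (per-variant rows plus GRS/wGRS rows per trait),
#' `interactions.tsv`, and `run_log.txt` recording the seed, package version
#' and every threshold. Any stage failure aborts with the stage name;
#' outputs written before the failure are left in place.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory results (`qc`,
#'   `associations`, `scores`, `interactions`, paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- stage("input", {
    if (is.null(config$genotypes) && is.null(config$phenotypes)) {
      simulate_cohort(n = config$n, call_rate = config$call_rate,
                      seed = config$seed)
    } else {
      list(genotypes = read_genotypes(config$genotypes),
           cohort = read_cohort(config$phenotypes),
           panel = if (is.null(config$panel)) lipid_variant_panel()
                   else read_panel(config$panel))
    }
  })

  qc <- stage("qc", qc_filter(dat$genotypes, dat$panel,
                              site = dat$cohort$site,
                              min_call_rate = config$min_call_rate,
                              hwe_threshold = config$hwe_threshold,
                              method = config$hwe_method))
  write_tsv(qc$report, file.path(config$out_dir, "qc_report.tsv"))

  summaries <- stage("transform", {
    lapply(stats::setNames(config$traits, config$traits), function(tr) {
      x <- dat$cohort[[TRAIT_COLUMNS[[tr]]]]
      if (is.null(x)) stop("phenotypes lack trait column: ", TRAIT_COLUMNS[[tr]])
      sk <- sample_skewness(x)
      scale <- if (sk > config$skew_threshold) "log" else "normal"
      summarize_trait(x, tr, scale)
    })
  })
  summary_df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(trait = s$trait, scale = s$scale,
               mean = if (s$scale == "normal") s$mean else s$gm,
               sd = if (s$scale == "normal") s$sd else s$gsd,
               stringsAsFactors = FALSE)
  }))
  write_tsv(summary_df, file.path(config$out_dir, "cohort_summary.tsv"),
            config$precision)

  keep <- qc$retained
  panel_kept <- dat$panel[dat$panel$rsid %in% keep, , drop = FALSE]
  assoc <- stage("associate", run_panel(dat$genotypes, dat$cohort, panel_kept,
                                        traits = config$traits,
                                        models = config$models,
                                        transform = config$transform))

  scores <- stage("grs", {
    lapply(stats::setNames(config$traits, config$traits), function(tr) {
      build_risk_scores(dat$genotypes, dat$cohort, assoc, tr,
                        alpha = config$alpha,
                        weight_model = config$weight_model,
                        panel = panel_kept)
    })
  })
  score_rows <- list()
  for (tr in config$traits) {
    s <- scores[[tr]]
    if (is.null(s$definition)) next
    labels <- c(ugrs = "GRS", wgrs = "wGRS")
    for (kind in names(labels)) {
      a <- s[[paste0("assoc_", kind)]]
      score_rows[[length(score_rows) + 1L]] <- cbind(
        data.frame(rsid = labels[[kind]], trait = tr, model = 1,
                   stringsAsFactors = FALSE),
        a)
    }
  }
  assoc_out <- rbind(assoc, do.call(rbind, score_rows))
  write_tsv(assoc_out, file.path(config$out_dir, "associations.tsv"),
            config$precision)

  inter <- stage("interact", {
    do.call(rbind, lapply(config$traits, function(tr) {
      interaction_screen(dat$genotypes, dat$cohort, panel_kept, tr,
                         modifiers = config$modifiers,
                         bmi_threshold = config$bmi_threshold,
                         transform = config$transform)
    }))
  })
  write_tsv(inter, file.path(config$out_dir, "interactions.tsv"),
            config$precision)

  log_lines <- c(
    paste0("lipidgrs ", as.character(utils::packageVersion("lipidgrs"))),
    paste0("seed: ", config$seed),
    paste0("n: ", nrow(dat$cohort)),
    paste0("min_call_rate: ", config$min_call_rate),
    paste0("hwe_threshold: ", config$hwe_threshold),
    paste0("skew_threshold: ", config$skew_threshold),
    paste0("selection_alpha: ", config$alpha),
    paste0("weight_model: ", config$weight_model),
    paste0("bmi_threshold: ", config$bmi_threshold),
    paste0("variants_retained: ", paste(keep, collapse = ","))
  )
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(qc = qc, associations = assoc_out, scores = scores,
                 interactions = inter, summaries = summary_df,
                 out_dir = config$out_dir))
}
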