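#' GRCh38 primary-assembly chromosome lengths
#'
#' Lengths in bp of chr1-chr22, chrX, chrY on the GRCh38/hg38 primary
#' assembly — the default denominator set for LOH genome fractions and the
#' whole-chromosome exclusion in the HRD-LOH score.
#'
#' @return Named numeric vector of 24 lengths.
#' @export
hg38_chrom_lengths <- function() {
  c(chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622,
    chr12 = 133275309, chr13 = 114364328, chr14 = 107043718,
    chr15 = 101991189, chr16 = 90338345, chr17 = 83257441,
    chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415)
}

.default_case_config <- function() {
  list(dialect = "tsv", case_id = NULL, zero_based_segments = FALSE,
       callable_mb = 3300, include_non_snv = TRUE, tmb_high_threshold = 175,
       chrom_lengths = hg38_chrom_lengths(), genome_length_bp = NULL,
       min_len_bp = 15e6, hrd_high_threshold = 10L,
       tol = 1e-8, max_iter = 10000L, prune = TRUE, prune_threshold = 0.01,
       uv_cutoff = 0.5, apobec_cutoff = 0.10, sbs3_bands = c(0.05, 0.20),
       msi_status = "unknown")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("run_case [", name, "]: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full per-case analysis
#'
#' Deterministic composition of the pipeline stages for one case: read
#' variants and segments, build the SBS96 catalog, refit signatures by EM,
#' band the etiology, and summarise burden and copy number. Any stage error
#' is re-raised with the stage name.
#'
#' @param variant_file Variant table (TSV dialect or VCF per
#'   `config$dialect`).
#' @param segment_file Allele-specific segment TSV, or `NULL` to skip the
#'   CNV block.
#' @param signature_file COSMIC-layout signature TSV, or a
#'   `signature_matrix`.
#' @param config Named list overriding defaults: `dialect`, `case_id`,
#'   `zero_based_segments`, `callable_mb`, `include_non_snv`,
#'   `tmb_high_threshold`, `chrom_lengths`, `genome_length_bp`,
#'   `min_len_bp`, `hrd_high_threshold`, `tol`, `max_iter`, `prune`,
#'   `prune_threshold`, `uv_cutoff`, `apobec_cutoff`, `sbs3_bands`,
#'   `msi_status`.
#' @return List of class `case_report` with `case_id`, `burden`,
#'   `exposures`, `etiology`, `cnv` (or `NULL`), `msi_status`.
#' @export
run_case <- function(variant_file, segment_file, signature_file,
                     config = list()) {
  cfg <- utils::modifyList(.default_case_config(), config)
  variants <- .stage("read_variants",
    read_variant_table(variant_file, dialect = cfg$dialect,
                       case_id = cfg$case_id))
  case_id <- cfg$case_id
  if (is.null(case_id)) {
    ids <- unique(variants$case_id)
    case_id <- if (length(ids) == 1L) ids else NA_character_
  }
  signatures <- .stage("read_signatures",
    if (inherits(signature_file, "signature_matrix")) signature_file
    else read_signature_matrix(signature_file))
  cat96 <- .stage("build_catalog", build_catalog(variants, case_id = case_id))
  fit <- .stage("em_fit",
    em_fit(cat96, signatures, tol = cfg$tol, max_iter = cfg$max_iter,
           prune_threshold = cfg$prune_threshold, prune = cfg$prune))
  etiology <- .stage("etiology",
    etiology_summary(fit, uv_cutoff = cfg$uv_cutoff,
                     apobec_cutoff = cfg$apobec_cutoff,
                     sbs3_bands = cfg$sbs3_bands))
  burden <- .stage("burden",
    burden_summary(variants, callable_mb = cfg$callable_mb,
                   include_non_snv = cfg$include_non_snv,
                   tmb_high_threshold = cfg$tmb_high_threshold))
  cnv <- NULL
  if (!is.null(segment_file)) {
    segments <- .stage("read_segments",
      read_segments(segment_file, zero_based = cfg$zero_based_segments))
    gl <- if (is.null(cfg$genome_length_bp)) sum(cfg$chrom_lengths)
          else cfg$genome_length_bp
    cnv <- .stage("cnv_summary",
      cnv_case_summary(segments, chrom_lengths = cfg$chrom_lengths,
                       genome_length_bp = gl, min_len_bp = cfg$min_len_bp,
                       high_threshold = cfg$hrd_high_threshold))
  }
  structure(
    list(case_id = case_id, burden = burden, exposures = fit,
         etiology = etiology, cnv = cnv, msi_status = cfg$msi_status),
    class = "case_report"
  )
}

#' @export
print.case_report <- function(x, ...) {
  cat("case_report [", x$case_id, "]\n", sep = "")
  cat("  mutations:", x$burden$total_mutations,
      "(", x$burden$pathogenic_per_exome, "pathogenic ); WGS-TMB",
      round(x$burden$wgs_tmb_per_mb, 1), "/Mb",
      if (x$burden$tmb_high) "[high TMB]", "\n")
  cat("  UV:", x$etiology$uv_band,
      sprintf("(share %.2f);", x$etiology$uv_share),
      "APOBEC:", x$etiology$apobec_flag, "; HRD band:", x$etiology$hrd_band, "\n")
  if (!is.null(x$cnv)) {
    cat("  CNV:", x$cnv$n_total, "events; LOH",
        sprintf("%.1f%%;", x$cnv$loh_percent),
        "HRD-LOH score", x$cnv$hrd_loh_score,
        if (x$cnv$hrd_high) "[high]", "\n")
  }
  cat("  MSI status:", x$msi_status, "\n")
  invisible(x)
}

#' Serialize a case report to JSON
#'
#' The layout follows the schema shipped at
#' `system.file("schema", "case_report.schema.json", package = "melwgs")`.
#'
#' @param report A `case_report`.
#' @param path Output JSON path.
#' @export
write_case_report <- function(report, path) {
  x <- list(
    case_id = report$case_id,
    burden = report$burden[c("total_mutations", "pathogenic_per_exome",
                             "wgs_tmb_per_mb", "panel_tmb_equiv", "tmb_high")],
    exposures = as.list(report$exposures$proportions),
    fit = list(log_likelihood = report$exposures$log_likelihood,
               n_iterations = report$exposures$n_iterations,
               converged = report$exposures$converged,
               pruned = report$exposures$pruned),
    etiology = report$etiology[c("uv_share", "uv_band", "apobec_flag",
                                 "hrd_band")],
    cnv = if (is.null(report$cnv)) NULL else
      report$cnv[c("n_total", "n_amplification", "n_trisomy_gain",
                   "n_homozygous_loss", "n_loh", "loh_percent",
                   "hrd_loh_score", "hrd_high")],
    msi_status = report$msi_status
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Check a case report against the shipped JSON schema
#'
#' Structural validation: every field the schema marks required must be
#' present (recursively for the nested blocks).
#'
#' @param report A `case_report` or a path to a report JSON.
#' @return `TRUE` invisibly, or an error naming the missing field.
#' @export
validate_case_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(
    system.file("schema", "case_report.schema.json", package = "melwgs"))
  check <- function(obj, sch, where) {
    for (f in unlist(sch$required)) {
      if (!f %in% names(obj)) {
        stop("validate_case_report: missing field ", where, f)
      }
      sub <- sch$properties[[f]]
      if (!is.null(sub$required) && !is.null(obj[[f]])) {
        check(obj[[f]], sub, paste0(where, f, "."))
      }
    }
  }
  check(report, schema, "")
  invisible(TRUE)
}

#' Run the cohort-level analysis
#'
#' Builds the gene-by-case mutation matrix, the recurrence list, incidence
#' percents, the fold-based over-representation list against a reference
#' cohort, and the per-gene clonality table.
#'
#' @param variants Variant data frame covering all cases (rows carry
#'   `case_id`), or a list of per-case variant data frames.
#' @param reference_percents Named numeric vector of reference incidence
#'   percents per gene (e.g. TCGA-SKCM), or `NULL` to skip the
#'   over-representation filter.
#' @param cases Ordered case ids; defaults to those present.
#' @param min_cases_exclusive,fold Thresholds for [recurrent_genes()] and
#'   [overrepresented_genes()].
#' @return List of class `cohort_report`: `matrix` (the `cohort_matrix`),
#'   `incidence` (data frame gene/n_mutated/n_cases/percent),
#'   `recurrent`, `overrepresented`, `clonality` (per-gene table).
#' @export
run_cohort <- function(variants, reference_percents = NULL, cases = NULL,
                       min_cases_exclusive = 2L, fold = 2.0) {
  if (is.list(variants) && !is.data.frame(variants)) {
    variants <- do.call(rbind, variants)
  }
  if (is.null(cases)) cases <- unique(variants$case_id)
  if (length(cases) < 1L) stop("run_cohort: need at least one case")
  m <- build_matrix(variants, cases, tcga_percent = reference_percents)
  n_mut <- rowSums(m$mutated)
  incidence <- data.frame(
    gene = m$genes, n_mutated = as.integer(n_mut),
    n_cases = length(cases),
    percent = incidence_percent(n_mut, length(cases)),
    stringsAsFactors = FALSE
  )
  over <- if (is.null(reference_percents)) character() else
    overrepresented_genes(m, fold = fold)
  structure(
    list(matrix = m, incidence = incidence,
         recurrent = recurrent_genes(m, min_cases_exclusive),
         overrepresented = over,
         clonality = clonality_table(variants)),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report:", length(x$matrix$cases), "cases,",
      length(x$matrix$genes), "mutated genes\n")
  cat("  recurrent (>2 cases):", length(x$recurrent), "genes\n")
  cat("  over-represented vs reference:", length(x$overrepresented),
      "genes\n")
  invisible(x)
}
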