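#' Reference tables from a published seven-case triple-wild-type melanoma
#' cohort
#'
#' The package ships, as plain TSV, the per-case burden summary and the
#' top-mutated-gene recurrence table (with TCGA-SKCM reference incidence
#' percents) reported for a whole-genome-sequenced cohort of seven cutaneous
#' melanomas lacking BRAF/RAS/KIT driver mutations. They serve as worked
#' inputs for the cohort statistics and as reference points for the burden
#' arithmetic.
#'
#' `twm_top_genes()` returns columns `gene`, `cases_mutated`, `n_cases`,
#' `tcga_percent`; `twm_case_burden()` returns `case_id`,
#' `total_mutations`, `pathogenic_per_exome`, `wgs_tmb_per_mb`, `uv_band`,
#' `msi`, `n_cnv`, `loh_percent`, `hrd_band`.
#'
#' @return A data frame.
#' @export
twm_top_genes <- function() {
  utils::read.delim(system.file("extdata", "twm_top_genes.tsv",
                                package = "melwgs"),
                    stringsAsFactors = FALSE)
}

#' @rdname twm_top_genes
#' @export
twm_case_burden <- function() {
  utils::read.delim(system.file("extdata", "twm_case_burden.tsv",
                                package = "melwgs"),
                    stringsAsFactors = FALSE)
}

#' Cohort matrix for the reference melanoma cohort, with decoy genes
#'
#' Realizes the reference top-gene table as a 7-case binary matrix via
#' [cohort_matrix_from_counts()], optionally padded with decoy genes mutated
#' in at most 2 cases (below the recurrence cut) to exercise the filters.
#'
#' @param n_decoys Number of decoy genes appended (case counts cycling
#'   0, 1, 2).
#' @return A `cohort_matrix` carrying the TCGA reference percents.
#' @export
twm_reference_matrix <- function(n_decoys = 10L) {
  top <- twm_top_genes()
  genes <- top$gene
  counts <- top$cases_mutated
  ref <- stats::setNames(top$tcga_percent, top$gene)
  if (n_decoys > 0L) {
    decoys <- paste0("DECOY", seq_len(n_decoys))
    genes <- c(genes, decoys)
    counts <- c(counts, rep_len(c(0L, 1L, 2L), n_decoys))
    ref <- c(ref, stats::setNames(rep(50, n_decoys), decoys))
  }
  cohort_matrix_from_counts(genes, counts, n_cases = top$n_cases[1],
                            tcga_percent = ref)
}
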