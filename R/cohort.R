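#' Build a gene-by-case binary mutation matrix
#'
#' @param variants Variant data frame; rows with empty gene symbols are
#'   ignored. Every `case_id` must appear in `cases`.
#' @param cases Ordered case identifiers defining the cohort (cases without
#'   variants are allowed and yield zero columns).
#' @param tcga_percent Optional named numeric vector of reference incidence
#'   percents per gene (e.g. TCGA-SKCM), consumed by
#'   [overrepresented_genes()].
#' @return Object of class `cohort_matrix`: list with `genes`, `cases`,
#'   `mutated` (0/1 matrix genes x cases) and `tcga_percent`.
#' @export
build_matrix <- function(variants, cases, tcga_percent = NULL) {
  if (length(cases) == 0L) stop("build_matrix: cases must be non-empty")
  v <- variants[!is.na(variants$gene) & variants$gene != "", , drop = FALSE]
  unknown <- setdiff(unique(v$case_id), cases)
  if (length(unknown)) {
    stop("build_matrix: variant with unknown case id: ", unknown[1])
  }
  genes <- unique(v$gene)
  mat <- matrix(0L, nrow = length(genes), ncol = length(cases),
                dimnames = list(genes, cases))
  if (nrow(v) > 0L) {
    mat[cbind(match(v$gene, genes), match(v$case_id, cases))] <- 1L
  }
  cohort_matrix(mat, tcga_percent = tcga_percent)
}

#' Construct a cohort matrix from an existing 0/1 matrix
#'
#' @param mutated 0/1 integer matrix with gene rownames and case colnames.
#' @param tcga_percent Optional named reference percents.
#' @return A `cohort_matrix`.
#' @export
cohort_matrix <- function(mutated, tcga_percent = NULL) {
  stopifnot(is.matrix(mutated), nrow(mutated) == 0L || !is.null(rownames(mutated)),
            !is.null(colnames(mutated)), all(mutated %in% c(0L, 1L)))
  structure(
    list(genes = if (is.null(rownames(mutated))) character() else rownames(mutated),
         cases = colnames(mutated),
         mutated = mutated, tcga_percent = tcga_percent),
    class = "cohort_matrix"
  )
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", length(x$genes), "genes x", length(x$cases),
      "cases;", sum(x$mutated), "mutated cells\n")
  invisible(x)
}

#' Cohort incidence as a rounded integer percent
#'
#' Rounds half-up on the percent scale, matching how small-cohort incidence
#' fractions are conventionally printed (6/7 -> 86, 4/7 -> 57, 3/7 -> 43).
#'
#' @param n_mutated Cases carrying the gene (0..n_cases).
#' @param n_cases Cohort size (>= 1).
#' @return Integer percent, vectorized.
#' @export
incidence_percent <- function(n_mutated, n_cases) {
  if (any(n_cases < 1)) stop("incidence_percent: n_cases must be >= 1")
  if (any(n_mutated < 0 | n_mutated > n_cases)) {
    stop("incidence_percent: n_mutated must lie in [0, n_cases]")
  }
  as.integer(floor(100 * n_mutated / n_cases + 0.5))
}

#' Genes recurrently mutated across the cohort
#'
#' @param matrix A `cohort_matrix`.
#' @param min_cases_exclusive Keep genes mutated in strictly more than this
#'   many cases (default 2).
#' @return Gene symbols in matrix row order.
#' @export
recurrent_genes <- function(matrix, min_cases_exclusive = 2L) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  matrix$genes[rowSums(matrix$mutated) > min_cases_exclusive]
}

#' Genes over-represented relative to a reference cohort
#'
#' Compares the cohort incidence — rounded to the integer percent actually
#' displayed, via [incidence_percent()] — against `fold` times the reference
#' percent, keeping genes strictly above. Genes without a reference percent
#' are skipped with a warning.
#'
#' @param matrix A `cohort_matrix` carrying `tcga_percent` (or pass
#'   `tcga_percent` explicitly).
#' @param fold Fold-increase threshold (default 2).
#' @param tcga_percent Named reference percents, overriding the matrix's.
#' @return Gene symbols in matrix row order.
#' @export
overrepresented_genes <- function(matrix, fold = 2.0, tcga_percent = NULL) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  ref <- if (is.null(tcga_percent)) matrix$tcga_percent else tcga_percent
  if (is.null(ref)) stop("overrepresented_genes: no reference percents")
  pct <- incidence_percent(rowSums(matrix$mutated), length(matrix$cases))
  have_ref <- matrix$genes %in% names(ref)
  if (!all(have_ref)) {
    warning("overrepresented_genes: no reference percent for ",
            sum(!have_ref), " gene(s); skipped")
  }
  keep <- have_ref & pct > fold * as.numeric(ref[matrix$genes])
  keep[is.na(keep)] <- FALSE
  matrix$genes[keep]
}

#' Build a cohort matrix from per-gene mutated-case counts
#'
#' Convenience constructor for fixture-style inputs that record, per gene,
#' how many of the cohort's cases carry it (each gene is marked mutated in
#' the first `counts[g]` cases; recurrence and incidence statistics depend
#' only on the counts, not on which cases carry the gene).
#'
#' @param genes Gene symbols.
#' @param counts Mutated-case count per gene.
#' @param n_cases Cohort size.
#' @param tcga_percent Optional named reference percents.
#' @param case_ids Case names; default `case1..caseN`.
#' @return A `cohort_matrix`.
#' @export
cohort_matrix_from_counts <- function(genes, counts, n_cases,
                                      tcga_percent = NULL,
                                      case_ids = paste0("case", seq_len(n_cases))) {
  stopifnot(length(genes) == length(counts), all(counts >= 0),
            all(counts <= n_cases))
  mat <- matrix(0L, nrow = length(genes), ncol = n_cases,
                dimnames = list(genes, case_ids))
  for (i in seq_along(genes)) {
    if (counts[i] > 0L) mat[i, seq_len(counts[i])] <- 1L
  }
  cohort_matrix(mat, tcga_percent = tcga_percent)
}
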