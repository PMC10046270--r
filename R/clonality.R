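#' Tumor-cell fraction of a heterozygous mutation from its VAF
#'
#' Under the heterozygous-diploid, purity-1 model a mutation observed at
#' variant allele fraction `v` is carried by `2 v` of the tumor cells,
#' capped at 1 (a VAF of 50% means every tumor cell carries it).
#' No purity or copy-number correction is applied.
#'
#' @param vaf Variant allele fraction(s) in \[0, 1\].
#' @return `min(2 * vaf, 1)`, vectorized.
#' @export
#' @examples
#' tumor_cell_fraction(0.50)  # 1.0 -- the whole tumor
#' tumor_cell_fraction(0.10)  # 0.2
tumor_cell_fraction <- function(vaf) {
  if (any(is.na(vaf)) || any(vaf < 0 | vaf > 1)) {
    stop("tumor_cell_fraction: vaf must lie in [0, 1]")
  }
  pmin(2 * vaf, 1)
}

#' Classify a mutation's clonality from its VAF
#'
#' Applies the band definitions used for melanoma driver annotation:
#' clonal at VAF >= 50%, polyclonal between 20% and 45% (both inclusive),
#' subclonal below 10%. VAFs falling in the unnamed gaps (10-20% and
#' 45-50%, endpoints per the inequalities above) are reported as
#' `indeterminate` rather than forced into a band.
#'
#' @param vaf Variant allele fraction(s) in \[0, 1\].
#' @return `clonality_call` (or a data frame for vector input) with fields
#'   `vaf`, `tumor_cell_fraction`, `category` in
#'   \{clonal, polyclonal, subclonal, indeterminate\}.
#' @export
#' @examples
#' classify_clonality(c(0.5, 0.3, 0.05, 0.15))$category
classify_clonality <- function(vaf) {
  tcf <- tumor_cell_fraction(vaf)
  category <- ifelse(vaf >= 0.50, "clonal",
              ifelse(vaf >= 0.20 & vaf <= 0.45, "polyclonal",
              ifelse(vaf < 0.10, "subclonal", "indeterminate")))
  out <- data.frame(vaf = vaf, tumor_cell_fraction = tcf,
                    category = category, stringsAsFactors = FALSE)
  class(out) <- c("clonality_call", "data.frame")
  out
}

#' Clonality of a gene in one case (max-VAF rule)
#'
#' A gene is as clonal as its most clonal hit: the gene/case pair is
#' classified by the maximum VAF among its variants.
#'
#' @param variants Variant data frame.
#' @param gene Gene symbol.
#' @param case_id Case identifier.
#' @return A one-row `clonality_call`.
#' @export
gene_clonality <- function(variants, gene, case_id) {
  hit <- variants$gene == gene & variants$case_id == case_id
  if (!any(hit)) {
    stop("gene_clonality: no variant of ", gene, " in case ", case_id)
  }
  classify_clonality(max(variants$vaf[hit]))
}

#' Per-gene, per-case clonality table for a cohort
#'
#' @param variants Variant data frame (possibly multi-case). Rows with empty
#'   gene symbols are ignored.
#' @return Data frame with columns `case_id`, `gene`, `max_vaf`,
#'   `tumor_cell_fraction`, `category`, one row per mutated gene/case pair.
#' @export
clonality_table <- function(variants) {
  v <- variants[!is.na(variants$gene) & variants$gene != "", , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(case_id = character(), gene = character(),
                      max_vaf = numeric(), tumor_cell_fraction = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(vaf ~ case_id + gene, data = v, FUN = max)
  call <- classify_clonality(agg$vaf)
  out <- data.frame(case_id = agg$case_id, gene = agg$gene,
                    max_vaf = agg$vaf,
                    tumor_cell_fraction = call$tumor_cell_fraction,
                    category = call$category, stringsAsFactors = FALSE)
  out[order(out$case_id, out$gene), , drop = FALSE]
}
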