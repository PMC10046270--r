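#' Whole-genome tumor mutational burden in mutations per megabase
#'
#' @param total_mutations Somatic mutation count for the case.
#' @param callable_mb Callable genome size in Mb. Defaults to 3300 Mb, near
#'   the center of per-case callable sizes implied by typical human WGS; pass
#'   the per-case value when known.
#' @return `total_mutations / callable_mb`.
#' @export
compute_wgs_tmb <- function(total_mutations, callable_mb = 3300) {
  if (any(callable_mb <= 0)) stop("compute_wgs_tmb: callable_mb must be > 0")
  if (any(total_mutations < 0)) stop("compute_wgs_tmb: negative mutation count")
  total_mutations / callable_mb
}

#' Convert a WES mutation count to its panel-TMB equivalent
#'
#' Linear conversion anchored at the published correspondence of a
#' 199-mutation whole-exome burden to a panel TMB of 10 m/Mb:
#' `count * 10 / 199`.
#'
#' @param wes_mutation_count Non-negative exome mutation count.
#' @return Panel-TMB equivalent in mutations per megabase.
#' @export
#' @examples
#' wes_to_panel_tmb(199)  # 10
wes_to_panel_tmb <- function(wes_mutation_count) {
  if (any(wes_mutation_count < 0)) {
    stop("wes_to_panel_tmb: negative mutation count")
  }
  wes_mutation_count * (10 / 199)
}

#' Count pathogenic-flagged variants
#'
#' Pathogenicity is an upstream annotation consumed as a flag; this only
#' counts `pathogenic == TRUE` rows.
#'
#' @param variants Variant data frame.
#' @return Integer count.
#' @export
count_pathogenic <- function(variants) {
  sum(variants$pathogenic, na.rm = TRUE)
}

#' High-TMB flag from the per-exome pathogenic mutation count
#'
#' @param pathogenic_per_exome Non-negative count.
#' @param threshold Count above which (strictly) the case is flagged
#'   high-TMB; default 175.
#' @return Logical.
#' @export
flag_tmb_high <- function(pathogenic_per_exome, threshold = 175) {
  if (any(pathogenic_per_exome < 0)) stop("flag_tmb_high: negative count")
  pathogenic_per_exome > threshold
}

#' Per-case mutation burden summary
#'
#' @param variants Variant data frame for one case (SNVs; the `non_snv`
#'   attribute from [read_variant_table()], if present and
#'   `include_non_snv = TRUE`, is added to the total).
#' @param callable_mb Callable genome size in Mb for the WGS-TMB denominator.
#' @param include_non_snv Count retained indel/MNV records in
#'   `total_mutations` (default `TRUE`; the trinucleotide catalog stays
#'   SNV-only either way).
#' @param tmb_high_threshold Passed to [flag_tmb_high()].
#' @return List of class `burden_summary` with `total_mutations`,
#'   `pathogenic_per_exome`, `wgs_tmb_per_mb`, `panel_tmb_equiv`, `tmb_high`.
#' @export
burden_summary <- function(variants, callable_mb = 3300,
                           include_non_snv = TRUE,
                           tmb_high_threshold = 175) {
  total <- nrow(variants)
  non_snv <- attr(variants, "non_snv")
  if (include_non_snv && !is.null(non_snv)) total <- total + nrow(non_snv)
  pathogenic <- count_pathogenic(variants)
  structure(
    list(total_mutations = total,
         pathogenic_per_exome = pathogenic,
         wgs_tmb_per_mb = compute_wgs_tmb(total, callable_mb),
         panel_tmb_equiv = wes_to_panel_tmb(pathogenic),
         tmb_high = flag_tmb_high(pathogenic, tmb_high_threshold)),
    class = "burden_summary"
  )
}
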