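#' Classify allele-specific copy-number segments
#'
#' Assigns each segment one category by integer total (`cn_total`) and minor
#' allele (`cn_minor`) copy number, with the precedence:
#' \describe{
#'   \item{homozygous_loss}{`cn_total == 0`}
#'   \item{loh}{`cn_minor == 0` with `cn_total >= 1` — covers copy-neutral
#'     LOH and hemizygous loss}
#'   \item{trisomy_gain}{`cn_total` 3 or 4 with the minor allele retained}
#'   \item{amplification}{`cn_total >= 5`}
#'   \item{neutral}{diploid heterozygous (`cn_total == 2`, `cn_minor == 1`)}
#' }
#' The thresholds follow common practice for absolute copy-number calls and
#' are deliberately simple; they are the categories a per-case CNV report
#' counts.
#'
#' @param segments Segment data frame (see [read_segments()]).
#' @return Character vector of categories, one per row.
#' @export
classify_segment <- function(segments) {
  with(segments, ifelse(cn_total == 0L, "homozygous_loss",
                 ifelse(cn_minor == 0L, "loh",
                 ifelse(cn_total %in% c(3L, 4L), "trisomy_gain",
                 ifelse(cn_total >= 5L, "amplification", "neutral")))))
}

.loh_granges <- function(segments) {
  loh <- segments[classify_segment(segments) == "loh", , drop = FALSE]
  GenomicRanges::GRanges(loh$chrom,
                         IRanges::IRanges(start = loh$start, end = loh$end))
}

#' Percent of the genome under loss of heterozygosity
#'
#' Sums the lengths of LOH-classified segments (merged first, so overlapping
#' or book-ended pieces are not double-counted) and reports them as a percent
#' of the genome. Segment length is `end - start + 1` (1-based inclusive).
#'
#' @param segments Segment data frame.
#' @param genome_length_bp Total genome length in bp (the denominator).
#' @return LOH percent in \[0, 100\].
#' @export
loh_genome_fraction <- function(segments, genome_length_bp) {
  if (genome_length_bp <= 0) {
    stop("loh_genome_fraction: genome_length_bp must be > 0")
  }
  gr <- GenomicRanges::reduce(.loh_granges(segments))
  100 * sum(as.numeric(GenomicRanges::width(gr))) / genome_length_bp
}

#' HRD-LOH genomic scar score
#'
#' Counts LOH segments longer than `min_len_bp` that do not span their whole
#' chromosome — the LOH scar score used as a marker of homologous
#' recombination deficiency. The defaults (> 15 Mb, sub-chromosomal,
#' high at a score of 10 or more) follow the established genomic-scar
#' definition.
#'
#' @param segments Segment data frame.
#' @param chrom_lengths Named numeric vector mapping every segment chromosome
#'   to its length in bp.
#' @param min_len_bp Minimum LOH segment length (exclusive bound).
#' @param high_threshold Score at or above which `hrd_high` is `TRUE`.
#' @return List with integer `score` and logical `hrd_high`.
#' @export
hrd_loh_score <- function(segments, chrom_lengths, min_len_bp = 15e6,
                          high_threshold = 10L) {
  loh <- segments[classify_segment(segments) == "loh", , drop = FALSE]
  missing <- setdiff(unique(loh$chrom), names(chrom_lengths))
  if (length(missing)) {
    stop("hrd_loh_score: no chromosome length for ", missing[1])
  }
  len <- loh$end - loh$start + 1
  sub_chrom <- len < chrom_lengths[loh$chrom]
  score <- sum(len > min_len_bp & sub_chrom)
  list(score = as.integer(score), hrd_high = score >= high_threshold)
}

#' Per-case copy-number summary
#'
#' Tabulates segment categories, the LOH genome percent, and the HRD-LOH
#' scar score for one case. `n_total` counts non-neutral segments.
#'
#' @param segments Segment data frame.
#' @param chrom_lengths Named chromosome lengths in bp; also supplies the
#'   LOH-percent denominator (their sum) unless `genome_length_bp` is given.
#' @param genome_length_bp Optional explicit LOH-percent denominator.
#' @param min_len_bp,high_threshold Passed to [hrd_loh_score()].
#' @return List of class `cnv_case_summary` with `n_total`,
#'   `n_amplification`, `n_trisomy_gain`, `n_homozygous_loss`, `n_loh`,
#'   `loh_percent`, `hrd_loh_score`, `hrd_high`.
#' @export
cnv_case_summary <- function(segments, chrom_lengths,
                             genome_length_bp = sum(chrom_lengths),
                             min_len_bp = 15e6, high_threshold = 10L) {
  cat_ <- classify_segment(segments)
  hrd <- hrd_loh_score(segments, chrom_lengths, min_len_bp, high_threshold)
  structure(
    list(n_total = sum(cat_ != "neutral"),
         n_amplification = sum(cat_ == "amplification"),
         n_trisomy_gain = sum(cat_ == "trisomy_gain"),
         n_homozygous_loss = sum(cat_ == "homozygous_loss"),
         n_loh = sum(cat_ == "loh"),
         loh_percent = loh_genome_fraction(segments, genome_length_bp),
         hrd_loh_score = hrd$score,
         hrd_high = hrd$hrd_high),
    class = "cnv_case_summary"
  )
}
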