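#' Read a somatic variant table (TSV or VCF)
#'
#' Produces the package's variant data frame: one row per biallelic SNV with
#' columns `case_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `vaf`, `gene`,
#' `pathogenic`, `ctx5`, `ctx3`. Multi-allelic records and non-SNVs (indels,
#' MNVs) are not emitted; non-SNVs are retained in the `non_snv` attribute so
#' burden metrics can optionally include them, and counts of skipped and
#' rejected records are reported on standard error and as attributes.
#'
#' For the VCF dialect the variant allele fraction is taken from the tumor
#' sample's `AF` FORMAT field when present, otherwise computed as alt depth /
#' total depth from `AD`. Records whose VAF falls outside \[0, 1\] are
#' rejected and counted.
#'
#' @param path Input file.
#' @param dialect `"tsv"` (native dialect, header required) or `"vcf"`
#'   (VCF 4.x).
#' @param case_id Case identifier for VCF input (VCFs are per-case); for TSV
#'   input the file's `case_id` column is used.
#' @param tumor_sample For VCF input, the sample column holding tumor allele
#'   fractions; defaults to the first sample.
#' @return Variant data frame with attributes `n_skipped` (non-SNV or
#'   multi-allelic), `n_rejected` (invalid VAF/fields) and `non_snv` (data
#'   frame of skipped indel/MNV records, for burden counting).
#' @seealso [write_variant_table()], [build_catalog()]
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               case_id = NULL, tumor_sample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_variant_table: no such file: ", path)
  if (dialect == "tsv") .read_variants_tsv(path) else
    .read_variants_vcf(path, case_id = case_id, tumor_sample = tumor_sample)
}

.empty_variants <- function() {
  data.frame(case_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), vaf = numeric(),
             gene = character(), pathogenic = logical(),
             ctx5 = character(), ctx3 = character(),
             stringsAsFactors = FALSE)
}

.finish_variants <- function(v, non_snv, n_skipped, n_rejected) {
  rownames(v) <- NULL
  attr(v, "n_skipped") <- n_skipped
  attr(v, "n_rejected") <- n_rejected
  attr(v, "non_snv") <- non_snv
  if (n_skipped + n_rejected > 0L) {
    message("read_variant_table: skipped ", n_skipped,
            " non-SNV/multi-allelic record(s), rejected ", n_rejected,
            " invalid record(s)")
  }
  v
}

.read_variants_tsv <- function(path) {
  # bases like "T" and flags like "true" must not be auto-coerced
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(case_id = "character",
                                         chrom = "character",
                                         pos = "integer",
                                         ref = "character",
                                         alt = "character",
                                         vaf = "numeric",
                                         gene = "character",
                                         pathogenic = "character",
                                         ctx5 = "character",
                                         ctx3 = "character"))
  required <- c("case_id", "chrom", "pos", "ref", "alt", "vaf",
                "gene", "pathogenic", "ctx5", "ctx3")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("read_variant_table: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  if (nrow(df) == 0L) return(.finish_variants(.empty_variants(), .empty_variants(), 0L, 0L))
  df$ref <- toupper(df$ref)
  df$alt <- toupper(df$alt)
  df$ctx5[df$ctx5 %in% c("", ".", "N", "NA")] <- NA_character_
  df$ctx3[df$ctx3 %in% c("", ".", "N", "NA")] <- NA_character_
  df$gene[is.na(df$gene)] <- ""
  df$pathogenic <- as.logical(toupper(df$pathogenic))
  is_snv <- df$ref %in% .BASES & df$alt %in% .BASES & df$ref != df$alt
  non_snv <- df[!is_snv, , drop = FALSE]
  snv <- df[is_snv, , drop = FALSE]
  ok <- !is.na(snv$vaf) & snv$vaf >= 0 & snv$vaf <= 1 &
    !is.na(snv$pos) & snv$pos >= 1L & !is.na(snv$pathogenic)
  .finish_variants(snv[ok, , drop = FALSE], non_snv,
                   n_skipped = nrow(non_snv), n_rejected = sum(!ok))
}

.read_variants_vcf <- function(path, case_id = NULL, tumor_sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(.finish_variants(.empty_variants(), .empty_variants(), 0L, 0L))
  if (is.null(case_id)) case_id <- "case"
  n <- nrow(fix)
  vaf <- rep(NA_real_, n)
  if (ncol(vcf@gt) >= 2L) {
    samples <- colnames(vcf@gt)[-1]
    sm <- if (is.null(tumor_sample)) samples[1] else tumor_sample
    if (!sm %in% samples) stop("read_variant_table: sample not in VCF: ", sm)
    af <- tryCatch(vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE),
                   error = function(e) NULL)
    if (!is.null(af) && any(!is.na(af[, sm]))) {
      vaf <- as.numeric(af[, sm])
    } else {
      ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                     error = function(e) NULL)
      if (!is.null(ad)) {
        parts <- strsplit(as.character(ad[, sm]), ",", fixed = TRUE)
        vaf <- vapply(parts, function(p) {
          d <- suppressWarnings(as.numeric(p))
          if (length(d) < 2L || anyNA(d) || sum(d) == 0) return(NA_real_)
          d[2] / sum(d)
        }, numeric(1))
      }
    }
  }
  df <- data.frame(case_id = case_id, chrom = fix$CHROM,
                   pos = as.integer(fix$POS),
                   ref = toupper(fix$REF), alt = toupper(fix$ALT),
                   vaf = vaf, gene = "", pathogenic = FALSE,
                   ctx5 = NA_character_, ctx3 = NA_character_,
                   stringsAsFactors = FALSE)
  is_snv <- df$ref %in% .BASES & df$alt %in% .BASES & df$ref != df$alt
  non_snv <- df[!is_snv, , drop = FALSE]
  snv <- df[is_snv, , drop = FALSE]
  ok <- !is.na(snv$vaf) & snv$vaf >= 0 & snv$vaf <= 1
  .finish_variants(snv[ok, , drop = FALSE], non_snv,
                   n_skipped = nrow(non_snv), n_rejected = sum(!ok))
}

#' Write a variant data frame in the native TSV dialect
#'
#' Round-trips exactly with [read_variant_table()]'s `"tsv"` dialect; unknown
#' context bases are written as `.`.
#'
#' @param variants Variant data frame.
#' @param path Output file.
#' @export
write_variant_table <- function(variants, path) {
  out <- variants
  out$ctx5[is.na(out$ctx5)] <- "."
  out$ctx3[is.na(out$ctx3)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a signature matrix object
#'
#' @param probs Numeric K x 96 matrix; row k gives signature k's probability
#'   over the 96 channels, in canonical order. Rows must sum to 1 within
#'   `1e-4` (they are renormalized to machine precision).
#' @param signature_ids Character vector of K signature names (e.g.
#'   `"SBS7a"`); defaults to rownames of `probs`.
#' @return Object of class `signature_matrix`: list with `signature_ids`,
#'   `probs` (rows renormalized, dimnames set) and `channel_labels`.
#' @export
signature_matrix <- function(probs, signature_ids = rownames(probs)) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 96L) stop("signature_matrix: need 96 columns")
  if (is.null(signature_ids)) {
    signature_ids <- paste0("S", seq_len(nrow(probs)))
  }
  if (anyDuplicated(signature_ids)) stop("signature_matrix: duplicate signature ids")
  if (any(probs < 0)) stop("signature_matrix: negative probabilities")
  rs <- rowSums(probs)
  off <- abs(rs - 1) > 1e-4
  if (any(off)) {
    stop("signature_matrix: row for ", signature_ids[off][1],
         " sums to ", format(rs[off][1]), ", not 1")
  }
  probs <- probs / rs
  dimnames(probs) <- list(signature_ids, sbs96_channels())
  structure(
    list(signature_ids = signature_ids, probs = probs,
         channel_labels = sbs96_channels()),
    class = "signature_matrix"
  )
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix:", length(x$signature_ids), "signatures x 96 channels (",
      paste(utils::head(x$signature_ids, 5), collapse = ", "),
      if (length(x$signature_ids) > 5) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Read a COSMIC-layout signature probability TSV
#'
#' Expects the COSMIC distribution layout: a `Type` column of 96 channel
#' labels (`"A[C>A]A"`, ...) and one column per signature. Rows are reordered
#' to canonical channel order and the matrix transposed to K x 96. Missing or
#' duplicated channels, or a signature column whose probabilities sum to more
#' than `1e-4` away from 1, are fatal errors naming the offender.
#'
#' @param path Signature TSV.
#' @return A `signature_matrix` with ids in file column order.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  type_col <- names(df)[1]
  channels <- sbs96_channels()
  labels <- df[[type_col]]
  dup <- labels[duplicated(labels)]
  if (length(dup)) stop("read_signature_matrix: duplicated channel ", dup[1])
  absent <- setdiff(channels, labels)
  if (length(absent)) stop("read_signature_matrix: missing channel ", absent[1])
  extra <- setdiff(labels, channels)
  if (length(extra)) stop("read_signature_matrix: unknown channel ", extra[1])
  rownames(df) <- labels
  mat <- t(as.matrix(df[channels, -1, drop = FALSE]))
  signature_matrix(mat, signature_ids = colnames(df)[-1])
}

#' Write a signature matrix in the COSMIC distribution layout
#'
#' @param signatures A `signature_matrix`.
#' @param path Output TSV.
#' @export
write_signature_matrix <- function(signatures, path) {
  df <- data.frame(Type = signatures$channel_labels,
                   t(signatures$probs), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' Expects a TSV with columns `chrom`, `start`, `end`, `cn_total`,
#' `cn_minor`. Coordinates are interpreted as 1-based inclusive; set
#' `zero_based = TRUE` when the upstream segmenter writes 0-based half-open
#' starts (starts are shifted by +1). Rows violating the segment invariants
#' (`start > end`, negative copy number, or minor exceeding the lesser
#' allele, i.e. `cn_minor > cn_total - cn_minor`) are rejected and counted.
#'
#' @param path Segment TSV.
#' @param zero_based Input starts are 0-based (default `FALSE`).
#' @return Data frame of valid segments with attribute `n_rejected`.
#' @export
read_segments <- function(path, zero_based = FALSE) {
  if (!file.exists(path)) stop("read_segments: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "cn_total", "cn_minor")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("read_segments: missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[required]
  df$start <- as.integer(df$start) + if (zero_based) 1L else 0L
  df$end <- as.integer(df$end)
  df$cn_total <- as.integer(df$cn_total)
  df$cn_minor <- as.integer(df$cn_minor)
  ok <- df$start <= df$end & df$start >= 1L &
    df$cn_total >= 0L & df$cn_minor >= 0L &
    df$cn_minor <= df$cn_total - df$cn_minor
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    message("read_segments: rejected ", sum(!ok), " invalid segment row(s)")
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Look up the immediate 5' and 3' reference bases around a position
#'
#' @param chrom Contig name.
#' @param pos 1-based position.
#' @param reference A named character vector of sequences, or a
#'   [Biostrings::DNAStringSet] (e.g. from [Biostrings::readDNAStringSet()]).
#' @return List with elements `ctx5` and `ctx3`; a flank that falls off the
#'   contig edge is `NA`.
#' @export
extract_context <- function(chrom, pos, reference) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  # FASTA headers often carry descriptions; match on the first word
  names(reference) <- sub("\\s.*$", "", names(reference))
  if (!chrom %in% names(reference)) {
    stop("extract_context: contig not in reference: ", chrom)
  }
  seq <- toupper(reference[[chrom]])
  len <- nchar(seq)
  if (pos < 1L || pos > len) {
    stop("extract_context: position ", pos, " outside contig ", chrom)
  }
  base_at <- function(i) {
    if (i < 1L || i > len) return(NA_character_)
    b <- substr(seq, i, i)
    if (b %in% .BASES) b else NA_character_
  }
  list(ctx5 = base_at(pos - 1L), ctx3 = base_at(pos + 1L))
}

#' Fill variant context columns from a reference sequence
#'
#' Applies [extract_context()] to every row of a variant table.
#'
#' @param variants Variant data frame.
#' @param reference As in [extract_context()].
#' @return The variant table with `ctx5`/`ctx3` populated.
#' @export
add_context <- function(variants, reference) {
  if (nrow(variants) == 0L) return(variants)
  ctx <- mapply(function(ch, p) unlist(extract_context(ch, p, reference)),
                variants$chrom, variants$pos, SIMPLIFY = TRUE)
  variants$ctx5 <- unname(ctx["ctx5", ])
  variants$ctx3 <- unname(ctx["ctx3", ])
  variants
}
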