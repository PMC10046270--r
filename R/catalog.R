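#' Construct a 96-channel mutation catalog object
#'
#' @param counts Integer vector of length 96, named by [sbs96_channels()]
#'   labels or unnamed in canonical order.
#' @param case_id Sample identifier.
#' @return An object of class `mutation_catalog`: a list with `counts`
#'   (named length-96 integer vector), `total`, and `case_id`.
#' @export
mutation_catalog <- function(counts, case_id = NA_character_) {
  channels <- sbs96_channels()
  if (is.null(names(counts))) {
    stopifnot(length(counts) == 96L)
    names(counts) <- channels
  } else {
    if (!setequal(names(counts), channels)) {
      stop("mutation_catalog: counts must be named by the 96 canonical channels")
    }
    counts <- counts[channels]
  }
  counts <- as.integer(counts)
  names(counts) <- channels
  if (any(counts < 0)) stop("mutation_catalog: negative counts")
  structure(
    list(counts = counts, total = sum(counts), case_id = case_id),
    class = "mutation_catalog"
  )
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("SBS96 mutation catalog", if (!is.na(x$case_id)) paste0("[", x$case_id, "]"),
      "- total", x$total, "mutations,",
      sum(x$counts > 0), "channels occupied\n")
  invisible(x)
}

#' Tally SNVs into a per-case SBS96 catalog
#'
#' Each variant with known flanking context is mapped to its pyrimidine-strand
#' trinucleotide channel via [channel_of()] and tallied. Variants with unknown
#' (`NA`) context bases are excluded from the catalog (their channel is
#' undefined) but reported in the `skipped` attribute; burden counting is
#' unaffected by this exclusion.
#'
#' @param variants Variant data frame (see [read_variant_table()]) with
#'   columns `ref`, `alt`, `ctx5`, `ctx3`, and optionally `case_id`.
#' @param case_id Catalog label; defaults to the single case id present.
#' @return A `mutation_catalog`; attribute `skipped` holds the number of
#'   context-less variants excluded.
#' @export
build_catalog <- function(variants, case_id = NULL) {
  if (is.null(case_id)) {
    ids <- unique(variants$case_id)
    case_id <- if (length(ids) == 1L) ids else NA_character_
  }
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(96), channels)
  skipped <- 0L
  if (nrow(variants) > 0L) {
    has_ctx <- !is.na(variants$ctx5) & !is.na(variants$ctx3)
    skipped <- sum(!has_ctx)
    v <- variants[has_ctx, , drop = FALSE]
    if (nrow(v) > 0L) {
      ch <- channel_of(v$ref, v$alt, v$ctx5, v$ctx3)
      tab <- table(factor(ch, levels = channels))
      counts <- stats::setNames(as.integer(tab), channels)
    }
  }
  out <- mutation_catalog(counts, case_id = case_id)
  attr(out, "skipped") <- skipped
  out
}

#' Write a catalog as a two-column TSV (channel, count) in canonical order
#'
#' @param catalog A `mutation_catalog`.
#' @param path Output file path.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(channel = names(catalog$counts),
                   count = unname(catalog$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a catalog written by [write_catalog()]
#'
#' @param path TSV with columns `channel` and `count`.
#' @param case_id Sample identifier to attach.
#' @return A `mutation_catalog`.
#' @export
read_catalog <- function(path, case_id = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "count") %in% names(df))) {
    stop("read_catalog: expected columns 'channel' and 'count' in ", path)
  }
  mutation_catalog(stats::setNames(df$count, df$channel), case_id = case_id)
}
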