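#' Canonical SBS96 channel labels
#'
#' The 96 single-base-substitution channels in canonical COSMIC order:
#' substitutions C>A, C>G, C>T, T>A, T>C, T>G, and within each substitution
#' the 5' then 3' flanking base cycling through A, C, G, T. Labels look like
#' `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_channels())
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    unlist(lapply(bases, function(p5) paste0(p5, "[", s, "]", bases)))
  }), use.names = FALSE)
}

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Map a substitution with context to its SBS96 channel
#'
#' Substitutions with a purine reference (A or G) are reported on the
#' opposite strand: ref and alt are complemented and the flanking bases are
#' complemented and swapped, so every channel has a pyrimidine (C or T)
#' reference. All arguments are vectorized and recycled to a common length.
#'
#' @param ref,alt Reference and alternate base, single characters in A/C/G/T;
#'   `ref != alt`.
#' @param ctx5,ctx3 Immediate 5' and 3' reference bases.
#' @return Character vector of canonical channel labels.
#' @export
#' @examples
#' channel_of("C", "T", "A", "A")  # "A[C>T]A"
#' channel_of("G", "A", "T", "G")  # "C[C>T]A" (reverse-complement strand)
channel_of <- function(ref, alt, ctx5, ctx3) {
  n <- max(length(ref), length(alt), length(ctx5), length(ctx3))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  ctx5 <- rep_len(toupper(ctx5), n)
  ctx3 <- rep_len(toupper(ctx3), n)
  bad <- !(ref %in% .BASES) | !(alt %in% .BASES) |
    !(ctx5 %in% .BASES) | !(ctx3 %in% .BASES)
  if (any(bad)) {
    stop("channel_of: non-ACGT base in arguments (first offending index ",
         which(bad)[1], ")")
  }
  if (any(ref == alt)) {
    stop("channel_of: ref == alt at index ", which(ref == alt)[1])
  }
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    new5 <- unname(.COMPLEMENT[ctx3[flip]])
    new3 <- unname(.COMPLEMENT[ctx5[flip]])
    ref[flip] <- unname(.COMPLEMENT[ref[flip]])
    alt[flip] <- unname(.COMPLEMENT[alt[flip]])
    ctx5[flip] <- new5
    ctx3[flip] <- new3
  }
  paste0(ctx5, "[", ref, ">", alt, "]", ctx3)
}

#' Parse SBS96 channel labels into their components
#'
#' Inverse of the label construction in [channel_of()] (pyrimidine-strand
#' representation only).
#'
#' @param channel Character vector of labels like `"A[C>T]G"`.
#' @return Data frame with columns `ctx5`, `ref`, `alt`, `ctx3`.
#' @export
parse_channel <- function(channel) {
  ok <- grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", channel)
  if (!all(ok)) {
    stop("parse_channel: malformed channel label: ", channel[!ok][1])
  }
  data.frame(
    ctx5 = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    ctx3 = substr(channel, 7, 7),
    stringsAsFactors = FALSE
  )
}
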