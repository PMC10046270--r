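# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a random signature matrix
#'
#' Draws each signature as a symmetric Dirichlet sample over the 96
#' channels. Small `concentration` gives spiky, realistic signatures;
#' very large values approach the uniform distribution.
#'
#' @param k Number of signatures (>= 1).
#' @param concentration Dirichlet concentration parameter per channel.
#' @param seed RNG seed; identical seed and parameters reproduce the matrix.
#' @param signature_ids Names for the signatures; default `SIM1..SIMk`.
#' @return A `signature_matrix`.
#' @export
simulate_signature_matrix <- function(k, concentration = 0.1, seed = NULL,
                                      signature_ids = paste0("SIM", seq_len(k))) {
  if (k < 1L) stop("simulate_signature_matrix: k must be >= 1")
  .with_seed(seed, {
    g <- matrix(stats::rgamma(k * 96L, shape = concentration), nrow = k)
    signature_matrix(g / rowSums(g), signature_ids = signature_ids)
  })
}

#' Simulate a mutation catalog from known exposures
#'
#' Draws `n` channels independently from the mixture
#' `p_c = sum_k pi_k s_kc` and tallies them — the generative model that the
#' EM refit inverts.
#'
#' @param signatures A `signature_matrix`.
#' @param exposures True mixing proportions over the signatures (non-negative,
#'   summing to 1 within 1e-6).
#' @param n Number of mutations to draw (>= 0).
#' @param seed RNG seed.
#' @param case_id Label for the catalog.
#' @return A `mutation_catalog` with `total == n`.
#' @export
simulate_catalog <- function(signatures, exposures, n, seed = NULL,
                             case_id = "sim") {
  stopifnot(inherits(signatures, "signature_matrix"))
  if (length(exposures) != length(signatures$signature_ids) ||
      any(exposures < 0) || abs(sum(exposures) - 1) > 1e-6) {
    stop("simulate_catalog: exposures must be a probability vector over the signatures")
  }
  if (n < 0L) stop("simulate_catalog: n must be >= 0")
  p <- as.vector(exposures %*% signatures$probs)
  .with_seed(seed, {
    counts <- if (n == 0L) integer(96) else
      as.integer(stats::rmultinom(1, size = n, prob = p))
    mutation_catalog(stats::setNames(counts, signatures$channel_labels),
                     case_id = case_id)
  })
}

.DEFAULT_GENE_POOL <- c(
  "TERT", "TTN", "MUC4", "MUC16", "MUC17", "PCLO", "ANK3", "ZFHX4",
  "CSMD1", "DNAH5", "RELN", "UNC13C", "BMPER", "BRINP2", "CTNND2",
  "LAMB4", "MROH2B", "POM121L12", "ZFPM2", "C6"
)

#' Simulate a variant cohort with known clonality structure
#'
#' Each variant receives a true clonality category drawn from `clonal_mix`;
#' its true VAF is 0.50 for clonal variants (heterozygous, purity 1) and
#' uniform inside the polyclonal (0.20-0.45) or subclonal (0.01-0.0999)
#' band otherwise. The observed VAF is binomial read-sampling noise at the
#' given `depth` (use `depth = Inf` for noise-free VAFs). When a signature
#' matrix and exposures are supplied, each variant's substitution and
#' flanking context are drawn from the signature mixture, so
#' [build_catalog()] on the output reproduces a catalog drawn from those
#' exposures; otherwise channels are drawn uniformly.
#'
#' @param n_cases Number of cases.
#' @param n_variants_per_case Variants per case.
#' @param clonal_mix Length-3 probability vector over
#'   (clonal, polyclonal, subclonal).
#' @param depth Sequencing depth for binomial VAF noise; `Inf` disables noise.
#' @param seed Global seed; per-case sub-seeds are derived at fixed offsets
#'   (`seed + 1000 * case_index`).
#' @param signatures,exposures Optional `signature_matrix` and true mixing
#'   proportions driving the channel draw.
#' @param genes Gene symbols sampled (with replacement) for gene labels.
#' @param pathogenic_rate Probability a variant is flagged pathogenic.
#' @return List with `variants` (variant data frame over all cases) and
#'   `truth` (class `synthetic_truth`: per-variant `clonality_labels`,
#'   per-case `exposures`, the `seed`).
#' @export
simulate_cohort <- function(n_cases, n_variants_per_case, clonal_mix,
                            depth = 60, seed = NULL,
                            signatures = NULL, exposures = NULL,
                            genes = .DEFAULT_GENE_POOL,
                            pathogenic_rate = 0.1) {
  if (length(clonal_mix) != 3L || any(clonal_mix < 0) ||
      abs(sum(clonal_mix) - 1) > 1e-6) {
    stop("simulate_cohort: clonal_mix must be a probability vector over (clonal, polyclonal, subclonal)")
  }
  if (is.null(seed)) seed <- 0L
  categories <- c("clonal", "polyclonal", "subclonal")
  channel_pool <- sbs96_channels()
  p_channel <- if (!is.null(signatures)) {
    stopifnot(inherits(signatures, "signature_matrix"),
              length(exposures) == length(signatures$signature_ids))
    as.vector(exposures %*% signatures$probs)
  } else rep(1 / 96, 96)
  per_case <- lapply(seq_len(n_cases), function(ci) {
    .with_seed(seed + 1000L * ci, {
      m <- n_variants_per_case
      true_cat <- sample(categories, m, replace = TRUE, prob = clonal_mix)
      true_vaf <- numeric(m)
      true_vaf[true_cat == "clonal"] <- 0.50
      np <- sum(true_cat == "polyclonal")
      true_vaf[true_cat == "polyclonal"] <- stats::runif(np, 0.20, 0.45)
      ns <- sum(true_cat == "subclonal")
      true_vaf[true_cat == "subclonal"] <- stats::runif(ns, 0.01, 0.0999)
      obs_vaf <- if (is.infinite(depth)) true_vaf else
        stats::rbinom(m, depth, true_vaf) / depth
      ch <- sample(channel_pool, m, replace = TRUE, prob = p_channel)
      parts <- parse_channel(ch)
      data.frame(
        case_id = paste0("case", ci),
        chrom = "chr1",
        pos = seq_len(m) * 1000L,
        ref = parts$ref, alt = parts$alt,
        vaf = obs_vaf,
        gene = sample(genes, m, replace = TRUE),
        pathogenic = stats::runif(m) < pathogenic_rate,
        ctx5 = parts$ctx5, ctx3 = parts$ctx3,
        true_category = true_cat, true_vaf = true_vaf,
        stringsAsFactors = FALSE
      )
    })
  })
  all <- do.call(rbind, per_case)
  variants <- all[, c("case_id", "chrom", "pos", "ref", "alt", "vaf",
                      "gene", "pathogenic", "ctx5", "ctx3")]
  rownames(variants) <- NULL
  truth <- structure(
    list(clonality_labels = all[, c("case_id", "true_category", "true_vaf")],
         exposures = exposures, seed = seed),
    class = "synthetic_truth"
  )
  list(variants = variants, truth = truth)
}

.SEG_EVENT_CN <- list(
  loh = c(cn_total = 2L, cn_minor = 0L),
  trisomy_gain = c(cn_total = 3L, cn_minor = 1L),
  homozygous_loss = c(cn_total = 0L, cn_minor = 0L),
  amplification = c(cn_total = 6L, cn_minor = 1L)
)

#' Simulate an allele-specific segment set with known categories
#'
#' Packs the requested events left-to-right across the toy genome, each
#' followed by a 1-bp neutral spacer (so adjacent LOH events never merge and
#' no event spans a whole chromosome); the remainder is neutral diploid.
#' Event copy numbers: LOH copy-neutral (2+0), gain trisomic (3+1),
#' homozygous loss (0+0), amplification (6+1).
#'
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param n_loh,n_gain,n_hl,n_amp Number of events of each class.
#' @param loh_len_bp LOH event length.
#' @param gain_len_bp,hl_len_bp,amp_len_bp Other event lengths.
#' @param seed RNG seed (accepted for interface symmetry; packing is
#'   deterministic).
#' @return List with `segments` (data frame incl. neutral filler) and
#'   `truth` (class `synthetic_truth` with per-event `segment_categories`).
#' @export
simulate_segments <- function(chrom_lengths, n_loh = 0L, loh_len_bp = 20e6,
                              n_gain = 0L, n_hl = 0L, n_amp = 0L,
                              gain_len_bp = 10e6, hl_len_bp = 1e6,
                              amp_len_bp = 1e6, seed = NULL) {
  events <- c(rep("loh", n_loh), rep("trisomy_gain", n_gain),
              rep("homozygous_loss", n_hl), rep("amplification", n_amp))
  lens <- c(rep(loh_len_bp, n_loh), rep(gain_len_bp, n_gain),
            rep(hl_len_bp, n_hl), rep(amp_len_bp, n_amp))
  segs <- list()
  truth_cat <- character()
  ei <- 1L
  for (chrom in names(chrom_lengths)) {
    cursor <- 1
    clen <- chrom_lengths[[chrom]]
    while (ei <= length(events) && cursor + lens[ei] - 1 <= clen - 1) {
      cn <- .SEG_EVENT_CN[[events[ei]]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = cursor, end = cursor + lens[ei] - 1,
        cn_total = cn[["cn_total"]], cn_minor = cn[["cn_minor"]],
        stringsAsFactors = FALSE)
      truth_cat <- c(truth_cat, events[ei])
      cursor <- cursor + lens[ei] + 1   # 1-bp neutral spacer
      ei <- ei + 1L
    }
    if (cursor <= clen) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = cursor, end = clen,
        cn_total = 2L, cn_minor = 1L, stringsAsFactors = FALSE)
      truth_cat <- c(truth_cat, "neutral")
    }
  }
  if (ei <= length(events)) {
    stop("simulate_segments: requested events do not fit on the genome (",
         length(events) - ei + 1L, " left over)")
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  truth <- structure(
    list(segment_categories = truth_cat, seed = seed),
    class = "synthetic_truth"
  )
  list(segments = segments, truth = truth)
}
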