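# Shared fixture builders. Oracles here are deliberately independent of the
# package's implementation paths (explicit loops, no calls into the code they
# check).

make_variants <- function(case_id = "case1", chrom = "chr1",
                          pos = NULL, ref = "C", alt = "T",
                          vaf = 0.5, gene = "TERT", pathogenic = FALSE,
                          ctx5 = "A", ctx3 = "A") {
  n <- max(lengths(list(case_id, chrom, pos, ref, alt, vaf, gene,
                        pathogenic, ctx5, ctx3)), 1L)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  data.frame(case_id = rep_len(case_id, n), chrom = rep_len(chrom, n),
             pos = rep_len(as.integer(pos), n), ref = rep_len(ref, n),
             alt = rep_len(alt, n), vaf = rep_len(vaf, n),
             gene = rep_len(gene, n),
             pathogenic = rep_len(pathogenic, n),
             ctx5 = rep_len(ctx5, n), ctx3 = rep_len(ctx3, n),
             stringsAsFactors = FALSE)
}

# Two signatures with disjoint channel support: uniform on channels 1-48 and
# 49-96. The ML mixture weights equal the empirical block masses.
disjoint_signature_pair <- function() {
  probs <- rbind(c(rep(1 / 48, 48), rep(0, 48)),
                 c(rep(0, 48), rep(1 / 48, 48)))
  signature_matrix(probs, signature_ids = c("BLOCK1", "BLOCK2"))
}

# Independent channel oracle: explicit per-variant reverse-complement logic.
oracle_channel <- function(ref, alt, ctx5, ctx3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) {
    tmp5 <- comp[[ctx3]]; tmp3 <- comp[[ctx5]]
    ref <- comp[[ref]]; alt <- comp[[alt]]
    ctx5 <- tmp5; ctx3 <- tmp3
  }
  paste0(ctx5, "[", ref, ">", alt, "]", ctx3)
}

# Exhaustive grid-search oracle for the K=2 mixture log-likelihood.
grid_search_pi1 <- function(counts, S, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  nz <- counts > 0
  ll <- vapply(grid, function(p) {
    mix <- p * S[1, nz] + (1 - p) * S[2, nz]
    if (any(mix == 0)) return(-Inf)
    sum(counts[nz] * log(mix))
  }, numeric(1))
  grid[which.max(ll)]
}

random_uv_signature_set <- function(seed) {
  # five named signatures incl. the UV block, spiky Dirichlet rows
  simulate_signature_matrix(
    5, concentration = 0.2, seed = seed,
    signature_ids = c("SBS1", "SBS5", "SBS7a", "SBS7b", "SBS38"))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
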