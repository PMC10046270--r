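#' UV-associated single-base-substitution signatures
#'
#' The COSMIC signatures attributed to ultraviolet exposure in cutaneous
#' melanoma. Doublet signatures are outside this SNV-only pipeline.
#' @export
UV_SIGNATURES <- c("SBS7a", "SBS7b", "SBS7c", "SBS7d", "SBS38")

.em_core <- function(n, S, tol, max_iter) {
  K <- nrow(S)
  N <- sum(n)
  nz <- n > 0
  reach <- colSums(S)[nz] > 0
  if (!all(reach)) {
    stop("em_fit: channel ", colnames(S)[nz][!reach][1],
         " has mutations but zero probability under every signature")
  }
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    p <- as.vector(pi_k %*% S)              # mixture channel probabilities
    ll <- sum(n[nz] * log(p[nz]))
    ll_trace[iter] <- ll
    # M-step folded in: pi_k <- sum_c n_c * pi_k s_kc / p_c / N
    pi_k <- pi_k * as.vector(S[, nz, drop = FALSE] %*% (n[nz] / p[nz])) / N
    if (ll - ll_old < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(pi = pi_k, log_likelihood = ll_old, n_iterations = iter,
       converged = converged, ll_trace = ll_trace)
}

#' Refit a fixed signature matrix to a catalog by expectation-maximization
#'
#' Models the catalog as `n` independent draws from the mixture
#' `p_c = sum_k pi_k s_kc` over the 96 channels and estimates the exposures
#' `pi` by EM from a uniform start: responsibilities
#' `r_kc = pi_k s_kc / sum_j pi_j s_jc`, then `pi_k <- sum_c n_c r_kc / N`.
#' The log-likelihood `sum_c n_c log p_c` is non-decreasing across
#' iterations; iteration stops when its improvement falls below `tol`.
#'
#' With `prune = TRUE` (the default, mirroring refitting against a candidate
#' list of signatures) any signature whose fitted exposure falls below
#' `prune_threshold` is removed and the fit repeated once on the reduced set;
#' pruned signatures are reported at exposure 0.
#'
#' @param catalog A `mutation_catalog` with `total >= 1`.
#' @param signatures A `signature_matrix`.
#' @param tol Absolute log-likelihood improvement below which EM stops.
#' @param max_iter Iteration cap; if reached, `converged` is `FALSE`.
#' @param prune_threshold Exposure below which a signature is dropped.
#' @param prune Whether to prune and refit.
#' @return Object of class `exposure_fit`: list with `signature_ids`,
#'   `proportions` (named, summing to 1), `log_likelihood`, `n_iterations`,
#'   `converged`, and `pruned` (ids removed in the refit).
#' @export
#' @examples
#' sigs <- simulate_signature_matrix(3, seed = 1)
#' cat96 <- simulate_catalog(sigs, c(0.6, 0.3, 0.1), n = 5000, seed = 2)
#' em_fit(cat96, sigs)
em_fit <- function(catalog, signatures, tol = 1e-8, max_iter = 10000L,
                   prune_threshold = 0.01, prune = TRUE) {
  stopifnot(inherits(catalog, "mutation_catalog"),
            inherits(signatures, "signature_matrix"))
  if (catalog$total < 1L) stop("em_fit: empty catalog")
  n <- catalog$counts[signatures$channel_labels]
  S <- signatures$probs
  fit <- .em_core(n, S, tol, max_iter)
  ids <- signatures$signature_ids
  pi_full <- stats::setNames(fit$pi, ids)
  pruned <- character()
  if (prune && nrow(S) > 1L) {
    keep <- fit$pi >= prune_threshold
    if (!all(keep) && any(keep)) {
      pruned <- ids[!keep]
      refit <- .em_core(n, S[keep, , drop = FALSE], tol, max_iter)
      pi_full <- stats::setNames(numeric(length(ids)), ids)
      pi_full[ids[keep]] <- refit$pi
      fit <- refit
    }
  }
  pi_full <- pi_full / sum(pi_full)
  out <- structure(
    list(signature_ids = ids, proportions = pi_full,
         log_likelihood = fit$log_likelihood,
         n_iterations = fit$n_iterations, converged = fit$converged,
         pruned = pruned),
    class = "exposure_fit"
  )
  attr(out, "ll_trace") <- fit$ll_trace
  out
}

#' @export
print.exposure_fit <- function(x, digits = 3, ...) {
  cat("EM signature refit: logLik", format(x$log_likelihood, digits = 8),
      "after", x$n_iterations, "iterations",
      if (!x$converged) "(NOT converged)", "\n")
  active <- x$proportions[x$proportions > 0]
  print(round(active[order(-active)], digits))
  if (length(x$pruned)) cat("pruned:", paste(x$pruned, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior attribution of a single mutation to signatures
#'
#' Given a fitted exposure vector, a mutation in channel `c` is attributed to
#' signature `k` with posterior probability `pi_k s_kc / sum_j pi_j s_jc`.
#' The UV posterior is the summed posterior over the UV-associated
#' signatures present in the fit ([UV_SIGNATURES]); the mutation is labeled
#' UV-related when that posterior reaches 0.5 (ties at exactly 0.5 count as
#' UV-related).
#'
#' @param channel Canonical SBS96 channel label.
#' @param exposures An `exposure_fit`.
#' @param signatures The `signature_matrix` used in the fit (same ids).
#' @param uv_signatures Signature ids treated as UV-associated.
#' @return List with `posterior` (named numeric over signatures, sums to 1),
#'   `uv_posterior`, and logical `uv_related`.
#' @export
attribute_mutation <- function(channel, exposures, signatures,
                               uv_signatures = UV_SIGNATURES) {
  stopifnot(inherits(exposures, "exposure_fit"),
            inherits(signatures, "signature_matrix"))
  if (!identical(exposures$signature_ids, signatures$signature_ids)) {
    stop("attribute_mutation: exposures and signatures disagree on signature ids")
  }
  if (!channel %in% signatures$channel_labels) {
    stop("attribute_mutation: not a canonical channel: ", channel)
  }
  w <- exposures$proportions * signatures$probs[, channel]
  tot <- sum(w)
  if (tot == 0) {
    stop("attribute_mutation: channel ", channel,
         " has zero probability under the fitted mixture")
  }
  post <- w / tot
  uv <- sum(post[names(post) %in% uv_signatures])
  list(posterior = post, uv_posterior = uv, uv_related = uv >= 0.5)
}

#' Band fitted exposures into the qualitative etiology vocabulary
#'
#' Summarises an exposure vector into the categories a per-case report uses:
#' the UV share (summed exposure of [UV_SIGNATURES]) banded as
#' `predominant` (share >= `uv_cutoff`) or `minor`; an APOBEC flag when
#' SBS2 + SBS13 exposure reaches `apobec_cutoff`; and an HRD band from the
#' SBS3 exposure (`none` below `sbs3_bands[1]`, `minor` up to
#' `sbs3_bands[2]`, `present` above). Signatures absent from the fit
#' contribute zero.
#'
#' @param exposures An `exposure_fit`.
#' @param uv_cutoff UV-predominance threshold (default 0.5).
#' @param apobec_cutoff SBS2+SBS13 flag threshold (default 0.10).
#' @param sbs3_bands Two increasing break points for the SBS3 band
#'   (default `c(0.05, 0.20)`; the lower bound is inclusive of `minor`,
#'   the upper inclusive too, i.e. `present` requires strictly more).
#' @param uv_signatures Signature ids treated as UV-associated.
#' @return List of class `etiology_summary` with `uv_share`, `uv_band`,
#'   `apobec_flag`, `hrd_band`.
#' @export
etiology_summary <- function(exposures, uv_cutoff = 0.5,
                             apobec_cutoff = 0.10,
                             sbs3_bands = c(0.05, 0.20),
                             uv_signatures = UV_SIGNATURES) {
  stopifnot(inherits(exposures, "exposure_fit"))
  p <- exposures$proportions
  get <- function(id) if (id %in% names(p)) unname(p[id]) else 0
  uv_share <- sum(p[names(p) %in% uv_signatures])
  apobec <- get("SBS2") + get("SBS13")
  sbs3 <- get("SBS3")
  hrd_band <- if (sbs3 < sbs3_bands[1]) "none"
    else if (sbs3 <= sbs3_bands[2]) "minor"
    else "present"
  structure(
    list(uv_share = uv_share,
         uv_band = if (uv_share >= uv_cutoff) "predominant" else "minor",
         apobec_flag = apobec >= apobec_cutoff,
         hrd_band = hrd_band),
    class = "etiology_summary"
  )
}

#' Write fitted exposures as a two-column TSV (signature_id, proportion)
#'
#' @param exposures An `exposure_fit`.
#' @param path Output file.
#' @export
write_exposures <- function(exposures, path) {
  df <- data.frame(signature_id = exposures$signature_ids,
                   proportion = unname(exposures$proportions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
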