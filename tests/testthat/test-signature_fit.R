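test_that("EM handles the single-signature and disjoint-support cases exactly", {
  sigs1 <- simulate_signature_matrix(1, seed = 3, signature_ids = "ONLY")
  cat96 <- simulate_catalog(sigs1, 1, n = 500, seed = 4)
  fit <- em_fit(cat96, sigs1)
  expect_equal(unname(fit$proportions), 1)
  expect_true(fit$converged)

  # disjoint support: ML weights are the empirical block masses
  sigs <- disjoint_signature_pair()
  counts <- setNames(integer(96), sbs96_channels())
  counts[1:48] <- as.integer(rmultinom(1, 70, rep(1, 48)))
  counts[49:96] <- as.integer(rmultinom(1, 30, rep(1, 48)))
  fit2 <- em_fit(mutation_catalog(counts), sigs, prune = FALSE)
  expect_equal(unname(fit2$proportions), c(0.70, 0.30), tolerance = 1e-7)
})

test_that("EM recovers simulated exposures and rejects degenerate inputs", {
  sigs <- disjoint_signature_pair()
  cat96 <- simulate_catalog(sigs, c(0.6, 0.4), n = 10000, seed = 21)
  fit <- em_fit(cat96, sigs, prune = FALSE)
  expect_lt(sum(abs(fit$proportions - c(0.6, 0.4))), 0.05)

  expect_error(em_fit(mutation_catalog(integer(96)), sigs), "empty catalog")
  # a mutation in a channel no signature can produce
  counts <- setNames(integer(96), sbs96_channels())
  counts[60] <- 5L
  block1_only <- signature_matrix(
    rbind(c(rep(1 / 48, 48), rep(0, 48))), signature_ids = "B1")
  expect_error(em_fit(mutation_catalog(counts), block1_only),
               "zero probability")
})

test_that("EM log-likelihood is non-decreasing on random instances", {
  for (s in 1:20) {
    sigs <- simulate_signature_matrix(4, seed = s)
    expo <- {
      set.seed(s + 500)
      w <- rgamma(4, 1); w / sum(w)
    }
    cat96 <- simulate_catalog(sigs, expo, n = 2000, seed = s + 100)
    fit <- em_fit(cat96, sigs, prune = FALSE)
    trace <- attr(fit, "ll_trace")
    expect_gt(length(trace), 1)
    expect_true(all(diff(trace) >= -1e-9))
  }
})

test_that("K=2 EM matches an exhaustive grid search over the mixing weight", {
  for (s in 1:20) {
    sigs <- simulate_signature_matrix(2, concentration = 0.3, seed = s)
    set.seed(s + 900)
    true_p <- runif(1, 0.1, 0.9)
    cat96 <- simulate_catalog(sigs, c(true_p, 1 - true_p), n = 3000,
                              seed = s + 300)
    fit <- em_fit(cat96, sigs, prune = FALSE)
    best <- grid_search_pi1(cat96$counts, sigs$probs)
    expect_equal(unname(fit$proportions[1]), best, tolerance = 1e-3)
  }
})

test_that("exposure recovery: mean L1 error below 0.05 over seeded simulations", {
  errs <- vapply(1:50, function(s) {
    sigs <- simulate_signature_matrix(5, seed = s)
    set.seed(s + 700)
    w <- rgamma(5, 1); w <- w / sum(w)
    cat96 <- simulate_catalog(sigs, w, n = 20000, seed = s + 200)
    fit <- em_fit(cat96, sigs, prune = FALSE)
    sum(abs(fit$proportions - w))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("exposures are equivariant under signature permutation", {
  sigs <- simulate_signature_matrix(4, seed = 13,
                                    signature_ids = paste0("S", 1:4))
  cat96 <- simulate_catalog(sigs, c(0.4, 0.3, 0.2, 0.1), n = 5000, seed = 14)
  fit <- em_fit(cat96, sigs, prune = FALSE)
  perm <- c(3, 1, 4, 2)
  sigs_p <- signature_matrix(sigs$probs[perm, ],
                             signature_ids = sigs$signature_ids[perm])
  fit_p <- em_fit(cat96, sigs_p, prune = FALSE)
  expect_equal(fit_p$proportions, fit$proportions[perm], tolerance = 1e-8)
})

test_that("pruning removes trace signatures and reports them at zero", {
  sigs <- disjoint_signature_pair()
  counts <- setNames(integer(96), sbs96_channels())
  counts[1:48] <- 20L   # 960 mutations, all in block 1
  fit <- em_fit(mutation_catalog(counts), sigs, prune = TRUE)
  expect_equal(fit$pruned, "BLOCK2")
  expect_equal(unname(fit$proportions), c(1, 0))
  expect_equal(sum(fit$proportions), 1)
})

test_that("per-mutation attribution matches hand arithmetic and normalizes", {
  # pi = (0.6, 0.4), s_1c = 0.05, s_2c = 0.0125 -> posterior 0.03/0.035, 0.005/0.035
  probs <- matrix(0, 2, 96)
  probs[1, 1] <- 0.05; probs[2, 1] <- 0.0125
  probs[1, 2:96] <- (1 - 0.05) / 95
  probs[2, 2:96] <- (1 - 0.0125) / 95
  sigs <- signature_matrix(probs, signature_ids = c("SBS7a", "SBS5"))
  counts <- setNames(integer(96), sbs96_channels())
  counts[1] <- 60L; counts[2] <- 40L
  fit <- em_fit(mutation_catalog(counts), sigs, prune = FALSE)
  fit$proportions[] <- c(0.6, 0.4)   # fix exposures for the hand-checked case
  att <- attribute_mutation(sbs96_channels()[1], fit, sigs)
  expect_equal(unname(att$posterior), c(0.03, 0.005) / 0.035, tolerance = 1e-12)
  expect_equal(att$uv_posterior, 0.857142857, tolerance = 1e-6)
  expect_true(att$uv_related)

  # posteriors over signatures sum to 1 across random channels and fits
  sigs_r <- random_uv_signature_set(seed = 31)
  cat_r <- simulate_catalog(sigs_r, rep(0.2, 5), n = 3000, seed = 32)
  fit_r <- em_fit(cat_r, sigs_r, prune = FALSE)
  set.seed(33)
  for (ch in sample(sbs96_channels(), 25)) {
    att_r <- attribute_mutation(ch, fit_r, sigs_r)
    expect_equal(sum(att_r$posterior), 1, tolerance = 1e-12)
  }
})

test_that("an all-UV fit attributes every reachable mutation fully to UV", {
  sigs <- random_uv_signature_set(seed = 41)
  # exposure mass entirely on the UV members SBS7a/SBS7b/SBS38
  fit <- em_fit(simulate_catalog(sigs, c(0, 0, 0.5, 0.3, 0.2), n = 2000,
                                 seed = 42), sigs, prune = TRUE)
  reachable <- sbs96_channels()[colSums(
    fit$proportions * sigs$probs) > 0]
  for (ch in reachable[1:20]) {
    expect_equal(attribute_mutation(ch, fit, sigs)$uv_posterior, 1.0)
  }
})

test_that("etiology banding applies the UV, APOBEC and SBS3 thresholds", {
  mk <- function(p) {
    f <- structure(list(signature_ids = names(p),
                        proportions = p,
                        log_likelihood = 0, n_iterations = 1L,
                        converged = TRUE, pruned = character()),
                   class = "exposure_fit")
    f
  }
  uv_case <- etiology_summary(mk(c(SBS7a = 0.9, SBS5 = 0.1)))
  expect_equal(uv_case$uv_band, "predominant")
  expect_false(uv_case$apobec_flag)
  expect_equal(uv_case$hrd_band, "none")

  apobec_case <- etiology_summary(mk(c(SBS2 = 0.4, SBS13 = 0.3, SBS5 = 0.3)))
  expect_equal(apobec_case$uv_band, "minor")
  expect_true(apobec_case$apobec_flag)

  hrd_case <- etiology_summary(mk(c(SBS3 = 0.12, SBS7b = 0.88)))
  expect_equal(hrd_case$hrd_band, "minor")
  expect_equal(etiology_summary(mk(c(SBS3 = 0.30, SBS7b = 0.70)))$hrd_band,
               "present")
  # boundary: uv_share exactly at the cutoff is predominant
  expect_equal(etiology_summary(mk(c(SBS7a = 0.5, SBS5 = 0.5)))$uv_band,
               "predominant")
})
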