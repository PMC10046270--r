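---
title: "Methods: signature refitting, burden, clonality and genomic scars in melwgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature refitting, burden, clonality and genomic scars in melwgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melwgs)
```

melwgs summarises somatic variant and copy-number calls from melanoma
whole-genome sequencing into the quantities a tumor-board-style report
needs: mutational-signature exposures with an etiology reading, mutation
burden, per-gene clonality, copy-number scars, and cohort recurrence. This
vignette documents the models behind each stage, the defaults and why they
were chosen, and what the synthetic-data generators do and do not emulate.

## Trinucleotide catalogs

Every biallelic SNV is assigned to one of 96 channels defined by its
substitution and immediate 5'/3' reference bases, reported on the
pyrimidine strand: a purine-reference substitution is reverse-complemented
(contexts swapped and complemented) before lookup, so `G>A` flanked by
`T_G` and `C>T` flanked by `C_A` are the same event. Channel order is the
canonical COSMIC order (substitutions C>A, C>G, C>T, T>A, T>C, T>G; within
each, 5' then 3' base cycling A, C, G, T). Variants whose flanking bases
are unknown cannot be assigned a channel; they are excluded from the
catalog but still count toward burden, which does not need context.
Indels and MNVs are kept in a side list for burden counting but never
enter the catalog — the 96-channel scheme is SNV-only, and doublet (DBS)
catalogs are out of scope.

## Signature refitting by EM

Given a fixed signature matrix $S$ with rows $s_{k\cdot}$ (each a
probability distribution over the 96 channels) and a catalog
$n = (n_1,\dots,n_{96})$ with $N = \sum_c n_c$, the catalog is modeled as
$N$ i.i.d. draws from the mixture $p_c(\pi) = \sum_k \pi_k s_{kc}$. The
exposures $\pi$ maximise the multinomial log-likelihood
$\ell(\pi) = \sum_c n_c \log p_c(\pi)$, which is concave in $\pi$ over the
simplex, so EM converges to the global optimum from any interior start.
`em_fit()` iterates

$$r_{kc} = \frac{\pi_k s_{kc}}{\sum_j \pi_j s_{jc}}, \qquad
  \pi_k \leftarrow \frac{1}{N}\sum_c n_c\, r_{kc}$$

from the uniform start $\pi_k = 1/K$. Because the problem is concave,
restarts add nothing; the uniform start makes the fit deterministic.
Convergence is declared when the absolute log-likelihood improvement drops
below `tol = 1e-8`, with a cap of `max_iter = 10000` iterations and a
`converged = FALSE` flag if the cap is hit (in practice fits on realistic
catalogs converge in tens of iterations). The likelihood trace is retained
and is non-decreasing by the usual EM argument; the test suite asserts
this on random instances and checks the $K=2$ optimum against an
exhaustive grid search at step $10^{-4}$.

**Pruning.** Refitting against a candidate list (for melanoma typically
SBS1, SBS2, SBS3, SBS5, SBS7a–d, SBS13, SBS17a/b, SBS38, SBS40) tends to
scatter small spurious exposures. With `prune = TRUE` (default), any
signature below `prune_threshold = 0.01` after the first fit is removed
and the fit repeated once on the reduced set; pruned signatures are
reported at exposure 0, and the refit keeps the exposure vector on the
simplex. The threshold is configuration: 1% is below any exposure a
qualitative etiology call would rely on.

**Per-mutation attribution.** A mutation in channel $c$ is attributed to
signature $k$ with posterior $\pi_k s_{kc} / \sum_j \pi_j s_{jc}$. The UV
posterior sums over SBS7a, SBS7b, SBS7c, SBS7d and SBS38 (the
UV-associated SBS signatures; the doublet signature DBS1 is UV-associated
too but outside an SNV-only pipeline). A mutation is labeled UV-related at
posterior $\ge 0.5$; the tie at exactly 0.5 is deliberately resolved
toward UV so the boundary is documented rather than floating-point-
dependent.

**Etiology banding.** Reports band the exposures qualitatively: UV
*predominant* when the summed UV exposure is $\ge 0.5$ of the catalog,
else *minor*; an APOBEC flag when SBS2 + SBS13 $\ge 0.10$; an HRD band
from SBS3 (*none* $< 0.05$, *minor* in $[0.05, 0.20]$, *present*
$> 0.20$). Cutaneous-melanoma reports state these bands qualitatively
without printing thresholds, so the cutoffs are configuration with the
stated defaults — chosen so that a catalog dominated by UV channels reads
"predominant", a double-digit APOBEC share is flagged, and a minority but
non-trivial SBS3 component reads "minor".

## Burden

WGS-TMB is `total_mutations / callable_mb`. The callable genome size is a
per-case quantity that upstream pipelines rarely publish; the default of
3300 Mb sits near the center of the 3.2–3.4 Gb range implied by typical
human WGS callable fractions, and the test suite checks that this default
reproduces a reference cohort's printed per-case TMB values within 3%
relative error from their printed mutation counts. When the per-case
callable size is known it should be passed explicitly.

The WES→panel conversion is linear, anchored at the published
correspondence of a 199-mutation exome burden to a panel TMB of 10 m/Mb:
`count × 10/199`. The high-TMB flag applies a strict `> 175` threshold to
the pathogenic-mutations-per-exome count. The threshold's unit is
genuinely ambiguous in clinical usage (a count per exome versus a rate per
Mb); melwgs exposes both the threshold and the quantity it applies to as
configuration, with the count reading as default, rather than hard-coding
one interpretation. Pathogenicity itself is an upstream annotation
(VEP/ClinVar-style) consumed as a flag, never computed here.

## Clonality

Under the heterozygous-diploid, purity-1 model, a mutation at VAF $v$ is
carried by $\min(2v, 1)$ of the tumor cells. Classification uses the
driver-annotation bands: clonal at $v \ge 0.50$, polyclonal for
$0.20 \le v \le 0.45$, subclonal at $v < 0.10$. The intervals
$(0.10, 0.20)$ and $(0.45, 0.50)$ belong to no band; melwgs reports them
as an explicit *indeterminate* class instead of silently widening a band —
fidelity to the printed boundaries over tidiness. The 45% polyclonal
endpoint is treated as inclusive (the bands are stated as closed ranges).
A gene in a case is classified by the maximum VAF among its variants: a
gene is as clonal as its most clonal hit, and one label per gene/case is
what downstream driver tables use. No purity, ploidy or copy-number
correction is applied; on copy-altered loci the 2·VAF arithmetic is biased
and a CCF model would be needed (out of scope).

## Copy-number categories, LOH percent, HRD-LOH

Segments carry integer total and minor-allele copy numbers. Categories,
in precedence order: homozygous loss (`cn_total = 0`); LOH
(`cn_minor = 0`, `cn_total >= 1` — copy-neutral LOH and hemizygous loss
alike, and LOH outranks the gain classes so a 6+0 segment reads LOH);
trisomy-like gain (`cn_total` 3–4 with minor allele retained);
amplification (`cn_total >= 5`); else neutral diploid. The integer
cutoffs are configuration — category names are conventional but their
boundaries are not standardised.

The LOH percent is the merged length of LOH segments as a percent of the
genome (default denominator: the GRCh38 primary-assembly length from
`hg38_chrom_lengths()`). A genome-fraction definition is used because a
percent-of-segments definition is not self-consistent with per-case CNV
counts in published summary tables; merging (via `GenomicRanges::reduce`)
makes the fraction invariant to how the segmenter split the intervals.

The HRD-LOH scar score counts LOH segments longer than 15 Mb that do not
span their whole chromosome, with `hrd_high` at a score of 10 or more —
the established genomic-scar definition. Telomeric allelic imbalance and
large-scale transition scores are out of scope.

## Cohort statistics

The gene-by-case matrix is binary (any hit marks the cell, promoter
mutations counting like coding ones). Incidence percents round half-up to
integers — the convention that reproduces printed small-cohort fractions
(6/7 → 86, 4/7 → 57, 3/7 → 43). The recurrence filter keeps genes mutated
in strictly more than 2 cases. The over-representation filter compares the
*rounded* cohort percent (the number a reader sees) strictly against
`fold × reference_percent` with `fold = 2`; using the displayed percent
and a strict inequality is the only convention consistent with reference
gene lists in which 43% vs 40% is excluded while 43% vs 7% is included.
No statistical enrichment test is performed — the comparison is a fold
filter, and the reference percents (TCGA-SKCM) are consumed as a table,
never recomputed.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, seeded, and restore the caller's RNG
state. `simulate_signature_matrix()` draws signatures as symmetric
Dirichlet rows (default concentration 0.1, giving the spiky profiles real
SBS signatures have). `simulate_catalog()` draws channel counts
multinomially from a designated mixture — exactly the generative model the
EM refit inverts. `simulate_cohort()` draws per-variant clonality truth
from a designated mix, sets the true VAF to 0.50 for clonal variants
(heterozygous, purity 1) or uniformly inside the polyclonal/subclonal
band, and observes it through binomial read sampling at a configurable
depth (default 60×, typical for WGS; `Inf` disables noise). When given a
signature matrix and exposures it draws each variant's substitution and
context from that mixture, so catalogs built from the simulated table are
draws from the designated exposures. `simulate_segments()` packs
non-overlapping events of designated classes onto a toy genome with 1-bp
neutral spacers. A single global seed drives fixed per-case offsets
(`seed + 1000·case`), so cases are independent but jointly reproducible.

Not emulated: purity < 1, copy-number-distorted VAFs, mutation clustering
along the genome, realistic chromosome coordinates, read-level artifacts,
or correlated signature activity. Passing tests on this synthetic data
therefore demonstrate the estimators' correctness under their stated
models, not robustness to the ways real tumors violate those models.

One boundary effect is worth knowing: because clonal truth sits exactly at
the 0.50 classification threshold, binomial noise at any finite depth
sends about half of the clonal draws an epsilon below it, into the
indeterminate gap — never into a wrong band. Recovery-from-noise tests
therefore assert exact recovery for draws more than four binomial standard
deviations from every band boundary, rather than a blanket agreement rate.

## Problem sizes and numerics

The test suite runs EM recovery at catalogs of 20,000 mutations over 5
signatures (50 seeded replicates, mean L1 exposure error under 0.05),
grid-search agreement at 3,000 mutations over 2 signatures, and clonality
recovery at 5,000 variants at 10,000× depth; the whole suite completes in
well under a minute. Degenerate inputs are errors, not silent results: an
empty catalog, a mutated channel unreachable by every candidate signature,
a VAF outside [0, 1], a segment with `start > end` or a minor allele
exceeding the lesser-allele bound, and a missing chromosome length all
raise (or reject-and-count, for per-record validation) with the offender
named. Coordinates are 1-based inclusive throughout; segment files written
0-based can be read with `zero_based = TRUE`.
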