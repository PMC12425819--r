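---
title: "Power-gated somatic mutation frequency comparison: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-gated somatic mutation frequency comparison: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutcohort)
library(dplyr)
```

This vignette is the package's account of the statistical machinery it
implements: what each procedure assumes, which parameters matter and why
their defaults are what they are, the numerical conventions adopted where
several are defensible, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The problem

Comparing per-gene somatic mutation frequencies between a small exposed
cohort (tens of tumors) and a large control cohort (hundreds to thousands)
is asymmetric in an unusual way: for most driver genes the *best possible*
outcome — every exposed tumor wild-type, controls at their observed
frequency — still cannot reach significance once multiple testing is
accounted for. Testing such genes is not merely futile; it inflates the
denominator of the false-discovery-rate correction and drags down the
q-values of the genes that *can* be informative. The package therefore
separates two questions:

1. **Could this gene ever show a significant difference at these margins?**
   (the power gate)
2. **Does it?** (the exact test, run only on gate survivors)

## The power gate

For a gene, condition on the observed margins: exposed size $n_1$, control
size $n_2$, and the total mutated count $m = k_1 + k_2$ pooled across
cohorts. Every possible allocation $a \in [\max(0, m-n_2), \min(m, n_1)]$ of
the $m$ mutated samples to the exposed cohort defines a 2×2 table with those
margins (zero counts allowed). `min_achievable_p()` computes the Fisher
$P$ for each allocation and returns the minimum — the $P$ an oracle
adversary could have produced. Because the hypergeometric pmf over $a$ is
shared by all allocations at fixed margins, all allocation $P$s come from
one pmf pass, which keeps the full-panel gate effectively instantaneous.

A gene is **powered** when $\min_a P(a) \times B < \alpha$ with Bonferroni
divisor $B$ equal to the number of genes screened and $\alpha = 0.05$. $B$
is a parameter, not something the package infers: the panel comes from an
upstream driver-significance screen that is outside this package's scope
(49 for a two-sided screen over de novo-significant drivers, 30 for a
one-sided reduced-frequency screen, in the motivating study's setup).

Two design choices deserve note:

* **Observed-$m$-only scanning.** The enumeration fixes both margins at
  their observed values and scans only the allocation, not $m$ itself. This
  is the reading consistent with "holding the margins fixed", and it is the
  choice under which the conditional test and the gate use the same sample
  space.
* **The gate precedes testing.** `compare_gene_frequencies()` never reports
  a $P$ for an unpowered gene (it reports `NA`), and the BH correction runs
  across powered genes only.

`min_detectable_count()` answers the dual question for depletion screens:
the smallest control mutated count $m$ at which the extreme table
$[[0, n_1], [m, n_2 - m]]$ is one-sided significant. The one-sided $P$ of
that table is the hypergeometric point mass at zero, which is nonincreasing
in $m$, so the first crossing defines the answer; at $n_1 = 21$,
$n_2 = 554$, $\alpha = 0.05$ it is 76.

## Exact-test conventions

Several Fisher-test details are convention rather than mathematics; the
package fixes them as follows and the test suite pins them against
independent oracles (binomial-coefficient enumeration, and
`stats::fisher.test` as a cross-check).

* **Two-sided rule:** probability mass. $P$ is the sum of point
  probabilities of all outcomes no more probable than the observed one,
  with a relative tolerance of $1 + 10^{-7}$ when comparing point
  probabilities, to absorb floating-point ties. The per-margin pmf is
  normalized to sum to one so that a table whose observed outcome is the
  mode reports exactly $P = 1$.
* **Odds ratio:** the unconditional sample estimate $(ad)/(bc)$, not the
  conditional MLE. A zero denominator gives $\infty$ (or `NaN` when the
  numerator is also zero); no continuity correction. This matches the
  coarse odds ratios such analyses typically print (e.g. 0.2, 2).
* **r×c tables:** Monte Carlo over fixed-margin tables
  (`stats::r2dtable`), $10^6$ iterations by default, with the add-one
  estimator $(1 + \text{hits})/(N + 1)$ so the estimate is never zero; the
  seed and the Monte Carlo standard error are recorded in the result.
* **Stratified test:** the exact conditional combination. The statistic is
  the total exposed-success count across strata; its null distribution is
  the convolution of per-stratum central hypergeometric pmfs; strata with a
  zero row or column margin carry no information under this conditioning
  and are dropped (with a message). The two-sided rule mirrors the 2×2
  probability-mass convention, so a single stratum reduces exactly to
  `fisher_2x2()`. The literature also contains score/CMH-chi-square
  variants; only the exact-conditional form is implemented.
* **Rank-sum:** exact enumeration when the smaller group has at most 8
  values and there are no ties; otherwise the tie-corrected normal
  approximation with continuity correction (a 21-vs-554 comparison is
  firmly in approximation territory). When the pooled values are all
  identical the null distribution is degenerate and $P = 1$ by convention.
* **Frequency uncertainty:** the standard deviation of
  $\mathrm{Beta}(k+1,\, n-k+1)$ — the posterior of the frequency under a
  uniform prior — attached to every $k/n$ estimate and drawn as error bars
  by the `autoplot()` methods.

## The subtype cascade

`classify_subtype()` reimplements the TCGA-style endometrial classification
as a strict precedence cascade; every sample receives exactly one label.

1. **POLE**: at least one nonsynonymous POLE mutation with protein position
   in the exonuclease domain **and** supporting signature exposure. The
   domain is fixed at residues 268–471, the standard definition. Signature
   support means the summed exposure fraction of SBS10a/SBS10b/SBS14
   reaches `signature_fraction_threshold`.
2. **MSI**: an upstream microsatellite-instability flag on the annotation
   takes precedence when present (read-level MSI callers are out of scope;
   their verdict enters as data). Without a flag, the summed fraction of
   SBS6/SBS14/SBS15/SBS20/SBS21/SBS26/SBS44 is compared to the same
   threshold.
3. **CIN vs GS**: the fraction of the covered genome in segments whose
   copy-number change is at or below $-R_1 \cdot \text{purity}$
   ($R_1 = 0.36$, boundary inclusive, deletions only — the rule is about
   *deleted* genome). CIN when that fraction exceeds $R_2 = 0.034$, GS
   otherwise.

Parameter notes, units and defaults:

* `r1 = 0.36` is on the linear copy-ratio-change scale (not log2), applied
  to `seg_value` as read from SEG-style input.
* **Purity normalization direction.** A clonal one-copy deletion in a
  sample of purity $\rho$ shows an apparent change of roughly $\rho$ times
  the pure-tumor change, so the detection threshold must *shrink* with
  purity: effective threshold $= R_1 \rho$. The multiplicative reading is
  the default; `subtype_params(purity_normalization = "divide")` switches
  to the alternative for sensitivity analyses, since prose descriptions of
  "normalizing by purity" are ambiguous between the two.
* `signature_fraction_threshold = 0.2` (dimensionless fraction of the
  sample's mutations). No published value exists for this evidence
  threshold; 0.2 is low enough to accept genuinely signature-dominated
  samples (POLE and MSI tumors typically attribute well over half of their
  load to their characteristic signatures) and high enough that NNLS
  crosstalk between unrelated catalog columns does not produce spurious
  calls. It is an explicit, reported parameter, not a constant.
* **Signature attribution** is non-negative least squares
  (`pracma::lsqnonneg`) of the 96-channel spectrum onto a fixed catalog —
  deterministic and sufficient for the cascade's presence/absence
  decisions; Bayesian NMF-style de novo discovery is out of scope. When
  catalog columns are collinear only sums of the affected exposures are
  identifiable, which the tests assert explicitly.
* The 96 channels use the conventional pyrimidine-strand order
  (six substitution types × 16 trinucleotide contexts); purine-strand
  records are reverse-complemented on entry and a context whose middle base
  contradicts the reference allele is an error, not a silent fix.

## Clonality, timing, early events

A mutation is clonal iff its cancer cell fraction is at least 0.95
(boundary inclusive; CCF estimation itself — e.g. by ABSOLUTE — is an
upstream concern and enters as a column). In a genome-doubled sample, a
clonal mutation at multiplicity ≥ 2 is called pre-WGD and multiplicity 1
post-WGD; this multiplicity rule is a deliberate simplification of
probabilistic event-ordering frameworks, adequate for counting but not for
full trajectory inference.

"Early events per sample" are counted at **gene level**: a sample with two
clonal mutations in one early driver gene has one event. That is the
reading consistent with the small-integer event axes such comparisons plot;
`per_mutation = TRUE` switches to mutation-level counting. The early-driver
panel is an input list — the package makes no attempt to re-derive which
drivers are "early" from timing models. `compare_early_counts()` reports
both the plain two-sided rank-sum comparison and the shifted comparison
(exposed counts + $s$ vs control) that asks whether a deficit exceeds $s$
events; $s = 1$ by default.

## ddPCR and background expectation

Allele fraction is mutant droplets over total droplets × 100; a well is
positive strictly above the 2% cutoff (a well at exactly 2.0% is negative),
a threshold chosen to suppress FFPE deamination artifacts. The hotspot
panel defaults to PIK3CA E542K/E545K/H1047R.

`expected_background_cases()` encodes the observation that if exposure
multiplies absolute risk from $r_0$ to $r_1$, a fraction $r_0/r_1$ of
exposed cases would have occurred anyway: with the default risks 0.005 and
0.025 (a fivefold increase over a ten-year horizon), 21 exposed cases give
4.2 expected background cases, presented as 4. The quantity is linear in
the case count and invariant under common rescaling of both risks.

## The synthetic-data generator

`simulate_cohort_pair()` draws the paired cohorts every downstream stage is
tested on. Its defaults *are* the study conditions: 21 exposed vs 554
control samples; per-gene Bernoulli mutation indicators at frequencies
emulating the discovery comparison (PIK3CA 0.14 vs 0.48, PIK3R1 0.00 vs
0.31, with PTEN/TP53/ARID1A/KRAS/CTNNB1/FGFR2 near-equal across cohorts); a
TCGA-like subtype mix (7% POLE, 28% MSI, 26% CIN, 39% GS); uniform purity
on (0.3, 0.9); subtype-dependent deleted fractions (0.15 for CIN, 0.01
otherwise) built from 1-Mb-granular segments that clear the $R_1$ threshold
by a safe margin; an 80%-clonal CCF mixture whose clonal values are clamped
at or above 0.95 and whose subclonal values stay below 0.93, so planted
labels are exactly recoverable; signature mixtures per subtype
(SBS10a-dominated for POLE, SBS6-led for MSI, aging signatures for CIN/GS)
from which each mutation's trinucleotide context is drawn; WGD status at
25% with pre-doubling mutations at multiplicity 2; and binomial ddPCR
droplet counts. Mean mutation loads are 600/300/90/80 per sample for
POLE/MSI/CIN/GS — the hypermutated subtypes are kept an order of magnitude
above the others rather than at their real (thousands-scale) loads, which
changes nothing the classifier consumes (it uses fractions, not totals).

One global seed drives a single random stream; the same configuration
writes byte-identical fixture files. The generator intentionally does *not*
emulate: sequence-level reads or calling error, per-gene mutation-rate /
territory modeling (frequencies are specified directly), co-mutation
correlation structure (indicators are independent Bernoulli by default),
subclonal copy-number, or tumor-specific signature noise. Passing tests on
generator output therefore demonstrate the correctness of the statistical
machinery under its stated assumptions — not robustness to the artifacts of
real calling pipelines, which must be handled upstream.

Because real COSMIC signature profiles are not bundled,
`synthetic_signature_catalog()` provides a clearly labelled synthetic
catalog: 13 sparse random simplex columns carrying the signature names the
cascade expects. It is for simulation and testing; real analyses should
load a published catalog through `read_signature_catalog()`.

## Numerical choices and degenerate inputs

* Hypergeometric pmfs are renormalized per margin; two-sided sums that
  cover the whole sample space snap to exactly 1.
* Point-probability comparisons use the $1 + 10^{-7}$ relative tolerance
  everywhere (2×2, stratified convolution, r×c Monte Carlo), so the same
  tie-handling applies across tests.
* Degenerate margins (an empty group, $m = 0$, a one-table sample space)
  yield $P = 1$ rather than an error; degenerate rank-sum inputs (all
  values tied) yield $P = 1$.
* `min_detectable_count()` returns `NA` with a message when no count up to
  $n_2$ crosses $\alpha$ (e.g. 1-vs-1 cohorts, where the best one-sided $P$
  is 0.5).
* The deleted-fraction boundary is inclusive ($\le -R_1\rho$); the CIN/GS
  split is strict ($> R_2$); the CCF clonality boundary is inclusive
  ($\ge 0.95$); the ddPCR cutoff is strict ($> 2\%$).
* Duplicate MAF records (same sample/gene/position/alternate allele) are
  collapsed with a warning rather than rejected — they are a common
  artifact of merged call sets.

## Problem sizes used by the test suite

The suite verifies the exact machinery by exhaustive enumeration for all
2×2 margins with total ≤ 60, checks Monte Carlo r×c convergence at 2×10⁵
iterations against full enumeration of small tables, runs the null
calibration of the two-sided test over 2,000 simulated 21-vs-554 tables,
and exercises the generator at 5–25 samples per cohort with reduced
passenger loads. These sizes were chosen to keep the full suite under a few
minutes while leaving every property's verification exhaustive or
statistically conservative at its scale.

## Limitations

* Purity, ploidy, WGD status, CCFs and multiplicities are inputs; the
  package neither infers them nor propagates their uncertainty.
* The Bonferroni divisor of the power gate is supplied by the user, since
  the upstream driver screen that defines the hypothesis set is out of
  scope.
* The stratified test is exact-conditional only; for very large strata a
  score-test variant would be cheaper, but the convolution is exact and
  fast at cohort scales of interest.
* NNLS attribution assumes the catalog is correct and complete; exposures
  to signatures absent from the catalog are forced onto the nearest
  available columns.
* The shifted rank-sum comparison treats the shift as exact and integral;
  it tests "larger than $s$ events" only in the stochastic-ordering sense
  of the rank-sum test.
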