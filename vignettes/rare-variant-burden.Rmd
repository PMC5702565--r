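---
title: "Methods: rare-variant burden, consequence and ancestry analysis for PPROM cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant burden, consequence and ancestry analysis for PPROM cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppromburden)
```

## The study design this package models

Preterm premature rupture of membranes (PPROM) is the leading identifiable
cause of preterm birth. The design implemented here contrasts fetal/neonatal
DNA from PPROM pregnancies against term controls at a fixed panel of
candidate genes involved in innate immunity and host defense, asking whether
rare damaging alleles are collectively overrepresented in cases. The
modelled cohort combines a whole-exome discovery set (76 cases / 43
controls) with a follow-up genotyping set (188 cases / 175 controls), giving
264 cases and 218 controls at 14 damaging variants; those numbers are the
package defaults wherever a cohort is simulated.

This is deliberately not a genome-wide method: with a handful of candidate
loci and allele frequencies in the 0.002–0.4 range, single-locus association
tests are hopelessly underpowered, and the analysis instead aggregates a
directional signal across loci.

## The burden test

Loci are treated as the paired units. For locus $l$,
$d_l = \hat p_{\text{case},l} - \hat p_{\text{control},l}$, where each
$\hat p$ is an alt-allele count over called chromosomes (missing genotype
calls are excluded from both numerator and denominator; `locus_freq()`
refuses to compute a frequency for a group with no calls at all rather than
silently returning 0/0).

The statistic is the Wilcoxon signed-rank sum
$W^+ = \sum_{l : d_l > 0} \operatorname{rank}(|d_l|)$ with midranks for tied
$|d_l|$. Two zero-difference conventions are exposed because published
analyses rarely state which they used:

* `zero_policy = "drop"` (default): zeros are removed before ranking — the
  classical Wilcoxon convention;
* `zero_policy = "pratt"`: zeros participate in the ranking but never count
  toward $W^+$ and never flip sign.

The null distribution is generated by independent random sign flips of the
nonzero $d_l$ — exchangeable signs are exactly what "no systematic
case/control difference" means here — and the empirical p-value uses the
add-one estimator $(1 + r)/(B + 1)$, which is never exactly zero and guards
the bias of reporting $0/B$. `exact_signflip_p()` computes the same null
exactly by dynamic programming over the (doubled, hence integer) rank
values, feasible for up to 20 nonzero differences; the permutation estimate
is required (and tested) to converge to it.

Sidedness is configurable. The default is one-sided `greater` because the
scientific hypothesis is directional (overrepresentation in cases). On the
study's own frequency table ($W^+ = 79$, 13 nonzero differences) the exact
one-sided p is 0.0081 (drop) / 0.0092 (Pratt) and the exact two-sided p is
0.0161 (drop) / 0.0183 (Pratt), all rejecting at 5%, while the study printed
an empirical p of 0.0416 from 10,000 permutations. The printed procedure's
sidedness, zero handling and input-frequency provenance are unstated, so no
single reconstruction can be declared "the" published one;
`reproduce_reported()` therefore runs the full sidedness × zero-policy grid
and compares each variant to the published value within a ±0.025 procedural
band, which the two-sided include-zeros variant meets.

A subtle numerical point: the paired differences are rounded to 12 decimals
before zero detection and ranking. Frequencies that print as a tie (0.374
vs 0.376 against a 0.002 difference elsewhere) otherwise differ at the
$10^{-18}$ level in binary floating point, breaking midranks and shifting
$W^+$ by a full unit.

### Direction tally

`classify_direction()` calls a locus case-higher, control-higher or similar
with a configurable absolute tolerance, default 0 (only exact equality is
"similar"). Under the strict default the study's table gives 10
case-higher / 3 control-higher / 1 similar. A narrative grouping that calls
a 0.374-vs-0.376 pair "similar" while calling 0.002-vs-0.003
"control-higher" corresponds to no single threshold, so the tally's
tolerance is a reporting knob, not part of the statistic.

## Ancestry estimation

Population stratification is the standard confounder of a case/control
frequency comparison, so the design checks ancestry balance between groups.
Each individual's admixture proportion $\theta$ (toward ancestral
population A, here the West African component of a two-way
European/West-African model) is estimated by maximum likelihood over a
panel of ancestry-informative markers (AIMs) with known ancestral allele
frequencies:
$\ell(\theta) = \sum_m \log \binom{2}{g_m} p_m^{g_m} (1-p_m)^{2-g_m}$ with
$p_m = \theta p_{A,m} + (1-\theta) p_{B,m}$.

Numerical choices:

* $\ell$ is concave (log of an affine function of $\theta$ per genotype
  term), so bounded golden-section search on $[0,1]$ finds the global
  maximum; the endpoints are additionally evaluated explicitly and boundary
  maxima are reported as converged estimates. Convergence tolerance on
  $\theta$ defaults to $10^{-6}$; tests verify agreement with a
  $10^{-4}$-step grid search.
* Ancestral frequencies are clamped into
  $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-3}$ by default, so a
  marker with a fixed reference frequency cannot send the likelihood to
  $-\infty$ on a single discordant genotype. How the original analysis
  smoothed its reference panel frequencies is unknown; the clamp is this
  package's choice and can be disabled (`clamp_eps = 0`).
* Markers with missing genotypes are dropped per individual; no imputation.
* A panel with $p_A = p_B$ everywhere is flagged non-identifiable rather
  than returning an arbitrary interior optimum.

With the default study-scale panel (102 markers, mean absolute ancestral
frequency difference $\delta = 0.733$), the estimator's RMSE at
$\theta = 0.70$ is well under 0.1 — tight enough to support the
group-balance check (`ancestry_balance()`, Welch t on the per-group
$\hat\theta$), though not individual-level precision claims.

## Consequence calling

`call_consequence()` operates on CDS coordinates of explicit transcript
models (`transcript_model()`: in-frame CDS from ATG through stop, no
internal stop, optional named domain intervals). Classification is by
translation comparison of the reference and edited CDS:

* an edit that destroys the initiator ATG is a start-loss;
* a length change not divisible by 3 is a frameshift, with the truncation
  reported at the first stop codon reached in the shifted frame (absent if
  none occurs before the CDS end);
* an in-frame edit whose translation stops earlier than the
  length-adjusted expected terminal stop is a nonsense call at that
  position — the length adjustment matters, because any in-frame deletion
  moves the terminal stop earlier without being a stop-gain;
* otherwise synonymous / missense (with residue change) / in-frame indel.

Genomic-to-CDS projection, splicing and strand are out of scope: the
package classifies on transcript coordinates, which is where the bespoke
logic lives and where it can be verified exhaustively at desk scale against
a brute-force translation oracle. Only the standard nuclear code is used
and only ATG is accepted as a start. Indels follow VCF anchored-base
conventions. `domains_affected()` partitions domains into retained
(end before the truncation), lost (start at or after it) and partial;
`truncated_fraction()` is the removed-residue fraction
$(L - t + 1)/L$.

`select_damaging()` implements the inclusion rules: truncating classes
always; in consensus mode additionally missense variants labelled
"probably damaging" by PolyPhen2 (HumDiv) *and* "damaging" by SIFT. The
predictors themselves are upstream tools whose labels are consumed as
input, never recomputed; selection is monotone in the mode.

## Demographics

`t_from_summary()` computes two-sample t-tests directly from (mean, SD, n),
because published cohort tables provide only summaries. The default is the
pooled-variance Student test: it reproduces the modelled study's printed
maternal-age p-value (0.256) exactly at 3 decimals, and "Student's t-test"
is what that study reports using; the Welch variant differs only in the
fourth decimal here (0.2566 vs 0.2561) and is exposed as
`welch_t_from_summary()` (raw-data paths delegate to `stats::t.test()`).
Count variables (gravidity, parity) are square-root transformed before
testing (`sqrt_count_test()`); their published p-values are *not*
recomputable from summaries, since the transform precedes summarisation,
and the demographics table reports NA for them rather than a pseudo-check.
One anomaly is carried as-is: the cases' neonatal-weight SD (1.59 kg at
mean 1.69 kg) is implausibly large for the cohort; the table recomputes
from the printed values without correcting them.

`detection_power(f, n)` $= 1 - (1-f)^n$ is the probability that at least
one copy of an allele at frequency $f$ appears among $n$ sampled
chromosomes. Evaluated at $f = 0.005$ it rounds to the modelled study's
printed 78% at $n = 304$ chromosomes — not at the study's "152
chromosomes" phrasing ($1 - 0.995^{152} \approx 53\%$). The package
implements the formula; the bundled reported-figures table records
$n = 304$ as the count that reconciles the printed percentage.

## The synthetic-cohort generator

`gen_cohort()` draws alt-allele dosages per group at planted loci:
Hardy-Weinberg draws (Binomial(2, f)) for common loci, strictly
heterozygous carriers (carrier probability 2f) for rare loci — matching the
modelled study, where every damaging variant was heterozygous except the
common FUT2 stop allele — and missing-completely-at-random genotype masking.
The default missing rate is 0.02, a typical array/iPLEX no-call rate; the
modelled study does not state one. The default loci are the study's 14
variants at their reported frequencies. `gen_aims()` is the exact forward
simulation of the admixture model above; `gen_panel()` builds panels hitting
a target $\delta$ (default 102 markers, $\delta = 0.733$) by rescaled
uniform frequency differences placed uniformly in $[0,1]$.

What the generator deliberately does **not** emulate: linkage
disequilibrium between loci, relatedness, batch or platform genotyping
error structure, informative missingness, ancestry-correlated allele
frequencies at the candidate loci, and read-level sequencing artefacts.
Passing tests therefore demonstrate that the estimators and tests are
correct *under the stated sampling model* — unbiased frequency recovery,
nominal type-I error, consistent $\hat\theta$ — not that real cohorts are
free of the confounders the model omits.

## Verification strategy and problem sizes

Every nontrivial computation is checked against an independent route: a
hand-built codon table and full protein comparison for consequence calls
(1,000 random transcript/variant pairs); dense grid search for the
ancestry MLE (100 random instances, $10^{-4}$ grid); full sign-matrix
enumeration and the closed forms $1/8$, $1/2^{10}$ for the exact sign-flip
distribution; `stats::t.test()` for summary-based t-tests. Calibration runs
use 1,000 null cohorts at the full study size (264/218, 14 loci, 200
permutations each) for the burden test's type-I error and replicate-cohort
averages (50–200 replicates) for frequency recovery; these sizes give 3-standard-error bands
tight enough to detect a miscalibrated test while keeping the default suite
around a minute.

## Limitations

* The burden test conditions on the locus panel; it does not model locus
  discovery, so its p-value inherits any winner's-curse in how the panel
  was assembled.
* Ancestral AIM frequencies are treated as known; their sampling error is
  not propagated into $\hat\theta$.
* The consequence caller is transcript-local: multi-exon genomic
  coordinates, splice-site effects and strand handling are out of scope.
* No covariate-adjusted association model is provided; ancestry enters only
  as a balance check, not as an adjustment.
* Reproduction mode re-derives figures from published tables at their
  printed precision; figures requiring raw genotypes or pre-transform raw
  counts (group ancestry means, gravidity/parity p-values) are out of its
  reach by construction.
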