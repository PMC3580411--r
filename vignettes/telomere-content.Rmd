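---
title: "Measuring telomeric DNA content change from whole-genome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring telomeric DNA content change from whole-genome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telcontent)
```

## The measurement

Telomeres are tandem arrays of the hexamer `TTAGGG` capping chromosome
ends. In a whole-genome sequencing (WGS) library, DNA from those arrays
shows up as reads that consist almost entirely of the repeat, and the
number of such reads scales with the total amount of telomeric DNA in the
sample. `telcontent` turns that into a tumor-vs-normal statistic in three
steps.

**1. Motif-read counting.** A read is telomeric when it contains the
exact, contiguous 24-mer `(TTAGGG)4` or its reverse complement
`(CCCTAA)4` anywhere in its sequence. Matching is deliberately strict:

* exact and contiguous — no mismatches, no interrupted copies. Four exact
  copies in a 100 bp read is a stringent enough signature that chance
  hits in non-telomeric sequence are vanishingly rare (for uniform
  background the per-read probability is about
  `2 * 77 * 4^-24 ~ 5e-13`), so there is no need for a fuzzy match and no
  tuning parameter to argue about;
* `N` never matches — an uncalled base is not evidence of the repeat;
* a read counts once however many copies or orientations it contains:
  the quantity of interest is "reads containing the repeat", which is
  what scales with telomeric DNA abundance at fixed read length;
* case is normalized away, since FASTQ/BAM case carries no meaning.

For aligned input the default filters drop duplicate, QC-fail, and
secondary/supplementary records (each physical read is seen at most
once), but keep unmapped reads: genuinely telomeric reads often fail to
align to the reference assembly, and dropping them would throw away most
of the signal. All four filters are flags on `read_filters()`. FASTQ
input has no flags, so every read is retained, and the two mates of a
pair are counted independently — reads, not fragments, are the unit.

**2. Coverage normalization.** Tumor and normal libraries are sequenced
to different depths, so raw counts are not comparable. The telomeric
read count is divided by the mean fold coverage,

$$c = \frac{\text{total bases of retained reads}}{\text{genome length}},$$

giving "telomeric reads per fold coverage" (`normalize_count()`). The
default basis uses *all* retained read bases rather than aligned bases,
for the same reason unmapped reads are kept: the numerator's reads are
largely unaligned, and using the same filtered stream for numerator and
denominator treats tumor and normal identically. An `aligned_bases`
basis (sum of reference-aligned bases from CIGARs) is available for BAM
workflows. The genome length is a scalar (e.g. `3.1e9`) or the contig
total of a FASTA `.fai` index via `genome_length_from_fai()`; whether
that length includes assembly N-gaps is the caller's choice of index.
No GC correction is applied: the motif read population sits near
ordinary genomic GC content, where Illumina abundance estimates are
essentially unbiased.

**3. The pair statistic.** For a tumor and its matched normal,

$$\Delta T = \log_2 \frac{T_t / c_t}{T_n / c_n}.$$

Using the *matched* normal cancels both inter-individual telomere-length
heterogeneity and age effects; using normalized counts cancels depth.
$\Delta T > 0$ is a relative gain of telomeric DNA in the tumor,
$\Delta T < 0$ a loss. If either normalized count is exactly zero, a
pseudocount (default 0.5) is added to **both** terms so the ratio stays
finite; nonzero pairs are never perturbed, and the record carries a
`pseudocount_used` flag. `delta_t()` refuses to combine samples counted
under different motif or filter settings.

## Classifying a cohort: mixture model, BIC, ternary calls

Many tumors have $\Delta T$ near zero — library-preparation and
sequencing noise, not biology. To separate signal from that noise the
cohort's $\Delta T$ values are modeled as a univariate Gaussian mixture.
`select_model()` fits every combination of $G \in \{1,2,3,4\}$
components and equal/unequal variance structure and keeps the fit with
the largest BIC, using the model-based-clustering convention

$$\mathrm{BIC} = 2\,\ell - p\,\ln n,$$

with $p$ the free-parameter count ($G-1$ weights, $G$ means, one shared
or $G$ variances); larger is better, and exact ties break toward fewer
components, then equal variance. On cancer cohorts the expected winner
is $G = 2$ with equal variance — a lower (loss) and an upper (gain)
component — but the selection is data-driven and the grid is not
restricted to that outcome.

Calls are then made from one-sided tail probabilities at significance
$\alpha$ (default 0.01, $z_{0.99} \approx 2.326$):

* **gain** — the sample rejects the *lower* component through its upper
  tail: $\Delta T > \mu_{low} + z_{1-\alpha}\sigma_{low}$;
* **loss** — the sample rejects the *upper* component through its lower
  tail: $\Delta T < \mu_{high} - z_{1-\alpha}\sigma_{high}$;
* **no change** — neither.

The two thresholds are cohort-level constants (`gain_boundary`,
`loss_boundary`), so the calls partition the $\Delta T$ axis into
loss / no-change / gain, in that order. Two conventions here were
genuinely open and are resolved as follows. First, "reject the first /
second cluster" is mapped so that the *gain* boundary comes from the
lower component and the *loss* boundary from the upper one — the only
mapping that produces a lower and an upper cutoff on the $\Delta T$
axis. Second, the tails are one-sided (a two-sided variant sits behind
`two_sided = TRUE`): the alternative on each side is directional by
construction.

When the components are separated by more than
$2 z_{1-\alpha}\sigma$, the boundaries cross and values between them
reject *both* components. Those samples are assigned by maximum
posterior probability (lower component to loss, upper to gain), with a
warning; the assignment preserves the loss → no-change → gain ordering
because the posterior crossover lies between the means.

### EM details

`fit_mixture()` is a standard univariate EM with a few deliberate
numerical choices:

* initialization from a hard partition — evenly spaced quantiles for the
  first restart, random draws for the remaining nine, each refined by
  one-dimensional k-means. Restarts whose k-means partition coincides
  would retrace the same EM path, so only distinct partitions are
  iterated; the "best of 10 restarts" semantics is unchanged while most
  of the redundant work disappears;
* convergence at relative log-likelihood change below `1e-8`, capped at
  1000 iterations; the log-likelihood trace is stored on the fit and its
  monotonicity is asserted in the test suite;
* a variance floor of `1e-6` prevents a component collapsing onto a
  single point;
* components are relabeled so means ascend — weights, variances and
  calls are invariant to label permutations.

$G = 1$ skips EM entirely: the maximum-likelihood solution is the
sample mean and biased sample variance, in closed form.

## Association statistics

`rank_sum_test()` is the unpaired Mann-Whitney/Wilcoxon rank-sum test
(the appropriate choice for independent groups such as burden by
telomere status or pediatric vs adult normals; a paired signed-rank
variant is available behind `paired = TRUE`). The exact null
distribution is enumerated when the pooled sample size is at most 20
and tie-free; otherwise the tie-corrected normal approximation with
continuity correction is used — the two branches agree to well under
0.01 in p at the crossover sizes. A fully tied pool returns $p = 1$
(no evidence either way), and an empty group returns a not-applicable
result with `NA` statistics rather than an error, so cohort strata with
no gain samples propagate cleanly through `burden_by_status()`. Raw
p-values are reported; no multiple-testing correction is applied.

`burden_by_status()` compares the gain group against loss and no-change
pooled — the scientific question is whether telomere gain marks genomic
instability — and `status_fractions()` tallies call percentages per
disease group. `concordance()` implements two validation-style rules:
against a continuous external log-ratio (qPCR-like), only gain/loss
calls are assessed and concordance is sign agreement; against a binary
normal/abnormal assay (FISH-like), gain maps to abnormal and everything
else to normal.

## The simulators, and what they do not emulate

`simulate_reads()` emits reads with known ground truth: exactly
`round(n_reads * telomere_fraction)` reads are `read_length` windows
into an infinite `TTAGGG` array with uniform phase, half of them
reverse-complemented so both search orientations are exercised;
background reads are i.i.d. uniform bases; independent per-base
substitution errors are applied at `error_rate`. The manifest records
the per-read labels, the exact emitted base total, and an md5 checksum;
identical parameters and seed reproduce the FASTQ byte for byte.
`simulate_pair()` scales the tumor's telomeric fraction by a known
multiplier, so the ground-truth $\Delta T$ is $\log_2$ of the
multiplier. `simulate_cohort_deltas()` draws cohort $\Delta T$ values
from a two-component equal-variance mixture (defaults: means $-0.5$ and
$1.0$, $\sigma = 0.3$, lower-component weight $0.7$, $n = 235$ — a
bimodal structure with component separation typical of a mixed
pediatric-cancer cohort) with the generating labels recorded.

Defaults mirror the intended use: 100 bp reads, substitution error rates
in the fraction-of-a-percent range typical of Illumina basecalls.
Deliberate simplifications, and hence limits on what passing tests show
about real data: no indels (the exact-match counting rule is probed by
substitutions alone), no GC or fragment-size bias, no quality-score
structure (constant `I`, never consulted), no alignment simulation (the
flag-filtering path is exercised with hand-written SAM fixtures
instead), and uniform background rather than human genome sequence — in
particular, interstitial telomeric repeats, which inflate real counts
additively in both tumor and normal, are absent. Because the telomeric
read count at zero error is exact rather than binomial, sampling
variability in the simulated $\Delta T$ comes only from the error
channel; the reproducibility and recovery tests therefore probe the
pipeline's systematic behavior, not library-sampling noise.

## Problem sizes and runtime choices

The validation suite runs the full pipeline at sizes chosen to exercise
asymptotic behavior while staying desk-scale: twenty libraries of
10^4–10^5 reads for oracle-equivalence checks; 10^5-read tumor/normal
pairs for $\Delta T$ recovery at multipliers 0.5/1/2; one hundred
bimodal and one hundred unimodal cohorts of $n = 235$ for BIC selection
rates; 2000 null replicates at $n = 50$ per group for rank-sum type-I
calibration; fifty same-parameter library pairs for reproducibility.
The acceptance script repeats the same computations at moderately
reduced replicate counts.

## Known limitations

* The method measures *content change*, not telomere length in kb, and
  cannot resolve per-chromosome lengths or separate interstitial from
  terminal repeats — matched-pair differencing removes the interstitial
  contribution only to the extent it is copy-neutral.
* Exact matching undercounts telomeric reads at high error rates; this
  affects tumor and normal nearly symmetrically and so largely cancels
  in $\Delta T$, but absolute normalized counts should be compared only
  across libraries of similar quality.
* Classification assumes the cohort is heterogeneous enough for a
  two-component structure to emerge; `classify_samples()` refuses
  fits with $G \neq 2$ rather than guessing.
* CRAM input is passed through to Rsamtools and may require an external
  reference to decode.
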