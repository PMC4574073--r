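---
title: "Calling tandem repeat instability in paired tumor-normal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tandem repeat instability in paired tumor-normal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatcohort)
```

## The problem

Microsatellites and minisatellites — tandem arrays of a 1–100 bp unit —
mutate by replication slippage, which adds or removes whole repeat units.
In tumors with defective mismatch repair (the MSI phenotype) this process
accelerates, and repeat mutations in gene promoters or exons can silence or
dysregulate the gene. `repeatcohort` implements a genome-region survey of
this process for cohorts of tumor genomes with matched normal (same-patient)
genomes:

1. detect tandem repeats in each genome's promoter and exon
   super-transcript regions;
2. pair the repeats of the two genomes of a patient and classify each as
   *stable*, *unstable* (copy-number change of at least one full unit) or an
   *orphan* (present in only one genome: a de-novo gain or a loss);
3. compare the per-pair numbers of genes carrying each instability type
   against a between-individual null built from **all** unordered pairs of
   normal genomes (35 normals give `choose(35, 2) = 595` pairs), with
   Wilcoxon rank-sum (WRS) tests; split tumors by MSI status; and test
   cancer-pathway gene sets for enrichment;
4. per gene, compare its mean expression (and promoter methylation) between
   tumors where the gene shows instability and tumors where it does not,
   with a paired Wilcoxon signed-rank (WSR) test across genes.

Because the original cohorts of this design are controlled-access, the
package ships a synthetic cohort generator that plants repeats with known
slippage, gain and loss events and coupled expression/methylation effects,
so that every stage can be tested against ground truth.

## Repeat detection

A candidate repeat is a window of the sequence together with a period $p$.
The window is scored by **global wraparound alignment** against cyclic
concatenations of a $p$-mer unit: matches score $+2$, mismatches $-7$ and
indels $-7$ (the classical tandem-repeat-finder weights; the alignment must
consume a whole number of units, at least two). A window is emitted when

* the alignment score is at least `min_score = 80` (so a perfect array must
  span at least 40 bp),
* unit identity — matches over aligned unit positions — is at least 0.90,
* the indel incidence per adjacent-unit junction is at most 0.10,
* the period is at most 100 bp, and the window is at most 10 % `N`.

`N` bases match nothing. Overlap resolution removes redundant
interpretations: among overlapping candidates with the same canonical unit
(the lexicographically minimal rotation) only the best-scoring survives, and
candidates with different units may co-exist only below 50 % overlap of the
shorter. Reported coordinates are 0-based and half-open, relative to the
region.

Two design choices deserve mention. First, the unit used for scoring a
candidate window is the window's *leading* $p$-mer; the reported consensus
pattern (the most frequent in-phase unit, ties broken lexicographically) is
recomputed on accepted windows. Scoring against a consensus defined by the
alignment itself would be circular; anchoring on the leading unit makes the
search criterion explicit, and for arrays within the 90 % identity threshold
the two rarely differ — when the leading unit is the mutated one, the
best-scoring accepted window simply starts one unit later. Second, the
package contains **two search strategies with identical acceptance rules**:
an exhaustive sweep over every (start, period) pair, and a seeded search
that restricts candidate starts to neighbourhoods of exact lag-$p$ match
runs (any array passing the identity threshold contains such runs). The
seeded search makes 5 kb promoters tractable; `find_tandem_repeats_brute()`
additionally re-scores every (start, length, period) triple independently
and serves as the exhaustive reference that the detector is tested against.
The seeded search may in principle trim heavily degenerate array flanks that
the exhaustive sweep would keep; the test suite compares the two on hundreds
of randomly planted, randomly mutated arrays.

```{r detect-example}
find_tandem_repeats(paste0(strrep("TTAGGC", 3), strrep("CA", 25)))
```

## Matching and classification

Repeats of two genomes are paired per gene region when they have the same
canonical unit and their starts differ by at most 50 nt (indels shift repeat
positions, hence the window). Candidate pairs are accepted greedily by
increasing positional distance (ties: higher summed score, then lower
start), one-to-one. Matched pairs with a copy-number difference of at least
`unstable_min_delta = 1` full unit are unstable; the one-unit default guards
against fractional copy-number jitter from array-boundary trimming and is
exposed as a parameter. Unmatched repeats are orphans. A gene counts once
per instability type however many qualifying repeats it carries; the
mononucleotide sub-tallies count only repeats whose canonical unit is a
single base. Reverse-complement units are *not* identified by default
(`match_revcomp = FALSE`): the regions are strand-oriented, and folding
strands would merge e.g. poly-A with poly-T promoter tracts, which have
different regulatory interpretations; a switch is provided.

Orphan status is window-scoped: a repeat is an orphan when no same-unit
repeat lies within the 50-nt window in the partner genome, even if one
exists elsewhere in the region — matching semantics, chosen because the
event of interest (gain/loss at a locus) is positional.

Genome-level QC precedes all of this: a genome whose promoter positions (or
exon positions) are more than 10 % unaligned (`N`) is removed entirely;
exactly 10 % passes.

## Cohort statistics

Per-pair gene counts are compared between the 35 tumor–matched-normal pairs
and the 595 pooled normal-normal pairs by two-sided WRS tests. The test is
exact (permutation distribution) when the smaller group has at most 8
observations and there are no ties, otherwise the normal approximation with
tie and continuity correction is used. The MSI-vs-MSS comparison runs the
same test within the tumor-normal pairs over a family of four panels
(promoter/exon, any/mononucleotide instability) with Bonferroni correction
(`m = 4`). Pathway enrichment tests per-pair *proportions* of pathway genes
carrying unstable (or orphan) repeats, Bonferroni-corrected over pathways
times event types; the proportion denominator is all pathway genes in the
analyzed universe, not only repeat-bearing genes (the more conservative and
more stable choice; configurable).

The expression scheme follows the gene-by-patient instability matrix: only
genes with instability in at least one patient enter; per gene the mean
expression over instability-flagged tumors and over the remaining tumors is
computed, log2-transformed (`log2(mean + 1e-6)`, epsilon for zero means),
and the paired values are tested across genes by a two-sided WSR test (exact
up to 25 nonzero untied differences). Genes flagged in all tumors have no
comparison group and are excluded. Methylation uses the identical scheme on
beta values without the log transform. Expression is compared across tumors
only; no tumor-vs-normal expression contrast is computed.

### Known calibration limits of the published design

Two properties of this design are worth knowing, and both are demonstrated
by the package's own null simulations (all generative effects zero):

* **The 595 normal-normal pairs are not independent** — every normal genome
  participates in 34 pairs. The WRS test treats them as 595 independent
  observations and therefore underestimates its null variance; the
  tumor-vs-normal comparison rejects a true null at roughly 5-6 times the
  nominal rate in our null simulations. The MSI-vs-MSS comparison uses 35
  disjoint pairs and is calibrated.
* **Log-of-mean is Jensen-biased by group size.** `log2(mean of k values)`
  is biased downward, and more so for small $k$; since the instability
  group is typically much smaller than its complement, the paired
  differences have a systematically negative median under a true null and
  the WSR test rejects far above nominal (direction "down"). The
  methylation scheme, which skips the log, is calibrated. For expression,
  `expression_association(..., aggregate = "mean_of_log")` provides a
  calibrated alternative; the default remains log-of-mean, matching the
  published scheme, so its p-values should be read as summaries of a large
  planted effect rather than as calibrated error rates.

## The synthetic cohort generator

`sim_config()` describes the study conditions; the defaults are the
conditions under which the package's acceptance tests run: 200 genes and 35
patients of whom 4 are MSI (the cohort split of the survey this package
operationalizes), a 5,000 bp promoter and one exon super-transcript
(500–1,500 bp) per gene, repeats planted in 60 % of promoters and 40 % of
exons, unit lengths drawn from a distribution heavily skewed toward 1–6 bp
(45 % mononucleotide), and copy numbers high enough that every planted
array stays above the 40 bp detectability minimum with one unit of slack.
Backgrounds are i.i.d. uniform A/C/G/T, rejection-sampled so that neither
the background nor the composed region contains any detectable repeat other
than the planted one — this keeps the truth table exhaustive.

Mutation model, per locus:

* **Germline layer.** Each patient's normal genome receives private
  slippage, gain and loss events at *half* the configured normal-normal
  rates, so two unrelated normals differ at approximately the configured
  rates (`p_slippage_normal = 0.016`, `p_gain_normal = 0.01`,
  `p_loss_normal = 0.006`). Germline gain and loss rates are included so
  that the normal-normal null has orphan repeats at all, as observed in
  real cohorts; without them the null would be degenerate at zero.
* **Somatic layer.** The tumor derives from the patient's normal with
  copy-number changes at `p_slippage_tumor = 0.08` (five times the
  normal-normal rate, times `msi_rate_multiplier = 10` for MSI patients,
  capped at probability 1), de-novo gains at `p_gain = 0.05` in regions
  with no repeat in the normal, and losses at `p_loss = 0.03`.
  The original study reports no per-locus rates, so these are free
  parameters chosen once for statistical power at $n = 35$; they are not
  estimates of the biology.

Copy-number changes move by $\pm k$ whole units with $k$ geometric
($p = 0.5$, so mostly one unit — slippage predominantly changes a single
unit), clamped so arrays never fall below the detectability minimum (a
downward move that would cross it is flipped upward; this also guarantees a
recorded copy change is never observed as a loss). Events are mutually
exclusive per (gene, patient, region) — loss takes precedence over
slippage, and gains are planted only where the reference has no repeat — so
the truth table has exactly one row per key and truth-recovery
precision/recall are well defined. Planted repeats are perfect; imperfect
arrays are exercised by detector tests, not by the cohort simulator, which
keeps truth unambiguous.

Expression is log-normal (`2^N(5, 0.7)` rpkm) with `expr_effect_log2 = -1`
added on the log2 scale for every (gene, patient) cell whose promoter
carries a somatic event — the effect is per cell, not per gene, matching
the instability-matrix comparison design. Methylation is
`beta = 0.3 + N(0, 0.05)`, shifted by `+0.1` for instability cells and
clamped to $[0, 1]$ (the spec of the generator has no noise parameter for
methylation, so the package adds `meth_base_sd`; without noise the null
comparisons would be degenerate). With within-gene noise of 0.7 log2 units
the planted −1 expression effect is recovered to within ±0.1 by averaging
the per-gene log2 differences over the ≈190 genes entering the analysis.

What the generator deliberately does **not** emulate: realistic human
sequence composition and repeat density, imperfect/interrupted repeats in
the cohort, sequencing errors and alignment artifacts, germline-vs-somatic
ambiguity, and subclonality. Passing tests on this cohort therefore
demonstrate the correctness of the detection, matching and statistical
machinery under the stated model — not robustness to the noise sources of
real tumor sequencing.

## Problem sizes used by the tests

The test-suite and acceptance computations use: 1,000 random sequences of
80–400 bp for detector-vs-reference equivalence (with planted, randomly
mutated arrays); one full sequence-level cohort at 200 genes × 35 patients
for truth recovery (detection over ≈84 Mbp); and 200 event-level replicates
at the same cohort size for power and null calibration, run through the
truth-derived repeat-call tables rather than re-detecting sequences — the
equivalence of those tables with detector output on planted cohorts is
exactly what the truth-recovery test establishes. Vectorised all-pairs
profiling is used when every (genome, gene, region, unit) carries at most
one repeat, which is always true for simulated cohorts; property tests pin
its equality with the greedy per-pair matcher.

## Numerical and degenerate-input conventions

* Alignment tie-breaks are deterministic: higher score, then more matches,
  then fewer indels, then fewer mismatches; candidate resolution orders by
  (score desc, period asc, start asc, end asc, canonical unit).
* An empty sequence yields an empty result; non-ACGTN characters are
  errors; an empty array scores 0 against any unit.
* All-equal groups give WRS p = 1; all-zero paired differences give WSR
  p = 1 with direction "none". Zero differences are dropped before ranking.
* Bonferroni caps at 1 and never decreases a p-value; family sizes are the
  figure-level families (4 MSI panels; pathways × event types).
* Identity/indel thresholds are applied inclusively (≥ 0.90, ≤ 0.10);
  the boundary can only matter for arrays sitting exactly on it.
* Every generator function derives an independent stream from
  `config$seed`, so `generate_expression()` is reproducible without
  re-running `generate_cohort()`.

## Limitations

Beyond the generator simplifications above: the detector's acceptance
criteria reproduce the published thresholds, not binary parity with any
particular tandem-repeat-finder build; greedy matching is compared against
optimal assignment only on small cases; and the two calibration caveats of
the published design discussed earlier apply to any cohort analyzed with
the default settings.
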