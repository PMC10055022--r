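---
title: "Methods and design notes for hybridplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for hybridplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridplan)
```

`hybridplan` implements the quantitative pipeline behind inbred-line and
F1-hybrid design in an outcrossing, self-incompatible leafy crop genotyped
at a few thousand biallelic SNPs. This vignette explains each model, its
assumptions, the tunable parameters, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## The data model

A genotype dataset is a tibble: `sample`, `population`, then one integer
column per locus with calls `0` (homozygous for allele A), `1` (homozygous
for allele B), `2` (heterozygous) and `NA` (no call). Two deliberate
conventions follow from the downstream methods:

- **Missing is a sentinel, never an allele.** The locus filter
  (`filter_complete_loci()`) keeps only loci with *zero* missing calls: with
  modest per-call dropout the completeness requirement across ~100 samples
  is severe (at a 1.2% per-call rate only about a third of loci survive),
  which is why per-sample dropouts are removed first
  (`drop_high_missing_samples()`, default threshold 0.2 — a conventional
  cut-off for "failed sample"; the threshold is a free parameter because no
  standard exists).
- **Order is preserved everywhere** (samples, loci, population blocks), so
  repeated runs are byte-identical.

The VCF importer keeps only biallelic SNP records (`0/0 -> 0`, `1/1 -> 1`,
`0/1 -> 2`, `./. -> NA`); depth-aware genotype refinement is an upstream,
variant-caller responsibility.

## Diversity statistics and F-statistics

Per population and locus, with allele-A frequency $p$ and $q = 1 - p$:
observed alleles $n_a = [p>0] + [q>0]$, effective alleles
$n_e = 1/(p^2 + q^2)$, expected heterozygosity $H_e = 2pq$ (no small-sample
correction — the spreadsheet-era convention these tables are usually
reported in; a corrected variant would multiply by $2n/(2n-1)$ and is
deliberately not the default), observed heterozygosity $H_o$ = fraction of
code-2 calls, and fixation index $F = (H_e - H_o)/H_e$. Per-population
values are means over loci; $F$ averages the per-locus *ratios* over loci
with $H_e > 0$, not the ratio of the means — the two differ, and the
ratio-mean is what the standard software of this field computes. The
summary's `Mean` row is the unweighted mean over populations.

Private alleles count (locus, allele) pairs seen in exactly one population.
Software packages disagree on the denominator for a private-allele
*percentage*; we divide by the number of alleles observed in that population
(`sum of na over loci`) and always report the raw count alongside.

Across $k$ populations, per locus: $H_s$ is the unweighted mean of $2pq$,
$H_t = 2\bar p \bar q$ with $\bar p$ the unweighted mean frequency, and

$$F_{is} = \frac{H_s - \bar H_o}{H_s},\quad
  F_{it} = \frac{H_t - \bar H_o}{H_t},\quad
  F_{st} = \frac{H_t - H_s}{H_t},$$

each averaged over loci with a positive denominator; standard errors are
$\mathrm{sd}/\sqrt{L}$ over loci. Gene flow uses the island model,
$N_m = \tfrac14 (1 - F_{st})/F_{st}$, reported as infinite at $F_{st}=0$.

**A known property, not a bug:** with a finite number of populations this
estimator does not recover the generative divergence parameter. Under the
Balding–Nichols model with parameter $\theta$,
$E[2\bar p\bar q] = 2pq(1-\theta/k)$, so the ratio of expectations is
$\theta(1-1/k)/(1-\theta/k)$ — about 0.41 for $\theta=0.48, k=4$ — and
averaging per-locus ratios (Jensen) lowers the mean estimate further. The
estimator is consistent for its own estimand (the heterozygosity deficit
among the *sampled* populations), which is what practitioners report; the
parameter-recovery test in the acceptance suite records this gap rather than
papering over it.

## AMOVA

The inter-individual distance is the codominant genotypic squared distance:
per locus 0 / 1 / 4 for identical / homozygote-vs-heterozygote / opposite
homozygotes (equivalently the squared Euclidean distance between
allele-dosage vectors), summed over loci. Sums of squares follow the
distance partition
$SS_{tot} = \sum_{i<j} d^2_{ij}/N$,
$SS_{within} = \sum_{pops}\sum_{i<j \in pop} d^2_{ij}/n_{pop}$; with
$df = k-1$ and $N-k$, $n_0 = (N - \sum n^2_{pop}/N)/(k-1)$,
$\sigma^2_{within} = MS_{within}$ and
$\sigma^2_{among} = (MS_{among} - MS_{within})/n_0$ floored at zero (with a
flag). $\Phi_{PT} = \sigma^2_{among}/\sigma^2_{tot}$ is tested by permuting
whole-individual population labels; the p-value uses the $+1$ correction, so
999 permutations (the default) can never report below 0.001. A
Hamming-genotype distance alternative was considered and rejected as the
default because the 0/1/4 metric is the documented basis of the AMOVA most
such tables are produced with. `amova_from_summaries()` applies the same
estimation equations directly to printed SS/df/sizes, so published tables
can be reconstructed and checked.

## Similarity, UPGMA, PCoA

Rohlf's simple-matching coefficient needs a binary coding for codominant
genotypes; we adopt allele-presence expansion (each locus becomes two 0/1
characters), which yields the half-credit homozygote-vs-heterozygote score
and makes $GS = 1 - d_{manhattan}/(2L)$ on dosage vectors. Within-population
summaries exclude the diagonal ($n(n-1)/2$ pairs); among-population cells
use all $n_1 n_2$ pairs; a single-individual population has no within pairs
and reports `NA` with `n_pairs = 0` (its SE convention: one pair observed
means zero observed spread, so SE 0).

UPGMA runs on $D = 1 - GS$ via average-linkage `hclust` (deterministic
lowest-index merging) and is exported as an `ape::phylo`; node height is
half the merge distance, so the tree is ultrametric and cophenetic distances
equal the merge distances. PCoA double-centres $-\tfrac12 D \circ D$
(Gower), eigendecomposes, and scales eigenvectors by $\sqrt\lambda$. Whether
to embed $D = 1-GS$ or $\sqrt{1-GS}$ is genuinely open (only the square
root is guaranteed Euclidean); we default to $1-GS$ — matching how such
ordinations are usually produced — and expose `sqrt_dist = TRUE`. Negative
eigenvalues (non-Euclidean $D$) are excluded from the variance denominator
and counted separately; axis percentages are over positive eigenvalues
only. Each axis is oriented so its largest-magnitude coordinate is positive,
making output sign-deterministic. An all-identical input yields a flagged
degenerate result instead of an error.

## Parental selection and cross prediction

Selection is per population and greedy: rank by observed homozygosity (ties
broken by input order), seed with the top individual, then repeatedly add
the most homozygous candidate whose GS to *every* already-selected parent
exceeds the threshold (default 0.90, default $k = 10$). If the cohesive pool
runs out before $k$, remaining slots are filled in homozygosity order and
flagged `relaxed` — this operationalises "high within-population GS, when
possible" as a deterministic rule. A brute-force subset search would
maximise a joint criterion instead; the greedy rule was chosen because it is
reproducible, transparent to breeders, and matches the "top-k by
homozygosity subject to cohesion" intent.

Progeny prediction is exact single-generation Mendelian expectation per
locus (0, 1, or 0.5 as above) averaged over loci. Linkage is deliberately
ignored: recombination landscapes for chicory are not characterised, and
linkage does not change single-generation *means*, only their variances
across progenies. Consequences: selfing expectation is exactly half the
parent's heterozygosity; the prediction is symmetric in the parents; and it
equals 1 iff the parents are opposite homozygotes everywhere. The
`cross_prediction_matrix` orders parents in population blocks (input
order) — the natural layout for the within/among breeding interpretation —
with GS below the diagonal, predictions above, and parental homozygosity on
the diagonal. Expected progeny homozygosity is `1 - expected heterozygosity`.
Strategy summaries use type-7 (linear-interpolation) quartiles.

## The in-silico CAPS assay

Virtual PCR matches the forward primer on the plus strand and the
reverse-complemented reverse primer downstream, 1-based inclusive
coordinates, default exact matching; if mismatches are allowed, a 3'-terminal
mismatch still disqualifies (polymerases do not extend mispaired 3' ends).
Digestion cuts at every motif occurrence, overlapping occurrences included.
The default enzyme is Tru1I. Its canonical recognition site is `T^TAA`,
although assay descriptions sometimes state the motif as the inserted
`AATT` itself; the two readings select cut sites 2 bp apart. We default to
`TTAA` offset 1 and make both motif and offset configurable
(`restriction_site("AATT", 2)` etc.); the synthetic locus places the
insertion immediately after a `TT`, so either reading cuts the sterile
allele and neither cuts the fertile one.

Band-pattern calling uses reference sizes 300 / 230 / 70 bp with a 15 bp
tolerance (a gel-resolution proxy): `{300}` is `MsMs`, `{300, 230, 70}` is
`Msms`, `{230, 70}` is `msms`, everything else is an explicit no-call. The
~70 bp product can drop below agarose detection; `allow_low_band_dropout`
accepts `{300, 230}` as `Msms` for that situation. Phenotypes follow full
penetrance: only `msms` is sterile. Concordance between two call vectors
excludes no-calls from the percentage and reports them separately
(2-decimal, half-away-from-zero rounding, matching how such tables are
printed).

The 302 bp published amplicon size is treated as the insertion-bearing
allele (so the wild-type amplicon is 298 bp): the digestion arithmetic
230 + 72 = 302 is only consistent with that reading. The synthetic locus is
built to those sizes and is labelled synthetic throughout — it is a
stand-in with the same assay geometry as the deposited reference alleles,
not their sequence.

## The synthetic cohort generator

`synth_cohort()` emulates the study system the analyses were designed for:
four full-sib populations of sizes 15/17/37/25 (94 plants), 9351 raw loci
with a 1.22% per-call missing rate (so roughly 2950 loci survive the
completeness filter), strong divergence, and one population with mixed
ancestry. The generative chain is:

1. **Ancestral frequencies** ~ Uniform(0.1, 0.9) — bounded away from
   fixation so loci are potentially informative.
2. **Founder divergence** — Balding–Nichols:
   $p_i \sim \mathrm{Beta}(p(1-\theta)/\theta,\,(1-p)(1-\theta)/\theta)$
   with $\theta$ = `fst` (default 0.5, chosen once to put the realised
   among-population variance in the high-differentiation regime these
   populations show); founder genotypes are Hardy–Weinberg draws.
3. **Admixture** (default: population 1 draws each gamete from its own
   founders or population 2's with probability ½) — gamete-level, i.e.
   F1-like 50:50 ancestry.
4. **Full-sib mating**, default 3 generations: each generation draws one
   parent pair per population and produces the next generation as their
   full sibs. Three generations bring expected heterozygosity to half its
   founder value (inbreeding coefficient ½), landing within-population GS
   around 0.85–0.95 and homozygosity around 0.80–0.92 — the uniformity
   regime of advanced inbred lines.
5. **Missing injection** — i.i.d. Bernoulli per call, mask returned.

Every stage derives its own RNG stream from the master seed by labelled
splitting, so adding stages never perturbs existing output, and every stage
returns its truth (ancestral and founder frequencies, pedigree, missing
mask) so tests compare estimates against known parameters.

What the generator does **not** emulate: linkage and shared RAD-tag
structure (loci are independent), genotyping error and allelic dropout
(missingness is independent of genotype), selection during line advancement,
and any real allele-frequency spectrum. Passing recovery tests therefore
demonstrates estimator correctness under idealised sampling, not robustness
to real RADseq artefacts.

## Problem sizes and numerical conventions

The test suite exercises hand-enumerable toys (2–12 samples) against
brute-force oracles at 1e-9, mid-size simulated cohorts (~35–94 samples,
60–600 loci), a 3000-locus cohort for the clustering/AMOVA regime checks,
and 50 × 2000-locus replicates for parameter recovery; Monte-Carlo
assertions use three standard errors under fixed seeds. Percentages in
written reports are rounded half-away-from-zero to 2 decimals
(`round_half_up()`); all in-memory values keep full precision. Degenerate
inputs (zero variance, all-identical samples, monomorphic loci, empty
amplicon sets) return flagged results where a downstream consumer can
reasonably continue, and errors where the request is ill-posed (a
single-population AMOVA, digesting an empty sequence).
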