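---
title: "Classifying biological relatedness from pairwise mismatch rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying biological relatedness from pairwise mismatch rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kinmatch` infers relatedness between pairs of individuals from
pseudo-haploid or diploid genotype calls. This vignette documents the
model, the tunable parameters and the numerical and design choices behind
the implementation, and what the simulation-based tests do and do not
demonstrate.

## The model

At a biallelic SNP, write a genotype as a dosage $d \in \{0, \tfrac12,
1\}$: the fraction of copies of the second allele. A pseudo-haploid call
(one allele sampled from one random read) is always 0 or 1; a diploid
heterozygote is $\tfrac12$. The per-site mismatch between two individuals
is the probability that one allele drawn from each differs:

$$ m(d_1, d_2) = d_1 + d_2 - 2 d_1 d_2 . $$

This equals the case enumeration (identical homozygotes 0, opposite
homozygotes 1, anything against a heterozygote exactly $\tfrac12$), which
is what lets pseudo-haploid and diploid samples be compared on one scale;
the tests verify the identity exhaustively against a brute-force
enumeration of allele draws. The pairwise mismatch rate P0 is the mean of
$m$ over all jointly covered autosomal sites.

If a random allele from each of two individuals is identical by descent
with probability $\theta$ (the kinship coefficient), and non-IBD alleles
mismatch with the population background probability $B$, then
$\mathrm{E}[P0] = B(1-\theta)$. $B$ depends on population diversity and
SNP ascertainment, so P0 is normalized by an estimate of $B$ — by default
the median of all pairwise P0 values, which is robust whenever most pairs
are unrelated. The normalized P0 has expectation $1-\theta$: 0.5 for
identical twins/duplicates, 0.75 for first degree, 0.875 for second,
0.9375 for third, 1 for unrelated pairs.

Assumptions worth stating: a single homogeneous population (population
structure inflates the mismatch between subgroups and distorts the
median baseline), comparable data processing across samples, and no
strong inbreeding (runs of homozygosity lower an individual's mismatch to
everyone).

## Classification rules and gates

Degrees are assigned by cutting the normalized P0 at the midpoints
between adjacent expectations: 0.625, 0.8125, 0.90625. Intervals are
half-open, closed on the left, so a value exactly at a cutoff falls in
the higher-degree class — a pure tie-break convention; ties have measure
zero in practice. The upper bound of the third-degree interval is fixed
at 0.953125 rather than the midpoint to unrelated (0.96875): the narrower
window is deliberately conservative, because the third-degree and
unrelated distributions overlap long before the others do. The constant
is exposed in `degree_thresholds()` for sensitivity analyses.

The amount of information behind a pair is measured in **expected
mismatches**: overlap count × normalization value, i.e. how many
mismatches an unrelated pair with this overlap would show. Unlike a raw
SNP count it transfers across panels and populations. Two gates are
expressed in this unit:

* third-degree calls require ≥ 3000 expected mismatches; below that the
  pair is labelled `Unrelated_consistent_with_3rd` rather than given a
  confident degree;
* first-degree subtype resolution requires ≥ 10000; below that the
  window statistic drifts upward and parent–offspring pairs would leak
  into the sibling band, so the subtype is withheld (`NotApplicable`).

Both gates are monotone in the amount of data: reducing coverage can only
withdraw a call, never upgrade one.

### Parent–offspring versus siblings

Parent–offspring pairs share exactly one chromosome at every position;
full siblings are in IBD states 0/1/2 with genome-wide proportions near
1/4, 1/2, 1/4 (Cotterman $k_0, k_1, k_2$). The genome is tiled with 20-Mb
windows and each window's normalized P0 is classified with the same
cutoffs (no gate); the subtype statistic is the proportion of windows
classified `identical`, `unrelated` *or* `third`. The `third` category is
counted because such windows indicate no fully shared chromosome — the
classification text for the statistic names all three categories even
though a plot caption mentions only two; the toggle
`degree_thresholds(count_third_in_k02 = FALSE)` restores the narrower
definition. Windows use the single genome-wide normalization value:
the baseline reflects panel and population, not genomic position.

20 Mb is large enough that IBD state is nearly constant within a window
(IBD segments in close relatives average ~50 cM, with ~1 cM/Mb in
humans), yet small enough for ~140 windows genome-wide. Proportions below
0.30 are called `ParentOffspring`, within [0.35, 0.60] `Siblings`, and
anything else `NotApplicable` — the gap between 0.30 and 0.35 is a
deliberate no-call buffer.

## Uncertainty

The SE of the genome-wide P0 comes from a delete-one block jackknife over
5-Mb tiles, the standard device for genome-wide statistics under local
correlation. Because low-coverage missingness makes per-block overlaps
very unequal, blocks are weighted by their overlap counts (Busing's
weighted jackknife); with equal blocks the formula reduces exactly to the
unweighted delete-one jackknife, which the tests verify against a
hand-computed three-block example. Degenerate inputs: fewer than two
non-empty blocks give `NA` with a warning; identical leave-one-out
estimates give SE 0. The 95% interval for $\theta = 1 - $ normalized P0
is the normal approximation $\pm 1.96\,\mathrm{SE}/B$, reported
untruncated. Diploid calls carry more information per site, so
diploid–diploid comparisons have systematically smaller jackknife SEs
than pseudo-haploid ones at matched overlap — asserted as a ≥95%-of-
replicates property in the tests.

Windows and jackknife blocks tile each chromosome from bp 1 in the 1-based
coordinate system (`[1, W], [W+1, 2W], …`); anchoring is a convention and
any fixed choice yields the same estimators. All non-empty windows are
retained regardless of how few SNPs they contain; the gates, not a
per-window filter, handle sparse data. Every pair is reported down to an
overlap of a single site (zero overlap reports `NA` with a warning) —
filtering is left to the gates so that no pair silently disappears.

The genome-wide estimator is the default; `window_size_bp` switches to
the legacy mode in which the pair statistic is the unweighted mean of
per-window P0 values. For any window size, the overlap-weighted window
mean equals the genome-wide estimate to machine precision (a test
asserts 1e-14), so the legacy mode differs only through its unweighted
averaging.

## The simulator

`simulate_dataset()` generates benchmark data with known truth:

* **Panel**: `n_snps` (default 200000) positions uniform on 22
  GRCh37-scale autosomes, proportional to length; allele frequencies from
  $f(p) \propto p^{-0.6}$ truncated to [0.01, 0.5]. The exponent was
  chosen once so that the unrelated pseudo-haploid baseline
  $\mathrm{E}[2p(1-p)] \approx 0.25$, matching ascertained panels in
  diverse populations; with the default call error the realized baseline
  is ≈ 0.26.
* **Founders**: two independent Bernoulli haplotypes per individual —
  no background LD, no runs of homozygosity, no population structure.
* **Meiosis**: per chromosome, crossover count Poisson with mean equal to
  the map length (uniform sex-averaged 1 cM/Mb), positions uniform, no
  interference; the starting haplotype is fair.
* **Pedigrees**: minimal structures per relationship type
  (parent–offspring, siblings, half-siblings, grandparent–grandchild,
  avuncular, great-grandparent, first-cousin, grand-avuncular, plus
  unrelated singletons). Ancillary co-parents are simulated but not
  emitted; with the default counts the emitted cohort is 696 individuals.
  The truth table labels every within-pedigree pair (including the
  incidental parent–offspring and grandparent pairs inside larger
  structures); everything else is unrelated.
* **Observation model**: per site and sample, depth ~ Poisson(coverage);
  depth 0 is missing, otherwise one true allele is sampled and flipped
  with probability `error_rate` (default 0.005, identical across
  individuals). Mean callable fraction is $1 - e^{-c}$, so the expected
  pairwise overlap is $n_{\mathrm{snps}}(1 - e^{-c})^2$. `"diploid"` mode
  emits the true dosages unthinned and error-free, modelling a
  high-quality diploid or imputed genome.

What the simulator does **not** emulate: read-level artefacts (position-
dependent deamination profiles, mapping bias), background linkage
disequilibrium, population structure, inbreeding, and unequal error rates
between samples. Passing benchmarks therefore demonstrate the estimator's
statistical behaviour under the stated sampling model, not robustness to
those empirical complications; on real data, enzymatic damage repair or
`filter_sites(..., "transversions_only")` is recommended when deamination
levels vary between libraries.

Two known, quantified biases of the observation model are worth noting.
First, a symmetric per-call error $e$ moves the normalized P0 of a
related pair towards 1 by approximately $2e(1-e)\theta/B$ (≈ 0.01 for a
first-degree pair at the defaults) — a property of the noise, not of the
estimator; the estimator-calibration test therefore runs error-free,
while the power benchmarks keep the default error. Second, under the
uniform no-interference map the sibling k0+k2 window proportion at high
coverage has a model-true expectation of ≈ 0.45 rather than the idealized
0.5 (window-boundary mixing pulls extreme windows toward the middle; a
real, heterogeneous genetic map with crossover interference yields purer
windows). Both the subtype bands and the tests account for this: sibling
means are asserted to lie inside the sibling calling band [0.35, 0.60],
parent–offspring below 0.30.

## Benchmark designs and reproducibility

The shipped tests and `scripts/acceptance.R` use three designs, sized to
estimate the operating characteristics with useful precision at desk
scale: a 202-individual mixed-pedigree cohort at 0.3× on the full
200000-SNP panel (165/68/17 true first/second/third-degree pairs and
~20000 unrelated pairs) for power and false-positive rates; 32 sibling
quartets at 5× for the subtype statistic; and 20 unrelated individuals at
0.2× for the coverage–overlap relation. All randomness flows through one
seed set at the top of `simulate_dataset()`, making outputs byte-identical
across runs with the same configuration.

## Limitations

* No resolution beyond the third degree, no within-second-degree
  subtyping, and no pedigree reconstruction — the output is per-pair.
* The normalization needs a mostly unrelated cohort of at least ~4
  individuals; smaller or heavily related datasets should supply a
  `user` value (e.g. twice the P0 of a technical-replicate pair).
* P0 ignores population allele frequencies by design; methods that use
  them (or genotype likelihoods, or imputation) extract more information
  per site at the cost of heavier inputs.
* Third-degree calls and subtype calls are gated, not guaranteed: with
  little data the method prefers `Unrelated_consistent_with_3rd` or
  `NotApplicable` over a confident wrong answer.
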