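---
title: "Detecting polygenic selection from allele-frequency differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polygenic selection from allele-frequency differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The question

A polygenic trait under stabilizing selection poses a problem for classical
selection scans: no single locus sweeps, because the optimum phenotype can be
assembled from many different combinations of trait-increasing alleles. Yet
the trait loci are not evolving neutrally. When several populations evolve
independently toward the same phenotypic optimum, each population can settle
on a *different* subset of alleles rising in frequency — a symmetry-breaking
driven by initial conditions and drift. The signature is collective: the set
of trait-associated SNPs shows a higher *mean* allele-frequency
differentiation (F\_ST) than the genomic background, even though few or none
of them are individual F\_ST outliers.

`polyfst` implements both halves of that argument:

1. a forward simulator demonstrating that Gaussian stabilizing selection on
   an additive polygenic trait inflates mean F\_ST at the trait loci relative
   to neutral loci, and
2. the statistical battery that tests a candidate SNP set against a genomic
   background: per-SNP Weir–Cockerham F\_ST, a one-tailed Mann–Whitney
   comparison, outlier trimming, removal of LD-confounded candidates, and a
   top-tail enrichment check on haplotype-based selection scores (iHS-like),
   used to exclude the competing explanation of recent local adaptation.

## The simulation model

Each of `n_populations` populations holds `N = n_individuals` diploids
carrying `L` biallelic markers; the first `n_loci_selected` contribute
additively and codominantly to the phenotype, the rest are neutral. With `m`
the number of trait-increasing ("beneficial") alleles in a genotype, each of
effect `x`, viability is

$$w(m) = \exp\!\left(-\frac{(m-\mu)^2 x^2}{2s}\right),$$

maximal when `m` equals the optimum count `mu` and with selection strength
controlled by `s` (larger `s`, weaker selection) and by `x` (`x = 0` turns
selection off exactly, so the simulator reduces to neutral Wright–Fisher
drift — this is the key internal control). Generations are discrete: each
offspring draws two parents with probability proportional to viability
(fitness-proportional sampling with replacement — soft selection, which is
the reading of "viability selection" that keeps `N` exactly constant; a
literal kill-then-refill scheme does not), and each parent transmits one
recombinant gamete, switching source haplotype between adjacent loci with
probability `recomb_rate`.

Defaults follow the regime we study throughout: `x = 5`, `mu = 10`,
`s = 10`, ten selected plus ten neutral loci, initial frequency 0.5 at every
locus, three populations, no mutation and no migration. Two quantities are
not part of that regime and had to be fixed here as package choices:

* **Generations** (`n_generations = 200`): under the default selection
  strength the per-population allele-frequency splitting — some trait loci
  rising toward fixation, a complementary subset falling — is fully developed
  well before 200 generations for `N` in the thousands; the default makes
  the phenomenon visible without wasting compute.
* **Recombination** (`recomb_rate = 0.5`): no linkage map accompanies the
  20-marker genome, so unlinked markers (free recombination) is the minimal
  assumption. Under free recombination the placement of selected loci in the
  first half of the marker vector is immaterial; it matters only if you
  lower `recomb_rate` for linked runs.

Two further numerical choices: fitness weights are rescaled by their maximum
before sampling, since only relative viability matters and the raw weights
underflow when `(m-\mu)^2x^2/(2s)` is large; and initialization draws each
allele Bernoulli(0.5) — the standard reading of an "initial frequency" —
with an exact-count option (`exact_init = TRUE`) when you want generation
zero at exactly 0.5. If every parental viability underflows to zero the
generation step signals an error rather than sampling uniformly.
Reproducibility: `run_simulation(params, seed = s)` gives population `k` its
own substream seeded `s + k - 1`, so runs are bit-identical for equal seeds.

```{r}
library(polyfst)
params <- sim_params(n_individuals = 500, n_generations = 100)
res <- run_simulation(params, seed = 7)
s <- sim_fst_summary(res, sample_size = 100)
c(selected = s$mean_theta_selected, neutral = s$mean_theta_neutral)
```

The selected set's mean theta exceeds the neutral set's, although every
locus experiences the same drift. At `N = 1000` over 200 generations this
ordering holds in effectively every replicate, and with `effect_x = 0` it
degenerates to a coin flip — both properties are exercised in the test
suite at 50 replicates each.

## The F\_ST estimator

Per SNP we use the unbiased ANOVA estimator of Weir & Cockerham (1984) for a
biallelic locus in `r` samples, from genotype counts: sample sizes `n_i`,
reference-allele frequencies `p_i` and observed heterozygote proportions
`h_i` enter the among-population (`a`), among-individual (`b`) and
within-individual (`c`) variance components, and `theta = a/(a+b+c)`.
Points that matter in practice:

* **Observed vs HWE heterozygosity.** Genotype counts are the native input
  (`wc_components`, `panel_fst`); an `hwe = TRUE` mode imputes
  `h_i = 2p_i(1-p_i)` for frequency-only data and is flagged in the output.
  The distinction is not cosmetic: simulator-derived panels are not at
  Hardy–Weinberg equilibrium while selection is acting.
* **Negative estimates are kept.** theta is slightly negative for many
  undifferentiated SNPs; clipping at zero would distort the lower tail of
  the background distribution, which the outlier-trimming stage uses.
* **Undefined, not zero.** A SNP monomorphic for the same allele everywhere
  has `a+b+c = 0`; it is flagged undefined and excluded from distributional
  analyses, mirroring the background-assembly rule that drops SNPs
  non-polymorphic in every sample. Samples with `n_i = 0` are dropped per
  SNP; fewer than two remaining samples also flags the SNP.
* The per-SNP theta distribution is the pipeline statistic; the multilocus
  ratio-of-averages `sum(a)/sum(a+b+c)` is provided
  (`fst_ratio_of_averages`) as a validation utility.

## The comparison battery

`run_comparison()` chains the stages in the order in which the analysis is
meant to be read, each answerable separately:

1. **Filtering** (`filter_panel`): drop SNPs unsampled everywhere,
   monomorphic everywhere, or with minor-allele frequency below `maf_min`
   (default 0.05) in *every* sample. The MAF rule is deliberately the weak
   reading — a SNP is kept if any one sample reaches the threshold — because
   that is what "MAF < 5% in all samples" literally excludes; the strict
   any-sample reading is available as `maf_rule = "any"`.
2. **Location test** (`mann_whitney_one_tailed`): U counts
   candidate-background pairs with the candidate theta larger, ties half.
   One-tailed, candidates stochastically greater. The p-value is by
   exhaustive enumeration of group labelings whenever `choose(m+n, m)` is at
   most 20,000 (so every split with both groups of size 8, or total size 12,
   is exact), else the tie-corrected normal approximation with continuity
   correction. Being a rank statistic, U and p are invariant to any common
   monotone shift of both groups.
3. **Outlier trimming** (`trim_outliers`): candidates outside the empirical
   5%/95% background quantiles are removed, leaving the "core set"; both
   tail counts are reported so you can compare them with the 2 x 5%
   expected under exchangeability. Quantiles are type-7 (linear
   interpolation), the common default; on large backgrounds the definition
   shifts thresholds only at O(1/n).
4. **LD confounding** (`ld_confound_filter`): a core-set SNP linked to a
   variant associated with a *different* trait at r² strictly above 0.8 in
   at least one population is removed and the test repeated; a surviving
   signal cannot be attributed to hitchhiking on selection for other
   phenotypes. The inequality is strict — r² = 0.80 exactly is kept.
5. **Score enrichment** (`tail_enrichment`): per population, the fraction of
   candidates whose selection score (e.g. a precomputed iHS track) exceeds
   the background's 95th percentile, with a two-sided exact binomial test
   against 5%. No test is named for this check in the source analysis, so
   the exact binomial is our choice; "compatible with expectation" means
   p well above alpha. Scores are used as given (signed); set
   `score_transform = "abs"` if your track's tail of interest is two-sided.
   Note the threshold comes from the pooled score table, so candidates
   should be rare relative to the background (as in any genome-wide track);
   a fixture where candidates are a large fraction of the table drags the
   threshold itself.

No multiple-testing correction is applied across the battery's three
Mann–Whitney tests — they are sequential robustness checks of one
hypothesis, not independent discoveries.

## Synthetic panels and what they do (not) show

`balding_nichols_panel()` generates the test fixture: per SNP an ancestral
frequency uniform on `ancestral_maf_range` (default 0.05–0.95), per
population an allele frequency from the Balding–Nichols Beta distribution
`Beta(p(1-F)/F, (1-p)(1-F)/F)`, then trinomial genotype counts under HWE for
`n_per_pop` diploids (default 90, a HapMap-era sample size, so estimator
noise is realistic). The model is chosen because its `F` parameter *is* the
F\_ST the estimator should recover, giving ground truth for recovery tests;
candidate SNPs are generated identically at `F_candidate`, giving an exact
null (`F_candidate = F_background`) and a controlled alternative.

The study conditions used in the validation suite, fixed in advance:
recovery at 10,000 SNPs, 3 populations of 100 diploids, `F = 0.1`
(ratio-of-averages expected within [0.09, 0.11]); null calibration at 300
replicates of 5,000 background + 150 candidates (Mann–Whitney p-values
uniform by KS at alpha 0.01, trimming near 10%); power at
`F_background = 0.09` vs `F_candidate = 0.15`, same sizes, detection in at
least 90% of 100 replicates. The simulator claim uses `N` scaled to 1,000
(from the reference regime's 10,000) with 200 generations and 50 replicates
— population-size scaling keeps the run inside a few minutes while the
selection regime stays strong relative to drift.

What the fixtures do **not** emulate: real HapMap ascertainment bias,
LD structure along chromosomes (the synthetic LD table assigns r² values
directly, it does not simulate haplotypes), demographic history shared
across SNPs (Balding–Nichols SNPs are exchangeable and independent), or the
genuine iHS computation (scores are consumed, never computed, from phased
haplotypes — that is out of scope). Passing tests therefore validate the
estimator, the test battery's calibration and power, and the simulator's
qualitative claim — not any statement about a particular human dataset.

## Degenerate inputs and edge rules

* `wc_components` accepts non-integer counts (expected counts are legal
  input); count sums are validated against `n` to 1e-8.
* Empty panels produce empty F\_ST tables; an empty LD table removes
  nobody; a population with no scored candidates is reported absent from
  the enrichment table, not an error.
* Candidates missing from the filtered panel are logged in
  `missing_candidates` and skipped; only a candidate set that vanishes
  entirely is an error.
* `trim_outliers` refuses backgrounds under 20 values (tail quantiles would
  not be interior).

## Limitations

* No mutation, migration, dominance, epistasis or environmental variance in
  the simulator — the model isolates the drift-vs-stabilizing-selection
  mechanism by design.
* Biallelic loci only; no jackknife/bootstrap confidence intervals on theta.
* The Mann–Whitney normal approximation is used above the enumeration
  cutoff; for the sample sizes where it engages (hundreds against
  thousands) its error is far below any decision boundary here.
* Whether the original height analysis used observed or HWE-imputed
  heterozygosity is unknowable from the text; both modes are provided and
  the choice is recorded in every output row.
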