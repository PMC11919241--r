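---
title: "Methods: recessive-disease prevalence from population allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive-disease prevalence from population allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recprev)
```

## The estimation problem

For an autosomal recessive disorder, an individual is affected only
when both chromosomes carry a pathogenic allele. Single alleles
circulate in the healthy population, so a population-scale sequencing
database observes them directly, and disease prevalence can be
estimated without any clinical ascertainment. Let $q_i$ denote the
population frequency of pathogenic allele $i$ and $q = \sum_i q_i$.
Under Hardy–Weinberg equilibrium the affected-genotype frequency is

$$q^2 \;=\; \sum_i \sum_j q_i\, q_j,$$

a sum over **ordered** pairs of alleles (homozygotes are the diagonal
terms $q_i^2$; a compound heterozygote $i/j$, $i \ne j$, contributes
$q_i q_j$ twice, matching the familiar $2\,q_i q_j$).

The assumptions this inherits: random mating (no consanguinity or
assortative structure), independence of allele frequencies across
sites (no linkage or shared haplotypes among the pathogenic alleles),
full penetrance of counted genotype pairs, and a database that is an
unbiased sample of the population of interest. None of these is
exactly true in practice; per-ancestry estimates (below) address
population structure only at the resolution of the database's own
ancestry labels.

## The three estimators

**Maximum likelihood.** $\hat q_i = \mathrm{AC}_i / \mathrm{AN}_i$,
the allele count over the total allele number at the site. Simple and
unbiased per site, but a variant truly present at $10^{-6}$ will
usually have $\mathrm{AC} = 0$ in a database of $10^5$ alleles and
contribute nothing.

**Bayesian mean.** Each $q_i$ carries a conjugate beta-binomial
posterior, $q_i \mid \mathrm{AC}, \mathrm{AN} \sim
\mathrm{Beta}(\alpha + \mathrm{AC},\, \beta + \mathrm{AN} -
\mathrm{AC})$, and the estimate plugs posterior means into the
quadratic form. The default prior is the uniform
$\mathrm{Beta}(1, 1)$: the posterior mean
$(\mathrm{AC}+1)/(\mathrm{AN}+2)$ then differs from the ML ratio by
at most $\mathcal{O}(1/\mathrm{AN})$ — negligible at database scale
— while giving zero-count variants a defensible non-zero frequency.
The prior is a tunable `prior = c(alpha, beta)` everywhere; informative
priors per consequence class can be supplied by the caller but are not
baked in, because any particular choice encodes beliefs about typical
frequencies of variant types that should be an explicit analysis
decision.

**Bayesian variance.** The previous estimator computes
$(E\,q)^2$, which is not $E(q^2)$. Under posterior independence,

$$E(q^2) \;=\; \mathrm{Var}(q) + (E\,q)^2
  \;=\; \sum_i \mathrm{Var}(q_i) + \Bigl(\sum_i E(q_i)\Bigr)^2,$$

implemented by replacing the diagonal pair terms with
$\mathrm{Var}(q_i) + E(q_i)^2$. Because the added variances are
non-negative, this estimate always dominates the Bayesian mean — a
property the test suite asserts.

## Severity-aware genotype compatibility

Not every pair of pathogenic alleles yields a living affected
individual. `build_policy()` assigns each variant a severity class and
derives a symmetric 0/1 matrix $A$; the estimate becomes
$\sum_{ij} A_{ij}\, m_{ij}$ where $m_{ij}$ is the method's pair term.

* **null** — loss-of-function consequences (nonsense, frameshift,
  canonical splice, start loss). Two nulls in trans abolish the gene
  product entirely and are modelled as embryonic-lethal, so *every*
  null–null pair (including null homozygotes) is excluded. The class
  membership is a configurable argument; the default is the standard
  loss-of-function definition.
* **mild_hom_excluded** — explicitly listed variants whose
  homozygote does not manifest disease. The defaults are the three
  *GNE* alleles with population evidence of healthy homozygotes
  (p.Asp207Val, p.Val727Met, p.Asp239Glu), matched by `hgvs_p` so the
  default works regardless of the transcript numbering in use. Only
  the diagonal entry is zeroed: a compound heterozygote of a mild
  allele with any other allele still counts, including a compound
  heterozygote of two *distinct* mild alleles — the evidence concerns
  homozygotes only, and excluding the cross terms would extrapolate
  beyond it.
* **synonymous** — same treatment as mild: homozygote excluded,
  compound heterozygotes retained.
* **standard** — everything else; all pairs count.

Precedence when classes overlap is null > mild > synonymous (a listed
mild variant with a loss-of-function consequence is treated as null).
Masking can only remove non-negative terms, so the severity-adjusted
estimate never exceeds the unadjusted one — also asserted as a
property.

## Triage of unreported variants

Databases contain many variants with no clinical classification.
The triage module grades them into four nested sets:

1. **MAF prefilter** (`maf_filter`, default cutoff 0.001): a truly
   pathogenic recessive allele at frequency above $10^{-3}$ would
   imply implausibly many patients; such variants are removed. The
   default comparison keeps frequencies $\le$ the cutoff and removes
   only strictly greater ones; an inclusive mode
   (`strict = FALSE`) removes frequencies $\ge$ the cutoff. Both
   conventions are defensible — a known pathogenic founder allele can
   itself sit above the cutoff — so both are implemented and the
   choice is explicit. Records with $\mathrm{AN} = 0$ cannot be
   judged and are retained with a warning rather than silently
   dropped.
2. **CADD cutoffs** (`fit_cadd_cutoffs`): normal distributions are
   fitted to the CADD scores of known pathogenic and known benign
   variants; the lower cutoff sits $k$ standard deviations below the
   pathogenic mean and the upper cutoff $k$ standard deviations above
   the benign mean ($k = 3$ by default, the conventional
   three-sigma confidence band). The sample standard deviation
   ($n-1$) is used, appropriate for the small curated score sets the
   fit typically sees. Cutoffs are kept unrounded internally;
   `round_cutoffs = TRUE` reproduces the integer thresholds usual in
   reporting. If the two fitted curves overlap so much that the
   cutoffs invert, the function warns rather than fails — the caller
   must decide whether the score separates their classes at all.
3. **CADD triage** (`cadd_triage`): score strictly above the upper
   cutoff → likely pathogenic; strictly below the lower → likely
   benign; otherwise — including a score exactly at either cutoff,
   and any variant with no CADD score — the gray zone. Boundary
   scores stay gray because the cutoff derivation gives no reason to
   break the tie either way, and absent scores stay gray because
   absence of evidence is not evidence of benignity.
4. **Gray-zone vote** (`gray_zone_vote`): a variant is voted
   pathogenic if Human Splicing Finder predicts a "big impact" on
   splicing outright, or if at least two of three categories are
   positive — splicing (HSF "important impact" or SpliceAI
   $> 0.5$), protein (SIFT "deleterious" or PolyPhen
   "probably damaging"/"damaging"), PrimateAI ($> 0.805$). A missing
   tool output counts as non-positive rather than as missing data,
   which makes the vote monotone: more positive evidence can only
   move a verdict towards pathogenic. Gray-zone variants with no
   annotations at all therefore fail the vote but are retained in the
   most liberal set, since nothing argued for their benignity.

`assemble_variant_sets` then builds S1 (known pathogenic only),
S2 (S1 + CADD-confident), S3 (S2 + vote passes), S4 (S2 + all
gray-zone), nested by construction. Estimates over S1 with the
severity policy are the conservative end of the range; S4 unadjusted
is the liberal end.

## Uncertainty

`bootstrap_ci` uses a parametric binomial bootstrap: per replicate,
$\mathrm{AC}_i^* \sim \mathrm{Binomial}(\mathrm{AN}_i, \hat q_i)$
independently per variant, the estimate is recomputed, and the 2.5th
and 97.5th percentiles (type-7 quantiles) bound the interval. Default
1000 replicates; the generator is seeded and the caller's RNG state
is restored afterwards. This captures sampling noise in the database
counts only — not uncertainty about which variants belong in the set,
penetrance, or database ascertainment bias — so intervals from
different variant sets need not overlap. The percentile scheme was
chosen over normal-theory intervals because the statistic is a
squared sum of small frequencies and its replicate distribution is
visibly right-skewed at realistic counts.

`burden(prevalence, population, fraction)` converts a per-million
rate into an expected case count; the fraction accommodates
adult-onset disease where only individuals past onset age currently
manifest (e.g. `0.5` when roughly half the population is younger than
typical onset).

## The synthetic-data generator

`simulate_catalog` emulates the statistical structure of a
population-database export with known ground truth:

* true allele frequencies log-uniform on $[10^{-6}, 10^{-3}]$ — the
  rare-variant regime a MAF prefilter leaves behind, spread evenly
  across orders of magnitude;
* per ancestry group, allele counts sampled at the individual level:
  genotype-class counts $(\text{hom}, \text{het}, \text{ref}) \sim
  \mathrm{Multinomial}(n_{\mathrm{ind}}, (q^2, 2q(1-q), (1-q)^2))$,
  so $\mathrm{AC} \le \mathrm{AN}$ and
  $2\,\mathrm{nhomalt} \le \mathrm{AC}$ hold by construction and
  marginally $\mathrm{AC} \sim \mathrm{Binomial}(\mathrm{AN}, q)$;
* three ancestry groups by default (allele numbers 200&#8239;000 /
  60&#8239;000 / 40&#8239;000, one large European-like group and two
  smaller ones), pooled into the global columns — the same order of
  magnitude as the exome component of a v2-era population database;
* a consequence mix dominated by missense (70%), with 10% synonymous
  and 20% putative loss-of-function split across nonsense,
  frameshift and canonical-splice — the proportions one sees in a
  single-gene variant tally;
* CADD scores from a pathogenic-like $\mathcal N(28, 5)$ or
  benign-like $\mathcal N(8, 5)$ model; these defaults make the
  three-sigma fit cutoffs land near 13 and 23, the regime the triage
  rules are designed for;
* binary tool outputs flipped at 5% false-positive/false-negative
  rates — enough noise that the vote matters, not so much that it is
  uninformative;
* half the variants truly pathogenic by default, so both triage error
  directions are exercised.

Identical seeds give identical catalogs. The generator does **not**
model demographic history, site-frequency spectra, linkage between
sites, relatedness, or ascertainment bias; a pipeline that passes all
tests on synthetic data is therefore validated for its arithmetic and
logic, not for robustness to those real-data features.

## Numerical and interface choices

* HGVS normalization is string-level only: whitespace stripped, case
  folded, transcript prefix attached. No sequence-aware validation or
  transcript lifting is attempted; protein-only (`p.`) records are
  quarantined with a reason instead of fuzzily matched, because the
  c./p. mapping is many-to-one.
* Merge conflicts in clinical class resolve by precedence
  known_pathogenic > other_disease > vus > benign (strongest evidence
  wins; other_disease outranks vus so that an exclusion decision is
  not silently reversed by a weaker source), and every conflict is
  logged on the result.
* Precomputed 0–1 pathogenicity scores are bucketed with a closed
  ambiguous interval (a score exactly at a threshold is ambiguous).
* The quadratic form is evaluated as a dense masked outer product;
  catalogs here are hundreds of variants, so no sparsity is needed.
  With the all-ones mask it agrees with the closed form
  $(\sum q)^2$ to $10^{-12}$ relative — asserted in the tests, where
  an exhaustive double-loop enumeration and a Monte-Carlo genotype
  simulation (two alleles per individual drawn from the pooled
  frequency vector) serve as independent oracles.
* Beta-posterior moments use the closed conjugate form; the test
  oracle integrates the posterior density numerically (restricted to
  the quantile range carrying the mass, since a blind $[0,1]$
  quadrature misses sharply peaked posteriors) and agrees to
  $10^{-8}$.
* Per-population estimates use each population's own AC/AN; a variant
  with no counts for a population is skipped for that population
  rather than imputed at frequency zero, so a population estimate is
  conditional on the variants actually observed there.
* Degenerate inputs: empty catalogs estimate 0; an all-zero-count
  catalog bootstraps to the degenerate interval (0, 0); zero-spread
  score sets collapse their cutoff to the mean with a warning.

## Validation problem sizes

The test suite validates estimator consistency on a simulated
database of $10^7$ alleles (relative error under 5%), Monte-Carlo
agreement on $10^6$ simulated diploids (within three binomial
standard errors of the closed form), and bootstrap coverage on 100
simulated catalogs of 10 variants at $5 \times 10^5$ alleles with
300 replicates each (nominal 95% intervals must cover the truth in
90–99 runs). These sizes give each check comfortable statistical
resolution while keeping the default suite fast enough to run on
every change.

## Known limitations

Structural variants (CNVs, large indels) are not represented —
tables keyed by HGVS c. notation cannot express them, and databases
only partially report them — so estimates omit their contribution.
The pipeline consumes precomputed annotation scores only; it never
runs CADD, SpliceAI, or the other tools. Priors for the Bayesian
estimators are global rather than per-consequence-class unless the
caller supplies otherwise. Confidence intervals reflect count
sampling noise only. The pipeline entry point is the exported
`run_pipeline()` function (plus `scripts/acceptance.R` for the
reproduction run); no shell subcommand wrapper is shipped, as the
package is intended to be driven from R.
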