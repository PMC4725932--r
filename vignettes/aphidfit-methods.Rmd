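---
title: "Models and methods behind aphidfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aphidfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidfit)
```

`aphidfit` analyses host-plant fitness of parthenogenetic aphids along
three axes — cohort demography, electrical penetration graph (EPG) feeding
behavior, and replicate-free salivary-gland differential expression with GO
enrichment — and ships generators that produce synthetic inputs with known
truth for each stage. This vignette explains the models, the parameter
choices that matter, the numerical details, and what validation on
synthetic data does and does not establish.

## Cohort demography

The unit of observation is one aphid followed daily from birth to death
(age 0 = day of birth), with its stage (N1–N4, Adult), daily offspring
count and survival recorded each day — the design of a standard
single-leaf life-table experiment with ~80 first-instar nymphs per
treatment. Because the study species is parthenogenetic, all individuals
are female and no male bookkeeping exists.

From a cohort of *n* individuals the schedules are

* $l_x$ — fraction of the initial cohort alive at age $x$ (so $l_0 = 1$,
  non-increasing);
* $m_x$ — mean offspring per *surviving* individual at age $x$, set to 0
  at ages where nobody is alive. With this convention
  $\sum_x l_x m_x = R_0$ is exactly the mean lifetime offspring per
  initial individual, early deaths included;
* $s_{xj}$ — fraction of the initial cohort alive *and* in stage $j$ at
  age $x$; rows sum to $l_x$ (enforced to $10^{-12}$ by the class
  validity).

**Intrinsic rate of increase.** $r$ solves the Euler–Lotka equation
$\sum_x e^{-r(x+1)} l_x m_x = 1$. With ages counted from 0, the age-stage
life-table literature uses exponent $x+1$; the classical textbook indexing
(ages from 1) corresponds to exponent $x$. Both are implemented behind
`convention = c("x+1", "x")`, default `"x+1"`. The equation's left side is
strictly decreasing in $r$, so bisection is globally convergent: the
initial bracket $[-1, 2]\ \mathrm{day}^{-1}$ (generous for any aphid) is
expanded by doubling until the residual changes sign (at most 60
doublings), then bisected to $|\Delta r| < 10^{-12}$; the residual at the
root is verified to be below $10^{-10}$. Closed-form cases (point-mass
fecundity $f$ at age $a$ gives $r = \ln f/(a+1)$; $R_0 = 1$ gives
$r = 0$) are exact to that tolerance.

**Derived parameters.** $\lambda = e^r$ and $T = \ln R_0 / r$ hold as
identities in every output (class validity re-checks them). Day counting:
nymph period = adult entry age; adult period = death age − entry age + 1
(the entry day counts as an adult day); total longevity = death age + 1.

**Bootstrap.** Standard errors come from resampling $n$ individuals with
replacement $B$ times and recomputing every parameter per resample; the
reported point estimate is the original-cohort value, not the bootstrap
mean. A resample with zero total offspring has no defined $r$, $\lambda$
or $T$; such resamples are dropped from those summaries and their count is
reported (`nDegenerate`), which keeps SEs defined for high-mortality
treatments instead of aborting. The package default is $B = 2000$: on the
cohort sizes involved (80–500) the SE of the SE is then well below the
precision at which these parameters are conventionally reported, and two
independent runs at $B = 10^4$ agree within 10% (tested). $B$ is a plain
argument for anyone wanting more.

## EPG feeding behavior

A recording is a set of non-overlapping waveform intervals (np, C, E1,
E2, F, G — non-probing, pathway, phloem salivation, phloem ingestion,
derailed stylet, xylem drinking) within a fixed 5 h window. The time
ratio of a waveform is its summed duration divided by the *nominal*
18 000 s, per the convention of reporting "time divided by 5 h";
unannotated time is surfaced as its own column and never redistributed, so
ratios plus unannotated sum exactly to 1. Ratios are invariant to interval
order and to splitting intervals (tested).

Group comparison is per waveform: a Welch $t$ test for two groups
(Student's pooled variant behind `welch = FALSE`; the unequal-variance
default is the robust modern choice when the source analysis says only
"t-test"), or one-way ANOVA with a Tukey-HSD compact letter display at
$\alpha = 0.05$ for more groups. Which post-hoc produced the published
letter displays is not stated anywhere we could rely on; Tukey HSD is our
documented choice, not a guess at theirs. Cells with zero variance across
all groups are reported as degenerate rather than tested. The attainment
matrix gives, per group, the fraction of recordings containing at least
one interval of each code — the "fraction of individuals entering each
feeding step" — and moves by exactly $1/n$ when one recording gains a
first interval of a code.

The waveform vocabulary is closed to the six analysed codes; unknown codes
are rejected unless `allowExtraCodes = TRUE` (potential-drop events and
finer subclasses are out of scope).

## Replicate-free differential expression

The expression stage mirrors a pooled-library design: one library per
condition, no biological replicates, so inference leans on the Poisson
sampling of reads from a pool.

* **RPKM** $= 10^9 C/(N L)$ is provided for abundance reporting.
* **TMM factors** follow the trimmed-mean-of-M-values recipe with the
  method's standard parameters: genes zero in either sample dropped, 30%
  trimmed from each tail of the log-ratios $M$, 5% from each tail of the
  average log abundance $A$, precision-weighted mean of the surviving
  $M$, factors rescaled to geometric mean 1. The reference sample is the
  one whose upper-quartile proportion is closest to the mean
  upper-quartile. If fewer than 20 genes survive the trim the factor
  falls back to the untrimmed weighted mean with a warning. The
  implementation is validated against an independent plain-loop oracle and
  against edgeR's `calcNormFactors` to $10^{-9}$. Note that exact
  invariance to uniform scaling of a column holds only without precision
  weights (the weights depend on absolute counts); with weights the
  factors move by $O(10^{-4})$.
* **Audic–Claverie test.** With $x$ reads in a library of size $N_1$,
  the predictive probability of $k$ reads in a library of size $N_2$ is
  $p(k|x) = (N_2/N_1)^k\,(x+k)!/\bigl(x!\,k!\,(1+N_2/N_1)^{x+k+1}\bigr)$,
  which is the negative-binomial pmf with size $x+1$ and success
  probability $N_1/(N_1+N_2)$ — so tails are evaluated through `pnbinom`
  in log-safe form rather than term-by-term summation. The two-sided p
  doubles the smaller of the two cumulative tails at $y$ (the tail
  pointing away from the expectation $x N_2/N_1$), capped at 1. Sidedness
  is not specified in the sources that describe the test; doubling the
  away tail is our documented construction. One consequence of the
  discrete doubling: swapping the roles of the two libraries shifts the
  tail by one predictive term, so $p(x,y)$ and $p(y,x)$ agree only up to
  that term (for equal libraries, within
  $\mathrm{dbinom}(x, x+y, 1/2)$) — exchange symmetry is near, not exact.
  Under a null of paired Poisson counts at pooled-library depth
  (lognormal gene means around 500 reads), the fraction of $p < 0.05$
  sits inside the binomial 99% CI of 0.05 (tested at $10^4$ genes).
* **Contrast calling.** The test runs on raw counts with TMM-effective
  library sizes $N f$ — one coherent normalization path. The expression
  ratio is computed on TMM-normalized counts-per-million with a 0.5
  pseudocount on both sides (never applied to p values); whether the
  original ratio threshold was RPKM- or TMM-based is unstated, and the
  TMM basis is our choice because TMM exists precisely to remove RNA
  output-size differences (`ratioOn = "rpkm"` is available). Genes with
  zero counts in both samples are untestable and excluded from the test
  and the BH denominator. Calls are `up`/`down` at ratio ≥ 2 (either
  direction) *and* BH-adjusted $P < 0.001$, per contrast (BH is applied
  within each contrast, not jointly).
* **Venn partitioning** over 2–3 contrasts reports every membership
  region of the varied (up ∪ down) sets plus the direction-split common
  sets (commonly up, commonly down, commonly varied).

## GO enrichment

Terms annotated to at least `minCount = 3` background genes (a floor
against vacuous tests) are scored on the 2×2 table of list membership ×
term membership: chi-square without continuity correction — whose
statistic is exactly $\sum (O-E)^2/E$ — unless *any* of the four expected
counts is below 5, in which case a two-sided Fisher exact test is used,
built as the doubled smaller hypergeometric tail. The Fisher branch
matches exhaustive hypergeometric enumeration to $10^{-9}$ over all
tables with $N \le 60$ (tested). Chi-square and Fisher agree closely near
the null but diverge in the far tail for any cell size — the chi-square
approximation, not a bug; the expected-cell rule keeps the chi-square
branch in its valid regime for the small-$K$ tables where it matters.

Annotation propagation (on by default when an ontology is supplied) closes
each gene's term set under is_a ancestry; only is_a edges are honored,
other relationship types are ignored with a warning, and cycles are an
error. A term's level is the shortest is_a path to its namespace root
(root = 0, its children = 1), so "level 3 molecular function" selects
terms three edges below the root; a longest-path alternative sits behind
`mode = "longest"`. Multiple-testing adjustment runs across the tested
terms (not the whole ontology), and enrichment direction is reported by
comparing $k$ with its expectation.

## Synthetic-data generators

The generators define the validation conditions; their defaults are fixed
at the study's scale and are not tuned per experiment.

* `simulateCohort`: four instar durations from discretized gammas (shape
  8, mean 1.85 d each, so the nymph period averages ~7.4 d), daily
  survival 0.98 (nymph) and 0.94 (adult), and Poisson daily offspring
  around a triangular curve peaking at 9 nymphs/day on adult day 4 and
  closing at day 20 — numbers chosen to mimic a thriving cohort of 80 on
  a favorable host (R₀ in the tens, r ≈ 0.25 d⁻¹, λ ≈ 1.3). A hard
  200-day cap bounds pathological parameter choices. A second triangular
  peak can be added to mimic the double-peaked reproduction that shows up
  on marginal hosts. The *analytic* expectation of $l_x$ and $m_x$ is
  computed by convolving the instar-duration pmfs (nymph/adult survival
  products, fecundity averaged over adult entry ages), and the truth
  $r$ comes from solving Euler–Lotka on those expected schedules —
  empirical $l_x$ over $10^4$ individuals agrees within 0.02 (tested).
* `simulateCounts`: log-normal baseline expression (sdlog 1.5), two
  libraries of $10^7$ reads, 4% of 5000 genes changed 4-fold (directions
  split evenly), counts Poisson around proportion × library size — the
  sampling model the Audic–Claverie test assumes; a negative-binomial
  variant is deliberately not the default since replicate-free inference
  cannot identify overdispersion anyway. The altered sample's means are
  rescaled to its library size so column sums match in expectation.
* `simulateEPG`: a semi-Markov chain over the six codes (log-normal
  dwells, transition matrix biased toward long E2 bouts for a
  well-feeding colony), truncated at 18 000 s, so intervals tile the
  recording exactly.
* `simulateAnnotation`: Bernoulli term membership with designated terms
  over-represented among true-DE genes at a stated odds ratio.

All generators are deterministic under a seed (the caller's RNG state is
preserved). What passing on synthetic data shows: the estimators recover
known truth under their own sampling assumptions (Poisson counts,
independent individuals, exact waveform annotations). What it does not
show: robustness to biological overdispersion between real libraries,
annotation errors, waveform misclassification, or cohort heterogeneity —
on real data the DE stage in particular inherits the optimism of all
replicate-free designs.

## Validation scale and numerical choices

The shipped test and acceptance runs use: 1000 random schedules for the
Euler–Lotka residual; 100 simulated cohorts of 500 with $B = 200$
bootstrap replicates for coverage of the truth $r$ (the package default
$B = 2000$ is used for reporting, 200 suffices for an SE inside a
simulation loop); the full $x, y \le 50$ grid at library ratios 1, 2, 10
against a direct-summation oracle; an exhaustive Fisher sweep at
$N \le 60$; $10^4$ gene pairs for null calibration; and 50 end-to-end
replicates for enrichment spike recovery. These sizes make every
stochastic check stable across seeds while keeping a full run in the
minutes range.

Degenerate inputs are handled explicitly rather than silently: zero total
fecundity is an error for $r$ ("no reproduction"), $r = 0$ makes $T$
undefined, cohorts without adults report nymph/adult periods as NA with
$n = 0$, all-constant EPG cells are flagged untestable, zero-in-both
genes are excluded from testing, and an annotation term missing from the
ontology survives propagation unpropagated with a warning.

## Limitations

* The demography is female-only single-cohort bookkeeping: no
  age-stage reproductive value, life expectancy matrices or projection
  beyond $s_{xj}$.
* EPG analysis starts from annotated intervals; raw-voltage waveform
  classification and potential-drop events are upstream of this package,
  and sequential/transition analyses beyond attainment are out of scope.
* The DE stage is strictly two-library replicate-free inference; with
  replicates, a negative-binomial GLM framework is the right tool
  instead.
* GO enrichment honors is_a edges only and tests the tested-terms
  universe; published enriched-term lists additionally depend on the
  annotation pipeline that produced them.
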