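# aphidfit

Quantifying how well an aphid clone performs on alternative host plants.
When a parthenogenetic clone (e.g. a pea-aphid host race reared on
*Vicia faba*) is shifted to related legumes, its fitness change shows up in
three places: cohort demography, stylet feeding behavior, and salivary-gland
gene expression. `aphidfit` implements the complete analysis chain for all
three, plus synthetic-data generators with known ground truth so every stage
can be validated without the original recordings.

## What it computes

**Life-table demography.** From daily records of survival, ecdysis and
newborn nymphs per individual (age 0 = day of birth), the package builds the
age-specific survival rate *l<sub>x</sub>*, age-specific fecundity
*m<sub>x</sub>* and age-stage occupancy *s<sub>xj</sub>*, and estimates

- net reproductive rate  *R₀ = Σₓ lₓ mₓ*,
- intrinsic rate of increase *r*, solved by bisection from the Euler–Lotka
  equation *Σₓ e^(−r(x+1)) lₓ mₓ = 1* (ages indexed from 0; the exponent
  convention is switchable),
- finite rate of increase *λ = eʳ*, mean generation time *T = ln R₀ / r*,
  and the nymph/adult/total period means,

all with bootstrap standard errors (individuals resampled with replacement,
every parameter recomputed per resample).

**EPG feeding behavior.** Electrical penetration graph recordings annotated
with the six waveforms np, C, E1, E2, F, G over a fixed 5 h window are
summarized as per-waveform time ratios (time in waveform / 5 h), compared
between groups by Welch *t* test or one-way ANOVA with Tukey compact-letter
displays, and condensed into feeding-step attainment matrices (fraction of
individuals entering each step).

**Replicate-free differential expression.** For two pooled RNA-seq
libraries: RPKM, TMM normalization factors (30%/5% trimmed, precision
weighted, geometric mean 1), the exact Audic–Claverie Poisson test on raw
counts with TMM-effective library sizes, Benjamini–Hochberg adjustment,
up/down calls at expression ratio ≥ 2 and adjusted *P* < 0.001, and
direction-aware Venn partitioning across 2–3 contrasts.

**GO enrichment.** Chi-square test on the 2×2 list/background × term
table, falling back to a two-sided Fisher exact test whenever any expected
cell is below 5, with BH FDR, optional is_a annotation propagation from an
OBO ontology, and filtering to a chosen GO level.

## Worked example

```r
library(aphidfit)

spec <- cohortSimSpec(n = 80)                 # 80 nymphs followed daily
sim  <- simulateCohort(spec, seed = 11)
pp   <- bootstrapPopulationParameters(sim$cohort, B = 2000, seed = 12)
pp
#> PopulationParameters ('synthetic')
#>   R0               45.6500 +/- 4.5157
#>   r                 0.2468 +/- 0.0076
#>   lambda            1.2799 +/- 0.0098
#>   T                15.4823 +/- 0.2870
#>   nymphPeriod       9.3175 +/- 0.1930
#>   adultPeriod      19.0159 +/- 2.4953
#>   totalLongevity   23.2375 +/- 2.2718
#>   n = 80 ( 63 adults ), B = 2000 , degenerate resamples: 0
sim$truth$r
#> [1] 0.2476444
```

The cohort of 80 produced on average 45.7 offspring per initial individual
(R₀), growing 1.28-fold per day (λ = e^0.247); the generator's analytic
truth r = 0.2476 sits well inside one bootstrap SE of the estimate. The
same objects feed `lifeTableReport()` for a mean ± SE comparison table
across hosts.

Differential expression on a simulated pair of 10-million-read libraries
(200 of 5000 genes truly changed 4-fold):

```r
cs  <- simulateCounts(countSimSpec(), seed = 13)
res <- deContrast(cs$se, "A", "B")
table(res$call)
#> down   ns   up
#>   98 4802  100
head(res[order(res$padj), c("gene_id", "countA", "countB", "ratio", "call")], 3)
#>       gene_id countA countB    ratio call
#> 43  gene00043   1441   5637 4.105049   up
#> 107 gene00107   3949  14754 3.927393   up
#> 141 gene00141   1058   3900 3.864764   up
```

198 of the 200 spiked genes are recovered at ratio ≥ 2 and adjusted
*P* < 0.001 with no false calls; the estimated ratios cluster around the
simulated 4-fold change.

See `vignettes/aphidfit-methods.Rmd` for the models, parameter choices and
limitations, and `runPipeline()` for the end-to-end orchestration with
manifest/checksum output.

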