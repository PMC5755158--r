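---
title: "Methods: enterotypes and quantitative genetics of swine fecal microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enterotypes and quantitative genetics of swine fecal microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model of the data

`herdqg` replays a longitudinal analysis of swine fecal microbiota in which
the community composition of each pig is measured three times — at weaning,
fifteen weeks post weaning, and at the end of the feeding test ("off-test")
— and the within-sample (alpha) diversity of those communities is treated
as a quantitative trait of the *host*. The pipeline has two halves:

1. **Community analysis.** Starting from an OTU count table (samples x
   OTUs, rarefied to a fixed depth), the package computes compositional
   summaries (Good's coverage, PCA of log-centred relative abundances,
   Kruskal-Wallis screens between time points) and discovers
   *enterotypes*: discrete community types found by clustering samples on
   the square-root Jensen-Shannon divergence of their genus profiles with
   partitioning around medoids, choosing the number of clusters by the
   Calinski-Harabasz index.
2. **Quantitative genetics.** The Shannon index and OTU richness of each
   sample become phenotypic records of the animal. An additive genetic
   ("animal") effect with covariance $A\sigma^2_a$ — $A$ the pedigree
   numerator relationship matrix — is estimated by REML together with
   litter, pen, and residual components, yielding heritabilities,
   likelihood-ratio comparisons of nested models, and (bivariately)
   genetic correlations between diversity and production traits such as
   back-fat thickness and average daily gain.

Because the study this design follows deposited no sequence data, the
package ships a synthetic-herd generator that emulates the experimental
design end to end. Every downstream claim the test suite makes is a
*recovery* claim on data with planted truth, not a reproduction of the
original estimates.

## The synthetic herd

`sim_config()` fixes the design: 28 paternal half-sib (sire) families,
~26 dams per sire with one litter each (~728 litters), one or two sampled
progeny per litter (~1200 pigs), pens of 20 paternal half-sibs of a single
sex, six contemporary groups, three birth sites, and two dam lines. Those
constants mirror the study design the pipeline targets; litter counts
close to dam counts motivate nesting exactly one litter per dam. Sexes
alternate within litter, which is the simplest device that reproduces the
near-equal sex split of such designs.

**Traits.** Breeding values for all traits are drawn jointly with
covariance $A \otimes G_0$, realized through a sparse Cholesky factor of
$A$ (a $10^{-8}$ diagonal jitter is added if the factorization fails
numerically). $G_0$ combines per-trait additive variances with a genetic
correlation matrix; if the requested correlation matrix is not positive
semi-definite it is bent to the nearest PSD correlation matrix by
eigenvalue clipping. Litter, pen and residual effects are independent
normals scaled by their components. The default trait table plants lowly
heritable weaning diversity, moderately heritable post-weaning diversity
(h² 0.17–0.19 with litter 0.10 and pen 0.05 fractions), moderately
heritable back fat (h² ~0.3), and moderate negative genetic correlations
between week-15 diversity and production — the parameter regime the
estimation half must be able to recover.

**OTU tables.** Each time point carries two genus-level template
compositions and a mixture weight; every sample draws a latent enterotype
label, genus proportions from a Dirichlet centred on its template
(concentration 60 by default — enough within-type spread to be realistic
while keeping the types separable), and a fixed read depth multinomially.
Genus probabilities are split over a few OTUs per genus with fixed
weights, so OTU-level and genus-level analyses are both meaningful. The
weaning contrast is an *Escherichia*-led low-diversity type against a
*Prevotella*-led high-diversity type; post-weaning contrasts are
*Clostridium*/*Turicibacter*-led versus
*Lactobacillus*/*Streptococcus*-led. Templates decay geometrically over a
~60-genus catalog so a long tail of rare genera is present. A list of
three or more templates per time point is also accepted, which the
negative and k = 3 recovery controls use.

What the generator does **not** emulate: overdispersion beyond the
Dirichlet-multinomial (no zero inflation), sequencing or chimera error,
phylogenetic structure among OTUs, diet or vaccination covariates, and any
coupling between an animal's genetic merit and its community composition
— the trait table and the OTU tables are generated independently. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated model, not robustness to real-data pathologies.

All randomness flows from one root seed through named substreams
(`pedigree`, `design`, `traits`, `otu`), so identical configurations and
seeds give byte-identical outputs and each stage can be regenerated alone.

## Community-analysis choices

- **Pseudocounts.** The log-centred transform replaces zeros with half the
  smallest nonzero value of the matrix (configurable to a fixed value);
  the JSD uses $10^{-10}$ followed by renormalization. The first is
  standard compositional practice; the second only needs to keep the KL
  terms finite and is far below one read at any realistic depth.
- **Natural logarithms everywhere**, matching the Shannon index in nats.
- **Rarefaction** subsamples without replacement (vegan's `rrarefy`);
  samples below the target depth are dropped because sampling more reads
  than exist is undefined. A sample exactly at depth passes through
  unchanged.
- **Sparse-OTU filter** keeps OTUs with a grand total at or above the
  threshold (1200 by default, i.e. 0.01% of a 1200-sample x 10,000-read
  study; the synthetic replays scale this fraction to their own size).
- **Kruskal-Wallis screening** uses midranks with tie correction and
  Bonferroni multiplication by the number of taxa tested; rank tests are
  invariant to monotone transforms, so applying them to log-centred or
  raw relative abundances differs only through row centring.
- **PCA** is the covariance (not correlation) eigendecomposition of the
  column-centred log-centred matrix: the transform centres but does not
  scale. Contributions of taxa to a component are squared loading shares
  in percent.

## Enterotyping choices

- **Distance.** $d = \sqrt{\mathrm{JSD}}$, which is a metric (the triangle
  inequality is property-tested on random triples).
- **PAM.** Deterministic BUILD + SWAP with ties broken by the lowest
  sample index, so clustering is seed-free. When the number of candidate
  medoid subsets is tiny ($\binom{n}{k} \le 300$) the objective is
  minimized by exact enumeration instead: any single-exchange k-medoids
  heuristic, including the reference implementation in the cluster
  package, can stall in a swap-local optimum on a few percent of small
  instances, and at these sizes the exact optimum costs nothing. At
  realistic sample sizes the classical heuristic runs, and its objectives
  are cross-checked against `cluster::pam` in the tests.
- **Cluster number.** The Calinski-Harabasz index needs coordinates for
  its sums of squares, so it is evaluated in a classical
  principal-coordinates embedding of the JSD matrix, dropping
  negative-eigenvalue axes. The search range is k = 2..10. The silhouette
  index is reported alongside but does not drive the choice. A flat CH
  curve — maximum below twice the minimum over the range, a margin chosen
  from the clear gap between planted-structure herds (ratios above 4) and
  single-template controls (ratios below 1.5) — raises a weak-structure
  warning, since the argmax of a flat curve is unstable across data draws.
- **LDA effect sizes.** A two-class re-implementation of the LEfSe idea:
  per-sample rescaling to $10^6$, a Kruskal-Wallis filter at
  $\alpha = 0.05$ on raw p-values, then for each retained genus the
  effect size is $\log_{10}$ of the average of the absolute raw
  class-mean difference and the absolute class-mean difference of the
  genus's component along the unit-norm Fisher discriminant axis (pooled
  covariance ridge-regularized by $10^{-3}$ of its mean diagonal),
  averaged over 30 within-class bootstrap resamples; `n_boot = 0` gives a
  deterministic single fit for testing. Scores are signed by the enriched
  class and the significant set uses the strict threshold |score| > 2.
  Only two-class contrasts are supported, as the pipeline only ever
  contrasts two enterotypes.

## Quantitative-genetics choices

- **A matrix** by the tabular method over the full pedigree. For
  estimation, the submatrix over recorded animals is used directly:
  marginalizing unrecorded ancestors leaves the likelihood unchanged, and
  it keeps the mixed-model algebra at the size of the data. A
  gene-dropping simulation (allele transmission through the pedigree)
  serves as the independent oracle in tests.
- **REML.** All variance-component models reduce to a linear covariance
  structure $V(\theta) = \sum_k \theta_k B_k$ — univariate models
  contribute one matrix per random term ($Z A Z'$, $ZZ'$, $I$), bivariate
  models three parameters (two variances, one covariance) per structure
  with the residual matched on animal. Estimation is average-information
  REML with: step halving on the AI direction; an active-set reduction
  that pins variance components at the floor ($10^{-8}\,\mathrm{var}(y)$)
  when their gradient points outward, so boundary components cannot damp
  the step for the free parameters; and a multiplicative EM-type update
  as fallback when no damped AI step is acceptable. Convergence requires
  both the relative parameter change and the log-likelihood change below
  $10^{-8}$ (200-iteration cap; non-convergence is flagged and the last
  iterate returned). Standard errors come from the inverse AI matrix and
  delta-method propagation for heritabilities and correlations. Sparse
  Matrix algebra keeps a 5000-record animal-model fit at a few seconds,
  because half-sib herds make $V$ block diagonal by sire family.
- **Heritability denominator.** $h^2$ divides the additive variance by
  the sum of *all* fitted components (animal + litter + pen + residual).
  The alternative (excluding pen or litter) is a configuration away from
  the user since all components are returned.
- **Bivariate PSD handling.** If an estimated 2x2 structure leaves the
  PSD cone the covariance is bent to 0.99 of its bound and flagged
  (`bent`); correlations whose variances sit at the floor are reported
  missing rather than as boundary values.
- **Likelihood-ratio tests** between nested random-effect models report
  both the naive $\chi^2_1$ p-value and the boundary-corrected
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture p-value (at a statistic of
  exactly zero the mixture convention yields 0.5). Calibration of the
  mixture test under a null pen effect and its power for a litter effect
  are checked by simulation.
- **Fixed-effect screens** (sex, age x family, birth site, dam line; and
  the enterotype contrast on production traits) are ordinary least
  squares with sequential (type-I) F tests, matching stepwise model
  building; the enterotype contrast is reported in trait units.
  Longitudinal family profiles fit the age x family interaction as a
  random effect in lme4, centre the shrunken cell effects within age, and
  correlate them across ages (pairwise-complete). Contemporary-group
  pre-adjustment recentres each group at the grand mean and is applied to
  the post-weaning time points only; richness receives the same
  adjustment by default, with a flag to disable.

## Problem sizes used in the checks

The recovery studies run at the sizes the claims refer to: the
heritability grid at n = 5000 records (100 sires x 25 dams x 2 progeny)
over h² in {0.05, 0.15, 0.25, 0.35} x litter in {0, 0.1} x pen in
{0, 0.05} with 3 replicates per cell; bivariate recovery of genetic
correlations in {-0.5, 0, 0.8} at the same scale; LRT calibration with
200 replicates at 28 x 6 x 2 and power with 100 replicates at the full
28 x 26 x 2 design with a litter fraction of 0.30; enterotype recovery on
herds of ~240 animals per time point at depth 2000. Replicate counts are
modest by design, with mean-error bounds stated in Monte-Carlo standard
errors.

## Known limitations

- The REML engine is dense-per-block and targets desk-scale problems
  (up to a few thousand records); a sparse A-inverse (Henderson's rules)
  path is a natural extension point for national-evaluation scales.
- Multi-trait (>2) REML, genomic relationship matrices, UniFrac-style
  phylogeny-aware distances, Dirichlet-multinomial mixture enterotyping,
  and zero-inflated differential-abundance models are out of scope.
- The LDA effect size is a faithful two-class analogue, not a line-by-line
  port of the original LEfSe, and its scores should be compared within an
  analysis rather than across tools.
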