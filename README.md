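# herdqg — enterotypes and quantitative genetics of swine fecal microbiota

`herdqg` is an R package and analysis workflow for treating the gut
microbiome of pigs as a set of host phenotypes. It covers the full path
from an OTU count table to genetic parameters:

- **OTU-table processing** — sparse-OTU filtering, rarefaction to a fixed
  depth, taxonomic aggregation, Good's coverage, log-centred
  compositional transforms, Kruskal–Wallis screening with Bonferroni
  correction, and PCA of composition.
- **Enterotype discovery** — square-root Jensen–Shannon divergence (JSD)
  between genus profiles, deterministic partitioning around medoids
  (PAM), cluster-number selection by the Calinski–Harabasz (CH) index
  with silhouettes alongside, LEfSe-style LDA effect sizes of the
  discriminating genera, transition tables of animals between
  enterotypes over time, and sire-family association tests.
- **Alpha-diversity phenotyping** — Shannon index
  (H = −Σ pᵢ ln pᵢ, in nats) and OTU richness per sample, with
  contemporary-group pre-adjustment of post-weaning records.
- **Pedigree-based quantitative genetics** — the numerator relationship
  matrix **A** by the tabular method, and average-information REML for
  the animal model y = Xb + Za + Wl + Qp + e with cov(a) = **A**σ²ₐ and
  identity-covariance litter/pen terms, univariately and bivariately.
  Heritabilities h² = σ²ₐ/σ²_P, genetic correlations
  r_g = cov_a/√(σ²ₐ₁σ²ₐ₂), boundary-corrected (½χ²₀+½χ²₁)
  likelihood-ratio tests between nested models, and delta-method
  standard errors throughout.

Because no real data ship with the study design this package replays, a
**synthetic-herd generator** emulates it end to end: 28 paternal half-sib
families, ~728 litters, single-sex pens of 20, 6 contemporary groups,
three sampling time points (weaning, week 15, off-test), OTU tables at
depth 10,000 with a planted two-enterotype mixture per time point, and
traits generated under the animal model with chosen variance components.
Every claim in the test suite is a *recovery* claim against that planted
truth.

## Worked example

```r
library(herdqg)

cfg  <- sim_config(n_sires = 15, dams_per_sire = 8, depth = 2000, seed = 41)
herd <- simulate_herd(cfg)

# enterotypes at weaning
counts <- filter_sparse_otus(herd$otu$counts$weaning, min_total = 48)
genus  <- relative_abundance(aggregate_taxa(counts, herd$otu$taxonomy, "genus"))
fit    <- select_enterotypes(genus, k_range = 2:6)
fit$chosen_k
#> [1] 2
round(fit$ch_by_k, 1)
#>     2     3     4     5     6
#> 500.0 259.0 176.4 134.7 109.6
adjusted_rand_index(fit$assignments,
                    herd$otu$labels$enterotype[herd$otu$labels$time_point == "weaning"])
#> [1] 1
```

The CH curve peaks sharply at k = 2 — the planted pair of community
types (an *Escherichia*-led low-diversity type and a *Prevotella*-led
high-diversity type) — and the recovered partition matches the latent
labels exactly (adjusted Rand index 1).

```r
# heritability of week-15 Shannon diversity under the full animal model
A   <- numerator_relationship_matrix(herd$pedigree)
dat <- merge(herd$frame, herd$traits$phenotypes, by = "animal")
m5  <- reml_univariate("Sha_15", dat, A = A, random = c("animal", "litter", "pen"))
heritability(m5)
#> $h2
#> [1] 0.1998969
#> $se
#> [1] 0.3212565
```

The generator planted h² = 0.17 for this trait; at 177 records the
estimate is unbiased but carries a large standard error — the reason the
recovery studies below run at n = 5000.

## Analysis workflow

The `analysis/` directory replays the full study on a paper-scale
synthetic herd (~1200 pigs, three time points); each script narrates what
it finds and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_herd.R     # pedigree, design, traits, OTU tables
Rscript analysis/02_composition.R      # filter, rarefy, coverage, KW screen, PCA
Rscript analysis/03_enterotypes.R      # JSD + PAM + CH, LDA scores, transitions
Rscript analysis/04_diversity_models.R # Shannon/richness, fixed-effect models
Rscript analysis/05_genetics.R         # A matrix, REML models 3/4/5, LRT, r_g
```

Scripts 02–05 read the files written by script 01, so run them in order.

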