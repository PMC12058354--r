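# swabdiv

Insect biodiversity from vegetation-swab eDNA, end to end: nanopore
amplicon reads in, habitat-level diversity statistics out.

swabdiv is for ecologists running (or re-analysing) eDNA metabarcoding
surveys in which plant surfaces are swabbed — by hand or by drone — a short
mitochondrial 16S fragment (~215 bp) is amplified and sequenced on a
nanopore device, and the question is which hexapod taxa occur in which
habitat and how richness, evenness and community composition differ between
habitats.

The package covers the whole chain:

* **Read processing** — FASTQ ingest (Phred+33), mean-quality filtering in
  error-probability space (`Q̄ = −10·log₁₀(mean pᵢ)`, threshold 12) and an
  inclusive length window of [115, 315] bases.
* **Clustering** — seeded greedy similarity clustering (batches of 1000
  reads, 97% global identity to the cluster seed), medoid-anchored
  majority-vote consensus sequences, and single-linkage merging of clusters
  whose consensi match at 98%.
* **Taxonomy** — filtering of similarity-search hits (e ≤ 1e−3, identity
  and query coverage ≥ 80%, top 20 by bitscore with ties kept), then a
  combined LCA/threshold rule: the lowest common ancestor of the
  tied-top-bitscore hits, truncated so species requires ≥ 98% identity,
  genus ≥ 96%, family ≥ 90%; Hexapoda-only filtering (Collembola included)
  and collapsing into a taxon-by-sample community matrix.
* **Diversity** — exact sample-based rarefaction
  `E[S(t)] = Σᵢ [1 − C(T−Yᵢ, t)/C(T, t)]`; asymptotic, logistic and
  Lomolino accumulation models with Gaussian-AIC selection; Hill numbers
  (`q0` richness, `q1 = exp(H)` evenness); the Jaccard β-diversity
  partition `β_jac = β_jtu + β_jne`; PERMANOVA (sequential sums of squares
  on the Gower-centred distance matrix, seeded free permutations, add-one
  p-values); PCoA; and exact noncentral-F power analysis for balanced
  one-way ANOVA designs.
* **Synthetic data** — generators for lineage-annotated reference
  sequences with controlled divergence bands, nanopore-like reads with
  known per-read ground truth, and habitat-structured site-by-taxon
  matrices; plus a packaged taxon-by-habitat incidence table of 76 hexapod
  taxa over grassland/shrub/forest sampling (6/6/5 samples).

## Worked example

Habitat asymptotes from the packaged incidence table:

```r
library(swabdiv)
fx <- load_incidence_fixture()
for (h in c("grassland", "shrubs", "forest")) {
  fit <- accumulation_asymptote(fx$incidence[, h], fx$n_samples[[h]])
  cat(sprintf("%-9s observed %2d taxa in %d samples -> asymptote %.1f\n",
              h, sum(fx$incidence[, h] > 0), fx$n_samples[[h]],
              fit$asymptote))
}
#> grassland observed 48 taxa in 6 samples -> asymptote 68.3
#> shrubs    observed 32 taxa in 6 samples -> asymptote 50.6
#> forest    observed 22 taxa in 5 samples -> asymptote 35.7
```

Each habitat's incidence frequencies are rarefied exactly (the forest
curve below: expected richness after 1…5 samples) and the asymptotic
regression model `S(t) = A + (R₀ − A)·exp(−eᶜ·t)` is fitted to the curve;
`A` estimates the taxon richness further sampling would approach.
Grassland is the richest habitat and forest the poorest — the expected
gradient for herbivore-dominated insect communities.

```r
rarefy_exact(fx$incidence[, "forest"], 5)
#> [1]  7.0 12.0 15.8 19.0 22.0

table(fx$rank)
#>  family   genus   order species
#>      22      10       9      35

anova_power_n(k = 3, f = 0.75, alpha = 0.05, target_power = 0.8)
#> balanced one-way ANOVA power: k = 3 , f = 0.75 , alpha = 0.05 , target power = 0.8
#>   continuous solution n per group = 6.8144 -> required n = 7 (attained power 0.813)

beta_pair(rownames(fx$incidence)[fx$incidence[, "grassland"] > 0],
          rownames(fx$incidence)[fx$incidence[, "forest"] > 0])
#>  beta_jac  beta_jtu beta_jnes
#> 0.8333333 0.7058824 0.1274510
```

The grassland–forest comparison shows why turnover matters: 83% Jaccard
dissimilarity, of which five-sixths is true species replacement
(`beta_jtu`) rather than richness-difference nestedness.

For a full run over FASTQ files, write a manifest and a flat `key = value`
configuration and call `run_pipeline(read_run_config("run.cfg"))`, or use
the CLI at `inst/cli/swabdiv` (`filter`, `cluster`, `assign`, `tabulate`,
`diversity`, `run`, `power`, `simulate`, `fixture` subcommands). Every
stage writes its outputs (filtered FASTQ, consensus FASTA, membership and
assignment TSVs, community matrix, diversity JSON) plus a machine-readable
run report that embeds the resolved configuration; identical configuration
and seed give byte-identical reports.

The methods vignette (`vignettes/methods.Rmd`) documents the models, the
parameter defaults and their rationale, the numerical decisions, and what
the synthetic-data generator does and does not emulate.

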