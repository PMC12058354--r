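---
title: "Methods: from swab reads to habitat diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from swab reads to habitat diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swabdiv)
```

swabdiv implements the analysis chain behind drone-assisted insect eDNA
monitoring: vegetation surfaces are swabbed, a ~215 bp mitochondrial 16S
fragment is amplified and sequenced on a nanopore device, and the reads are
turned first into a taxon-by-sample community matrix and then into
habitat-level diversity statements. This vignette records the models, the
parameter choices and the numerical decisions, in the spirit of a lab
notebook rather than a manual; function-level usage lives in the help pages.

## Read filtering

Nanopore amplicon reads arrive demultiplexed, one FASTQ per sample, mapped
to sample metadata by a manifest. Two filters are applied before anything
else:

* **Mean quality ≥ 12.** "Average Q-score" is computed in
  error-probability space: each per-base Phred score is converted to its
  error probability, probabilities are averaged, and the mean is converted
  back ($\bar Q = -10\log_{10}\overline{p}$). This is the convention
  nanopore basecallers use, and it is deliberately pessimistic: a read
  with a stretch of very poor bases cannot be rescued by a long good tail,
  which the arithmetic mean would allow. The arithmetic mean is available
  as an option but is not the default.
* **Length within [115, 315] bases, both bounds inclusive.** The window is
  generous around the 215 bp target because nanopore indel noise spreads
  the length distribution; "shorter than 115" and "longer than 315" are
  read literally, so 115 and 315 survive.

Quality encoding is fixed to Phred+33. Other offsets are rejected, not
guessed: silently reinterpreting qualities is a classic source of
irreproducible filtering.

## Clustering and consensus building

Reads are sorted into putative amplicon groups by a transparent greedy
algorithm: shuffle the reads with a caller-supplied seed, process them in
batches of 1000, compare each read against the seeds of all existing
clusters (a cluster's seed is its first member), join the best seed at
≥ 97% identity, otherwise found a new cluster. After all reads are
assigned, a consensus is built per cluster and clusters whose consensi
match at ≥ 98% are merged by single linkage, with the merged consensus
rebuilt from the pooled members.

Identity is always global (end-to-end Needleman–Wunsch, match +1, mismatch
−1, gap −2 per column, end gaps charged) and is counted as matches over
alignment columns, gaps included in the denominator. Alignments run through
Biostrings; a cheap length-ratio bound (identity ≤ 100·min(len)/max(len))
prunes hopeless comparisons first.

Consensus construction aligns every member to the cluster **medoid** (the
member minimising summed alignment distance to the others; exhaustive for
≤ 200 members, subsampled deterministically above that) and votes per
medoid column. Columns where the gap is the strict plurality are deleted;
ties among bases resolve lexicographically (A < C < G < T); insertions
relative to the medoid are dropped. All of this is deterministic, so a
clustering run is reproducible from (reads, parameters, seed).

Two consequences of these thresholds are worth stating plainly:

* **Congeners lump.** Reference species closer than ~3% cannot be split:
  their reads fall within the 97% membership radius of one another and
  their consensi within the 98% merge radius. Taxa that co-occur in a
  sample and diverge by less than the clustering radius emerge as a single
  cluster whose assignment falls back to the genus by the LCA rule. This
  mirrors the resolution limit of the marker itself.
* **Error-tail reads straggle.** Per-read error is binomial; at ~1–2% mean
  error a few reads carry 5+ edits, fall below 97% against every seed and
  found singleton clusters. The `min_size` export filter (default 1, i.e.
  keep everything) exists for exactly this: setting it to 2–3 reproduces
  the behaviour of established amplicon sorters that leave stray reads
  unassigned. Reads dropped this way are reported, not silently discarded.

## Taxonomic assignment

Similarity-search hits (the 12-column tabular convention plus a query
coverage column) are filtered at e-value ≤ 1e−3, identity ≥ 80% and query
coverage ≥ 80%, keeping the top 20 hits per query by bitscore — with ties
at the cutoff all retained rather than broken arbitrarily. Coverage is
query coverage: the fraction of the consensus that aligns, the
conventional criterion for amplicons where the query, not the reference,
is the fixed-length object.

Assignment then combines two rules. Among the hits tied at the maximal
bitscore, the lowest common ancestor of their lineages forms the candidate;
the maximal identity among those tied hits is compared against rank
thresholds — species kept at ≥ 98%, genus at ≥ 96%, family at ≥ 90% — and
the candidate truncated accordingly. Ranks above family are retained
whenever the candidate resolves them, down to the 80% floor; this is what
produces order-level taxa from distant hits. Which hit's identity to use
when several tie is not uniquely defined; the maximum is taken, the most
permissive choice consistent with the thresholds, so an assignment is never
demoted by a strictly worse tied hit.

Non-target taxa are removed by class: Hexapoda is taken as the classes
Insecta, Collembola, Diplura and Protura, so springtails stay in.
Assignments with no class at all (a bare Metazoa, say) are excluded as too
general rather than lumped with vertebrate contamination — the two
exclusion reasons are reported separately. Queries with identical assigned
lineages collapse into one taxon and their read counts sum per sample;
total reads are conserved between input and (matrix + excluded) output.

## Diversity statistics

All of the statistical layer is computed from first principles and
cross-checked in the test suite against the mature community-ecology
implementations (vegan, ape) on shared inputs.

**Exact rarefaction.** With incidence frequencies $Y_i$ over $T$ sampling
units, the expected richness in $t$ units is
$E[S(t)] = \sum_i \left[1 - \binom{T-Y_i}{t}/\binom{T}{t}\right]$,
the average over all $\binom{T}{t}$ subsets, computed without resampling
(and verified against exhaustive subset enumeration for all $T \le 6$).
Binomials are evaluated on the log scale; `lchoose` returns $-\infty$ for
impossible draws, which the formula turns into a guaranteed detection.

**Accumulation models.** Three classical forms are fitted to the curve by
Levenberg–Marquardt least squares: asymptotic regression
$S(t) = A + (R_0 - A)e^{-e^{c}t}$, logistic
$S(t) = A/(1 + e^{(x_m - t)/s})$, and Lomolino
$S(t) = A/(1 + b^{\log(x_m/t)})$. Starting values are deterministic
heuristics ($A = 1.05\max S$, $R_0 = S(1)$, $c = 0$, $x_m$ = median $t$,
slope/scale from two-point estimates on the linearised curve), with one
jittered restart on a singular start. A constant curve is handled as the
exact degenerate solution $A = R_0 = c$ rather than an optimiser failure.
Model choice uses the Gaussian-likelihood AIC
$n\ln(2\pi\,\mathrm{RSS}/n) + n + 2(p+1)$; the $2\pi$ constant cancels in
comparisons but keeps values meaningful on their own. An RSS below 1e−12
is floored there so that an exact fit has a finite (and winning) AIC. Ties
resolve toward fewer parameters, then model name. Non-convergence flags
the fit; flagged fits are excluded from selection rather than hidden.
Asymptote fits are only attempted for habitats with at least three
samples — below that the curve has too few points to constrain any of the
three forms.

**Hill numbers.** $^qD = (\sum p_i^q)^{1/(1-q)}$ with the $q\to1$ limit
$\exp(-\sum p_i \ln p_i)$; $q_0$ is richness, $q_1$ the evenness summary.
Evenness is computed per sample and then compared across habitats — the
per-sample reading is taken because pooling reads across samples would
conflate depth differences with evenness.

**β-diversity.** The Jaccard dissimilarity is partitioned into turnover
and nestedness: $\beta_{jac} = (b+c)/(a+b+c)$,
$\beta_{jtu} = 2\min(b,c)/(a + 2\min(b,c))$,
$\beta_{jne} = \beta_{jac} - \beta_{jtu}$. The partition is additive,
bounded and symmetric by construction; the suite fuzzes this on 10^4
random set pairs.

**PERMANOVA.** The distance matrix is Gower-centred
($G = CAC$ with $A = -\tfrac12 D^2$), term sums of squares are traces of
projector increments against $G$ with sequential (type-I) sums of squares
in the order habitat, replicate, time — the order in which the design
would be controlled — and the pseudo-F of each term uses the full-model
residual. p-values come from free permutation of samples with the add-one
convention, so the smallest attainable p is $1/(n_{perm}+1)$; permutations
are seeded and the projectors are computed once, making 999 permutations
effectively free at these sample sizes. Projectors are built by QR, so
aliased (collinear) terms lose their redundant columns instead of crashing
the solve. For semi-metric dissimilarities such as the turnover component,
individual term sums of squares can be negative on small designs — a known
property of the method, inherited from the negative eigenvalues of $G$,
not an implementation artefact.

**PCoA.** Eigendecomposition of the same $G$; axes are eigenvectors
scaled by $\sqrt{\lambda}$ for eigenvalues above a relative tolerance of
1e−9 of the spectral radius. Negative eigenvalues are reported and their
axes dropped; on genuinely Euclidean inputs the embedding reproduces the
distances to 1e−9, which the suite asserts on random planar and spatial
configurations.

**Power analysis.** For a balanced one-way ANOVA with $k$ groups and
Cohen effect size $f$, power is computed exactly from the noncentral F
distribution with noncentrality $\lambda = k n f^2$. The design equation
is inverted for the continuous $n^*$, and the reported requirement is the
smallest integer n whose power reaches the target. For the field design of
interest ($k=3$, $f=0.75$, $\alpha=0.05$, power 0.8) the continuous
solution is $n^* = 6.81$, so the minimal adequate integer design is 7 per
group; the attained power at 6 per group is 0.73. Both the continuous
solution and the attained powers are returned, because rounding
conventions — not the distribution theory — are where power analyses
diverge in practice.

## The synthetic-data generator

The generator exists to give the pipeline inputs whose truth is known. Its
defaults emulate the field study's conditions: three habitats sampled
6/6/5 times; a per-sample mean richness gradient of 14/8/7 taxa
(grassland > shrubs > forest, the observed per-sample means); habitat
taxon pools of 48/32/22 taxa sharing a small common core
(`pool_overlap = 0.15`, giving the high between-habitat turnover the field
data show); 215 bp amplicons; and ~2% per-base read error split as 1%
substitutions and 0.5% each insertions and deletions, a plausible figure
for quality-filtered nanopore amplicon reads. One read in ten is generated
with mean quality deliberately below the Q12 threshold and flagged, so the
quality filter can be validated read-for-read.

Reference sequences are built by seeded mutation along a lineage tree with
exact per-level substitution counts (species ~0.5%, genus ~2.5%, family
~12% from their ancestors), which pins the identity bands the taxonomy
thresholds need: congeneric species align above 98%, confamilial genera
between 90 and 96%, cross-family pairs below 90%. The bands are verified
with the package's own aligner and the construction is rejection-sampled
until they hold.

What the generator does **not** emulate: homopolymer-specific nanopore
errors, PCR chimeras, abundance-biased amplification, contamination and
tag jumps, or any spatial structure within a habitat. Passing the
recovery tests therefore demonstrates that the algorithms do what they
claim on data matching their assumptions — not that the field protocol is
free of those artefacts.

## Sizes used in the tests

The suite is sized to run on one core in a few minutes: end-to-end
recovery uses 4–8 reference taxa and 40–100 reads; clustering property
checks use 24–36 reads per scenario; the PERMANOVA null check uses 100
seeded label shuffles at 199 permutations each over 18 samples; fuzz
suites run 10^4 (β partition) and a few hundred (LCA, rank monotonicity)
cases. The rarefaction oracle enumerates all subsets exhaustively up to
T = 6, which is also the largest T in the packaged incidence table.

## Known limitations

* The clustering stage is a faithful but simple greedy sorter; it is not
  a drop-in reimplementation of any particular published tool, and its
  seed-dependence (which read founds a cluster) is resolved by an explicit
  RNG seed rather than by iterative refinement.
* Taxa within the clustering radius of one another are reported at their
  LCA, typically the genus; this is a marker-resolution limit, not a bug,
  but it means species-level completeness depends on the local fauna's
  divergence structure.
* The incidence table packaged with swabdiv supports habitat-level
  inference (rarefaction, asymptotes, rank bookkeeping). Per-sample
  analyses on the original field data (GLM contrasts, evenness tests,
  PERMANOVA on the real design) require the per-sample matrix, which is
  not part of the package; those methods are exercised on synthetic data.
* PERMANOVA assumes exchangeability of samples under the null; the
  pipeline permutes freely and does not implement restricted permutation
  within blocks.
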