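---
title: "Comparative phylogenomics of lifestyle-linked traits and BGCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phylogenomics of lifestyle-linked traits and BGCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanotraits)
```

## The scientific problem

Many cyanobacteria live in mutualistic symbioses with plants, fungi, diatoms
and other eukaryotes, while close relatives remain free-living. Given a
phylogeny over a genome collection, per-genome quality and lifestyle
metadata, KEGG-ortholog (KO) annotations and predicted biosynthetic gene
clusters (BGCs), `cyanotraits` asks which molecular functions and which
families of secondary-metabolite clusters are enriched or depleted in
host-associated lineages — while accounting for the fact that related
genomes are not independent observations. The package implements the whole
analysis chain: trait-matrix construction, BGC grouping, phylogenetic
regression, and phylogenetic-signal testing, plus a synthetic-data
generator that makes every stage testable end to end.

## Trait construction from KO annotations

A molecular function is described as an ordered list of *steps*; each step
is a boolean expression over KO identifiers, with `,` meaning OR
(alternative orthologs), `+` meaning AND (complex subunits, binding tighter
than `,`), and parentheses for grouping. Completeness of a function in a
genome is the unweighted fraction of satisfied steps. Two presets binarise
completeness into traits, both with strict inequalities: **complete**
functions (`> 0.98`) and **indicative** functions (`> 0.50`). Definitions
are a declarative input file rather than hard-coded rules, so the pipeline
is correct for any definition set; the definitions shipped under
`inst/extdata/` are plausible multi-step stubs for well-known functions
(nitrogen fixation, photosystem II, secretion systems, ...), not a copy of
any external tool's rule base. Genome QC uses strict thresholds as well:
retained genomes are `> 90%` complete with `< 5%` contamination, so
boundary genomes are excluded.

For fixed pathways of interest the package also maps raw ortholog presence:
`nitrogen_fixation_pathways()` encodes the Fe–Mo (nif) and V-dependent
(vnf) nitrogenase orthologs, with `K00531` (anfG) and `K22899` (vnfH)
marked *known-absent* — systematically missing in cyanobacteria — so a
pathway can be called detected without them.

## BGC grouping by domain composition

Predicted clusters are first filtered: records at contig edges (start at 1
or end at the contig length, or an explicit flag) are removed, as are
records shorter than 3000 bp — *shorter than*, so a 3000 bp cluster
survives. Each surviving record is reduced to its *set* of protein-domain
accessions. Pairwise Sørensen–Dice similarity, `2|A∩B| / (|A|+|B|)`,
defines a weighted graph over records; an edge requires Dice at or above a
threshold whose default is 0.5 ("a majority of domains shared" — the
grouping literature does not fix a value, so it is exposed as a parameter
and worth a sensitivity check on real data). Louvain community detection on
this weighted graph yields the BGC groups. Design choices made here:

* **Set, not multiset, domain composition** — conventional for
  domain-composition similarity; duplicated domains carry little signal.
* **Weighted Louvain** — edges carry their Dice weight rather than being
  collapsed to 0/1.
* **Isolated records become singleton groups** rather than being dropped,
  so the partition always covers every filtered record (a conservation
  property the tests assert).
* **Deterministic, seeded node order.** Louvain's local-move phase visits
  nodes in a seeded shuffle of the sorted ids; identical inputs and seed
  give identical partitions. Modularity at resolution `γ` is
  `Q = Σ_c [Σin_c/2m − γ(Σtot_c/2m)²]`, and the returned `Q` is recomputed
  independently from the final partition as an internal consistency check.

Each group receives a consensus class (majority of member classes, ties
broken lexicographically; hybrid `+`-joined labels count as their own
class). Groups containing at least one record from an annotation-backed
source (antiSMASH-style or reference clusters) are retained for analysis;
a genome × group presence matrix and per-genome count tables (total and per
class) feed the regressions. An external reference collection is supported
simply as additional records (source `antismash`/`mibig`) mixed into the
same graph, not as a mandatory download.

## Phylogenetic regressions

### Binary traits: Firth-penalised phylogenetic logistic regression

`phyloglm_firth()` models `logit P(y_i = 1) = x_i'β` at the tips of the
tree, with phylogenetic dependence controlled by a rate parameter `α`: the
working correlation between tips `i` and `j` is `exp(−α d_ij)` with `d_ij`
the patristic distance on the tree rescaled internally to unit height
(`log α` is searched in `[−4, 4]` on that scale, a range wide enough to
span near-Brownian to effectively independent tips; `α` is reported back on
the original branch-length scale). `β` solves the Firth-adjusted
generalised score equations

```
X' A^{1/2} R(α)^{-1} A^{-1/2} (y − p)  +  a(β) = 0,   A = diag(p(1−p)),
```

where `a_r = tr(I^{-1} ∂I/∂β_r)/2` is the Firth bias-reduction adjustment
built from the information matrix `I = X' A^{1/2} R^{-1} A^{1/2} X`. Two
properties anchor this construction and are enforced by tests:

* with `R = I` the equations are *exactly* the modified score equations of
  Firth-penalised logistic regression, so on a star tree (or whenever the
  data carry no residual correlation, pushing `α` to the independent end)
  the fit reproduces plain Firth logistic regression; and
* the Firth penalty keeps `β` finite under complete separation — important
  because rare traits concentrated in one clade separate perfectly quite
  often in these screens.

`α` maximises the Gaussian pseudo-likelihood of the Pearson residuals; the
fit alternates `β` and `α` updates (Newton steps with step-halving,
gradient tolerance `1e-8`, up to 200 iterations; outer alternation to a
`1e-6` coefficient tolerance). Non-convergent traits are flagged, never
silently dropped.

Inference: Wald p-values from the information matrix are reported
alongside a parametric-bootstrap p-value, which is the headline because the
bootstrap is an explicit part of the procedure (default `B = 100`).
Bootstrap replicates simulate the trait along the tree under the fitted
model via a Gaussian copula with correlation `R(α̂)` and exact marginal
probabilities `p̂`, then re-estimate `β` with `α` held at its point
estimate (a stabilisation that also keeps 100 refits cheap); the two-sided
p-value is `(1 + #{|β*−β̂| ≥ |β̂|})/(B_ok + 1)`.

### Counts: Pagel's-λ phylogenetic linear regression

`phylolm_lambda()` fits `y = Xβ + ε`, `ε ~ N(0, σ² V_λ)` where `V_λ`
multiplies the off-diagonal Brownian covariances by `λ ∈ [0, 1]` (diagonal
unchanged). For fixed `λ` the GLS solution is closed-form; `λ` is profiled
on a 0.01 grid and refined by bounded optimisation (tolerance `1e-6`).
Estimates stay on the raw count scale, so a coefficient of `−4` means
"four fewer clusters on average in host-associated genomes". Wald t-tests
(df `n − p`) and the same style of parametric bootstrap (λ re-profiled on a
0.05 grid per replicate, with cached factorisations) provide p-values.

### Enrichment scans

`enrichment_scan()` (binary traits) and `count_enrichment_scan()` (counts)
fit one regression per column against a lifestyle (or host-source) factor
whose first level is the baseline; positive estimates mean enrichment in
the non-baseline (host-associated) level. The significance flag is an
uncorrected `p < 0.05` on the headline p-value — deliberately so, to match
the screening convention this pipeline follows; a Benjamini–Hochberg column
is emitted for transparency but does not drive the flag. Per-trait RNG
seeds are derived by hashing the global seed with the trait id, so results
are independent of scan order and stable under parallel or partial
execution.

## Phylogenetic signal: the Fritz–Purvis D-statistic

For a binary trait, nodal values are estimated tips-to-root with each
internal node the arithmetic mean of its children; `d_obs` is the summed
absolute difference contributed at each node (for a bifurcation,
`|v_left − v_right|`; polytomies sum `|child − mean|` over all children).
`d_obs` is scaled between the mean `d` of `n_null` random tip shuffles
(no signal; expectation of `D` is 1) and the mean `d` of `n_null`
Brownian-threshold simulations at the observed prevalence (Brownian
clumping; expectation 0):

```
D = (d_obs − mean d_Brownian) / (mean d_random − mean d_Brownian)
```

`D` can legitimately fall outside `[0, 1]`. `p_random` is the fraction of
shuffled `d` at or below `d_obs` (clumping), `p_brownian` the fraction of
Brownian `d` at or above it. The Brownian null thresholds the simulated
liabilities at the empirical quantile so the simulated prevalence equals
the observed prevalence *exactly* — this keeps null and observed `d` on the
same scale, which is what makes the calibration tests meaningful. The
default of 1000 null sets matches common practice; zero-length branches
simply add no Brownian variance. With a fixed seed the whole computation is
bit-reproducible.

## The synthetic study

`simulate_study()` generates data with the statistical structure of a
phylum-scale survey, at desk scale. Defaults (the study conditions the
tests and the acceptance script use):

| parameter | default | what it emulates |
|---|---|---|
| `n_tips` | 300 | a family-scale tree (Nostocaceae-like) |
| tree model | Yule, rate 1 | pure-birth; fewer parameters than birth–death and sufficient for calibrating comparative statistics |
| `n_host_clades` | 8 | monophyletic host clades, one category each (2–10 tips) |
| `qc_fail_rate` | 0.1 | genomes failing CheckM-style QC |
| `n_functions` | 40 | KO-defined functions; function 1 planted at prevalence 0.9 (host) vs 0.1 (free), the rest null with baselines spread over (0.15, 0.85) |
| `n_archetypes` | 30 | BGC domain archetypes (disjoint domain pools of 5–30 domains); archetype 1 planted at 0.9 vs 0.1 |
| `count_shift` | 4 | mean reduction of total BGC count in host-associated genomes, applied by scaling non-planted host prevalences |
| `domain_dropout`, `domain_gain` | 0.05, 0.05 | annotation noise on emitted domain sets |
| `decoy_short_rate`, `decoy_edge_rate` | 0.05, 0.05 | records violating the length/edge filters, with ground truth |
| `antismash_fraction` | 0.3 | records labelled with an annotation-backed source |

Trait presence is drawn from the planted logistic model given lifestyle
(optionally with Brownian-liability correlation along the tree,
`phylo_signal_traits = TRUE`, off by default so regression calibration can
be examined with and without tree signal); present traits receive every KO
of the function, absent traits a uniformly drawn proper subset of steps, so
the generator's truth table coincides exactly with
`classify_traits(completeness_matrix(...), 0.98)` — a construction
round-trip the tests assert. KO pools are disjoint across functions so no
trait leaks into another.

What the generator does *not* emulate: real KEGG-Decoder rule sets,
overlapping KO usage across pathways, correlated habitat/lifestyle
confounding, genome incompleteness biasing annotation, or BGC archetypes
with partially shared domains. Passing tests therefore demonstrate that the
estimators and the pipeline recover the structure they claim to recover
under controlled conditions — not that any particular biological conclusion
holds on real data.

## Numerical choices and degenerate inputs

* Trees are used exactly as given (no ultrametricisation); branch lengths
  must be non-negative, tips unique.
* Working correlation matrices get a tiny escalating diagonal ridge
  (`1e-10` to `1e-6`) only if a Cholesky factorisation fails; patristic
  distance matrices are symmetrised against floating-point asymmetry.
* Constant responses, single-class traits, singular designs and constant
  predictors are rejected with explicit errors; scan wrappers convert
  per-trait failures into flagged rows instead of aborting the scan.
* Consensus-class ties break lexicographically; Louvain ties resolve by
  the seeded visit order, and community ids are renumbered by first
  appearance over sorted node ids so output labels are deterministic.
* All-zero count columns are flagged degenerate and excluded from the
  significance report body (but kept as rows).

## Problem sizes used in the checks

The shipped tests and `scripts/acceptance.R` run the study at its default
scale (300 tips) for the end-to-end and group-recovery checks, 100-tip
trees with 100–200 replicates for regression parameter recovery and type-I
calibration, 50-tip trees with 200-replicate null sets for D-statistic
calibration, and 50-tip star trees for the Firth-equivalence check. These
sizes were chosen to give stable Monte-Carlo estimates in minutes on a
single core.

## Known limitations

* The logistic model's `α` is a working-correlation parameter estimated by
  pseudo-likelihood, not a fully efficient joint MLE; its value is best
  read comparatively (large `α` = little residual signal).
* Bootstrap p-values have resolution `1/(B+1)`; with the default `B = 100`
  the smallest attainable p is ≈ 0.0099.
* The D-statistic is computed per trait without multiplicity control, as is
  the enrichment flag (by design, see above).
* `find_host_clades()` reports maximal single-category clades with ≥ 2
  tips; two adjacent planted clades of the same category merge, which the
  generator avoids by assigning distinct categories to adjacent clades.
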