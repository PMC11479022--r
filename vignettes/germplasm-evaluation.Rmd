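---
title: "Comprehensive evaluation of germplasm from morphological descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive evaluation of germplasm from morphological descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germeval)
library(dplyr)
```

## The problem

Germplasm collections — living samples of a crop gathered across its growing
regions — are characterised with standardised morphological descriptors
(IPGRI codes) long before any molecular data exist. From a table of
accessions by traits, a breeder wants three things: a measure of how much
phenotypic diversity each trait carries, an objective composite score to
rank accessions and pick "excellent" material, and a grouping of the
collection that a conservation strategy can cover. germeval implements this
workflow end to end for categorical descriptor data, with a built-in
synthetic generator emulating a 288-accession cardamom
(*Elettaria cardamomum*) collection so the whole pipeline can be exercised
and tested without field data.

## The model, step by step

### Trait diversity

Each trait's diversity is the Shannon–Wiener index of its class frequencies,

$$H' = -\sum_i P_i \ln P_i,$$

in nats, where $P_i$ is the share of accessions in class $i$. $H'$ is 0 when
every accession shares one class and $\ln k$ when $k$ classes are equally
frequent. The two quantitative traits (cluster internodal length, cm;
capsules per cluster, count) are first stratified into ten levels centred on
the trait mean $\bar X$ with cut points every $0.5\sigma$: level 1 is
$x < \bar X - 2\sigma$, level 10 is $x \ge \bar X + 2\sigma$, and levels 2–9
are half-open intervals $[\text{lower}, \text{upper})$. The half-open
convention (and the closed lower endpoint of level 10) is forced by the
outer-level definitions; it makes the ten levels a complete partition of the
real line, with the mean itself falling in level 6. The standard deviation
uses the $n-1$ denominator, the default of the statistical software this
field works with; `make_binning()` accepts explicit `mean`/`sd` overrides
when published summaries should define the scale instead of the data at
hand.

```{r diversity}
tab <- simulate_accessions(n = 288, seed = 1)
prof <- diversity_profile(tab)
prof |> select(trait, kind, h_prime) |> arrange(desc(h_prime)) |> head()
attr(prof, "summary")
```

### Indicator encoding and covariance PCA

All traits are expanded to presence/absence indicators: one column per
descriptor class, and ten per quantitative trait (its sigma-levels). For the
default cardamom scheme this yields 49 + 20 = 69 columns; every accession
has exactly one 1 per trait, so row sums equal 17. No reference category is
dropped — downstream PCA tolerates the resulting collinearity, and keeping
every class makes loading tables directly readable.

The PCA is an eigendecomposition of the sample covariance matrix of the raw
0/1 columns. Covariance (not correlation) scaling is deliberate: a class
held by 2 of 288 accessions has a tiny variance and should contribute
little, rather than being inflated to unit variance. The contribution rate
of component $j$ is $100\,\lambda_j/\sum_k \lambda_k$. Components are
selected by the leading run with contribution rate at or above 6% (falling
back to the first three when nothing clears the threshold), or by a fixed
`top_k`; in the cardamom study design the 6% rule selects the first three
components.

Numerical choices: eigenvectors have unit norm and a deterministic sign
(the largest-absolute loading of each component is made positive), since an
eigenvector's sign is otherwise backend-arbitrary and a sign flip would
invert the membership scale below. Tied eigenvalues leave the rotation
within their eigenspace undetermined; germeval keeps the solver's stable
order, and tests compare rotation-invariant quantities in tied cases.

```{r pca}
ind <- encode_indicators(tab)
pca <- fit_pca(ind)
glance(pca) |> head(4)
sel <- select_components(pca, "min_contribution", threshold = 6)
sel
```

### The composite F-value

Scores on each selected component are rescaled to fuzzy memberships
$u_{ij} = (S_{ij} - \min_i S_{ij})/(\max_i S_{ij} - \min_i S_{ij})$, and the
morphological composite value is the weighted sum

$$F_i = \sum_j w_j\, u_{ij}, \qquad
  w_j = c_j \Big/ \textstyle\sum_{k \in \text{sel}} c_k,$$

with $c_j$ the contribution rates. Normalising the weights over the
*selected* components makes the weights sum to one, so $F \in [0,1]$ with 0
and 1 attainable; the alternative (`normalize_over = "all"`), which divides
by the total contribution, is exposed because the comprehensive-evaluation
literature is not explicit on this point and published F ranges are
consistent with either. A degenerate component (constant scores) maps to
membership 0.5 with a warning rather than an error, carrying no ranking
information. Ranking is dense (ties share a rank) with ties broken by
ascending accession id, so selection is reproducible and independent of row
order.

```{r fvalue}
f <- membership_rescale(pca$scores, sel) |> f_value(pca, sel)
range(f$f_value)
head(rank_and_select(f, 14))
```

### The selection equation

Because $F$ is, by construction, an affine function of the indicator
columns, a regression of $F$ on the indicators can recover it essentially
exactly — that identity is a tested invariant. The practical tool is a
*compact* equation: classical stepwise OLS with partial-$F$ entry at
$\alpha_{\text{in}} = 0.05$ and removal at $\alpha_{\text{out}} = 0.10$
(the common defaults of SPSS-style stepwise procedures). Candidates that
are perfectly collinear with the current model — inevitable with complete
one-hot blocks — are skipped with a warning rather than fitted with a
pseudoinverse, mirroring how stepwise software behaves. With a pure-noise
response the procedure returns the intercept-only model at the expected
type-I rate; with few candidates its fit matches the exhaustive best-subset
optimum in tests.

```{r stepwise}
sw <- suppressWarnings(fit_stepwise(ind, f$f_value))
glance(sw)
tidy(sw) |> head()
```

### Grouping, varieties, and the two-stage conservation set

Accessions are clustered on their selected PC scores with plain Euclidean
distance and unweighted average linkage (UPGMA — the "between-groups"
linkage of common statistical packages, which default to *squared*
Euclidean; `squared = TRUE` reproduces that convention). The tree is cut at
a configured `k` (six in the cardamom design; germeval does not guess an
optimal `k` because the workflow it implements fixes one), labels are
assigned in order of first appearance, and each group is profiled by the
percentage of members per trait class, flagging classes at or above 80% as
the group's defining features.

Two visual variety rules are provided for cardamom: by stature (plants over
3 m are 'Mysore'/'Vazhukka', the rest 'Malabar') and by capsule colour
(light green or yellow capsules are 'Malabar'; green or dark green,
'Mysore'/'Vazhukka'). Their agreement is reported, never assumed.

The conservation selection runs in two stages: stage 1 takes the top
$k_1 = 14$ accessions by F-value over the whole collection; stage 2 re-runs
the *entire* analysis — fresh binnings, fresh PCA axes, fresh memberships —
on the height-defined Mysore/Vazhukka subset alone and adds its top
$k_2 = 12$ accessions not already selected, skipping duplicates so the
union is exactly $k_1 + k_2$. The fresh re-analysis (rather than reusing
stage-1 axes) is a design choice: a subset-specific evaluation produces its
own selection equation, which is how the workflow treats the second
cultivar in practice. Average subset diversity is computed on the full
table's binning scale so the two stages are comparable. Entropy of a larger
subset is *not* monotonically larger, so the union-vs-stage-1 diversity
gain is checked as a frequent (not certain) outcome over seeded replicates.

```{r twostage}
dend <- linkage_average(pca$scores, sel)
partition <- cut_k(dend, 6)
cons <- two_stage_selection(tab, partition = partition)
cons
coverage_check(cons, partition)$counts
```

## The synthetic generator

`simulate_accessions()` emulates the cardamom collection the analysis was
designed around: 288 accessions, categorical classes drawn from the
collection's observed marginal frequencies (`cardamom_class_counts()`), and
the two quantitative traits from truncated normals with the collection's
mean, SD and range (internodal length 2.79 ± 1.55 cm on [0.5, 18], to
0.1 cm; capsules per cluster 10.75 ± 3.74 on [3, 25], integer). The normal
is the simplest model consistent with those four summaries; its sigma-level
histogram is smooth, so the generator reproduces the *summaries* of the
quantitative traits, not the collection's exact (and irregular) level
counts. In single-group mode traits are sampled independently — only the
marginals are published — which means single-group data carry no real trait
correlations: PCA on them has a flat spectrum and clustering is
structure-free. Multi-group mode is the mechanism that induces
correlations: per-group class probabilities are drawn from a Dirichlet
centred on the marginals with $\alpha = \text{concentration} \times
\text{marginal}$, so smaller `concentration` means stronger divergence
(at 0.5, two planted groups are recovered by the PCA-plus-UPGMA pipeline
with Rand index above 0.9 in tests). Passing tests on synthetic data
therefore show the machinery is correct under the stated generating model
— not that real cardamom accessions satisfy that model.

## Problem sizes and limitations

The test suite exercises the pipeline at the collection's own scale (288
accessions, 69 indicators) for the end-to-end and calibration checks, with
oracle comparisons (SVD eigensolver, brute-force UPGMA, exhaustive best
subsets, direct entropy summation) at small n where exhaustive computation
is exact; replicate counts are 50–100 for the frequency-based checks.

Known limitations: classes are treated as purely nominal (no ordinal
distance semantics); missing values are rejected rather than imputed; no
factor rotation, no robust/sparse PCA, no regularised alternatives to the
stepwise equation; no automatic choice of the number of groups. The
published loading tables of the cardamom study cannot be reproduced without
its unpublished raw data; the structural properties above (bounds,
identities, oracle agreement) are what the package asserts instead.
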