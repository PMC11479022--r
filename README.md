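# germeval

Morphological diversity and comprehensive evaluation of crop germplasm
collections.

Plant genetic resources programmes characterise their collections with
standardised IPGRI-style morphological descriptors — categorical classes
like plant height `2-3 m` or capsule colour `Light green`, plus a few
measured traits — and need, from that single table, three deliverables: a
per-trait diversity assessment, an objective ranking that picks "excellent"
accessions, and a grouping of the collection that a conservation strategy
can cover. `germeval` implements this workflow, modelled on the
comprehensive-evaluation studies used for cardamom (*Elettaria
cardamomum*), maize, apple and similar crops, as a tidyverse-style R
package: data frames in, tibbles out, `tidy()`/`glance()`/`autoplot()` on
fitted objects.

## The method

Starting from an accession × trait table:

1. **Diversity** — each trait's Shannon–Wiener index
   *H′ = −Σ Pᵢ ln Pᵢ* over its class frequencies; quantitative traits are
   first binned into ten levels of width 0.5σ centred on the mean (level 1:
   x < X̄ − 2σ; level 10: x ≥ X̄ + 2σ).
2. **Encoding** — every trait class becomes a 0/1 indicator column (one-hot
   per trait; 69 columns for the default 17-trait cardamom scheme).
3. **Covariance PCA** — eigendecomposition of the indicator covariance
   matrix; components are kept while their contribution rate
   *cⱼ = 100 λⱼ / Σλ* stays at or above 6%.
4. **F-value** — per-component min–max membership rescaling of the scores,
   then the morphological composite value *Fᵢ = Σⱼ wⱼ uᵢⱼ* with weights
   *wⱼ ∝ cⱼ* normalised over the selected components; accessions are ranked
   by F.
5. **Selection equation** — stepwise OLS of F on the indicators
   (partial-F entry 0.05 / removal 0.10) yields a compact equation naming
   the trait classes that drive selection.
6. **Grouping** — UPGMA (between-groups average linkage) on Euclidean
   distances between PC scores; groups are profiled by class percentages
   with an 80% dominance rule.
7. **Two-stage conservation** — top-14 overall, then a fresh re-analysis of
   the height-defined 'Mysore'/'Vazhukka' subset adds 12 more, giving a
   26-accession conservation set whose group coverage and average H′ are
   reported.

A seeded generator, `simulate_accessions()`, emulates the 288-accession
cardamom collection (observed categorical marginals; truncated-normal
quantitative traits; optional planted group structure), so the full
pipeline runs and is tested without any field data.

## Worked example

```r
library(germeval)
library(dplyr)

tab <- simulate_accessions(n = 288, seed = 42)

diversity_profile(tab) |> select(trait, kind, h_prime) |>
  arrange(desc(h_prime)) |> head(3)
#> 1 capsules_per_cluster quantitative    2.05
#> 2 internodal_length    quantitative    2.05
#> 3 stems_per_plant      categorical     1.30

ind <- encode_indicators(tab)
pca <- fit_pca(ind)
glance(pca) |> head(3)
#>   component eigenvalue contribution_rate cumulative_rate
#> 1 PC1            0.547              7.37            7.37
#> 2 PC2            0.482              6.50           13.9
#> 3 PC3            0.463              6.24           20.1

sel <- select_components(pca)          # contribution >= 6%: PC1-PC3
f <- membership_rescale(pca$scores, sel) |> f_value(pca, sel)
round(range(f$f_value), 3)
#> 0.182 0.805

dend <- linkage_average(pca$scores, sel)
partition <- cut_k(dend, 6)
cons <- two_stage_selection(tab, partition = partition)
cons
#> Two-stage conservation selection: 14 + 12 = 26 accessions
#> Average H': stage 1 = 0.552  union = 0.695
```

The diversity profile says which descriptors actually discriminate among
accessions (here the two quantitative traits, binned to ten levels, carry
the most information). The F-value range shows the composite score spreads
accessions well inside its [0, 1] bounds, and the two-stage selection
reports the diversity gained by adding the under-represented tall cultivar:
the 26-accession union averages H′ = 0.695 against 0.552 for the top-14
alone.

`run_pipeline()` chains all of the above and can write a report bundle
(diversity, loadings, ranking, group profiles, conservation table, selection
equation, Newick dendrogram, run log) to a directory.

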