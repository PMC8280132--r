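# ppiclust

Pathway discovery for schizophrenia (SCZ) and bipolar disorder (BD) from
metabolite biomarkers, via protein–protein interaction (PPI) network
clustering.

Diagnosis of these disorders is still interview-based, and individual
metabolite biomarkers have proven hard to replicate. `ppiclust` implements a
systems-level alternative for researchers working with such biomarker
panels: instead of interpreting metabolites one at a time, it pools them,
maps them to the proteins that handle them, and asks which biological
pathways are repeatedly implicated by the densely interacting protein
modules around them.

## The method

Starting from a biomarker list and four reference tables (metabolite→protein
associations, a compound/enzyme metabolic graph, a scored interaction list,
a disease-gene reference) plus pathway gene sets in GMT format:

1. **Seed mapping.** Each biomarker contributes its associated proteins
   plus every enzyme within path length 2 on the metabolic graph; the union
   over biomarkers is the seed set *S*.
2. **Disease network.** An interaction (*a*, *b*, score) is kept if
   *a*, *b* ∈ *S* (any score) or exactly one endpoint is in *S* and
   score > 0.7.
3. **Overlapping clustering.** A density-periphery algorithm (DPClus
   family) grows clusters from high-weight seeds under a density threshold
   *d*<sub>in</sub> and a cluster-property threshold
   *cp*<sub>nk</sub> = *E*<sub>nk</sub>/(*d*<sub>k</sub>·|*N*<sub>k</sub>|) ≥ 0.5,
   guaranteeing that every node lands in at least one cluster and that
   every multi-node cluster has density ≥ *d*<sub>in</sub>. The sweep runs
   at *d*<sub>in</sub> = 0.1, …, 0.9.
4. **Significance and density selection.** Clusters are scored by the
   one-sided Fisher's exact test for disease-gene enrichment with
   Bonferroni and Benjamini–Hochberg correction (selection at FDR < 0.05).
   Each protein gets an SScore = −log₁₀(FDR) of its best cluster; the
   density whose SScore ranking yields the highest ROC AUC against the
   disease-gene reference is selected.
5. **Pathway ranking.** Each significant cluster contributes its top-3
   enriched pathways (count ≥ 2, EASE ≤ 0.1, FDR ≤ 0.05); pathways linked
   to ≥ 3 clusters in the resulting bipartite graph are the final calls.

Because the original study's inputs came from live databases (HMDB, KEGG,
HIPPIE, DisGeNet, DAVID) with no deposited snapshot, the package includes a
synthetic-data generator (`synth_config()`, `synthesize_inputs()`) that
emulates all six inputs with planted modules, disease genes at a
configurable odds ratio, and aligned pathway sets — so the entire pipeline
is testable end to end with known ground truth.

## Worked example

```r
library(ppiclust)

report <- run_pipeline(pipeline_config(synth = demo_config(seed = 1)))
report
#> <pipeline_report>
#>   biomarkers: 10; seeds: 168 SCZ / 144 BD / 72 common / 240 total
#>   network: 240 nodes, 4213 edges
#>   chosen density: 0.9 (AUC 0.7924); significant clusters: 11
#>   selected pathways (degree >= 3): 2

report$pathway_ranking
#> # A tibble: 2 × 3
#>   pathway degree selected
#>   <chr>    <int>    <int>
#> 1 PW01         8        1
#> 2 PW02         3        1
```

The demo plants five dense 40-protein modules (ring-overlapping by 10) on a
300-protein universe; the first two modules carry disease genes at odds
ratio 10 and have aligned pathway sets (`PW01`, `PW02`). The run above
recovers both: the AUC sweep selects density 0.9 (the sweep value nearest
the planted within-module density of 0.86), eleven overlapping dense-core
clusters are significant at FDR < 0.05, and exactly the two planted
pathways reach bipartite degree ≥ 3. `plot_auc_by_density(report)`,
`autoplot(report$network)` and `autoplot(report$bipartite)` draw the
corresponding figures, and `tidy()`/`glance()` methods expose every result
as a tibble.

File-based runs use the same machinery with
`pipeline_config(paths = list(...))`; a thin command-line front end is
installed as `exec/ppiclust` (subcommands `synth`, `map`, `network`, `run`,
each taking a flat key=value `--config` file and an `--outdir`).

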