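# mixlineage

Detection and characterization of **mixed-lineage tumor cells** in non-small
cell lung cancer (NSCLC) from single-cell RNA-seq, for computational
biologists analyzing tumor single-cell atlases or validating lineage-
plasticity claims on their own cohorts.

Histology assigns a lung tumor one label — adenocarcinoma (ADC), squamous
cell carcinoma (SCC), or a neuroendocrine tumor (NET) — but individual cancer
cells can co-express classical marker genes of two or even three of these
lineages. `mixlineage` implements the full analysis chain around that
observation:

* **Lineage attribution.** Per cell and lineage, the attribution score is the
  maximum over the lineage's marker panel of log2(TPM+1) expression, after
  flooring markers below 5 to zero. Cells are clustered on their (A, S, N)
  score vectors into five groups labelled `ADC`, `SCC_ADChigh`,
  `SCChigh_ADC`, `NET_ADC`, `triple_positive` by their mean score pattern.
* **Signatures and ternary scores.** Top-50 archetype cells per lineage (by
  classical trio expression) seed a one-vs-rest Wilcoxon DE run; the top-50
  DEGs per lineage score all tumor cells, scaled to [0, 100], for ternary
  composition analysis.
* **Clonality evidence.** Expression-derived relative CNV (100-gene moving
  average along the genome, centered on normal epithelial cells, 10-Mb
  windows, with a bulk-WGS window-depth cross-check) and tumor-specific
  mitochondrial variants from a cell × variant allele-frequency matrix.
* **Survival.** The bulk lineage-mixing score
  `score = c (1 − max(A, S, N)) / max(A, S, N)` on a normalized lineage
  composition, cohort splits at score 1 (ADC) and 1.33 (SCC), and an
  in-package Kaplan–Meier / log-rank comparison.
* **Synthetic data.** A generator planting known lineage mixtures, CNV
  segments, mitochondrial clones and survival effects, used by the test
  suite to verify that every method recovers what was planted.

## Worked example

```r
library(mixlineage)

cfg <- simulation_config(n_patients = 2, cells_per_patient = 150, seed = 1)
sim <- simulate_single_cell_dataset(cfg)
m   <- log_transform(tpm_normalize(sim$expression))

lab <- cluster_cells(m, n_clusters = 30, seed = 1)
ty  <- assign_major_types(m, lab)
ann <- sim$cells
ann$major_type <- unname(ty$major_type[ann$cell_id])
ann <- cell_annotation(ann)

epi <- ann$cell_id[ann$major_type == "epithelial"]
fit <- classify_lineages(m[match(epi, cell_ids(m)), seq_len(ncol(m))],
                         cell_annotation(ann[ann$cell_id %in% epi, ]))
print(fit)
#> lineage_classification
#>   193 tumor epithelial cells subtyped (full panel)
#>     SCC_ADChigh      53
#>     NET_ADC          47
#>     ADC              40
#>     triple_positive  33
#>     SCC              20
#>   mixed-lineage cells: 133 / 193 (68.9%)

fit$mixed_fraction
#>   patient_id n_tumor_cells n_mixed mixed_fraction
#> 1        P01            97      64      0.6597938
#> 2        P02            96      69      0.7187500
```

The simulation planted a mixed-lineage fraction of 0.7; the pipeline
recovers 68.9% overall (0.66 and 0.72 for the two patients) — the kind of
agreement the test suite requires (±5 points at ≥ 1000 cells).

The mixing score and survival stratification on a simulated bulk cohort:

```r
mixing_score(c(A = 0.5, S = 0.3, N = 0.2))
#> [1] 1

coh <- simulate_bulk_cohort(cfg)           # hazard increases with mixing
grp <- split_cohort(coh)                   # ADC at 1, SCC at 1.33
lr  <- logrank_test(grp, coh$time, coh$event)
#> log-rank chi-square 20.53, p = 5.87e-06
```

A composition whose dominant lineage holds half the signal scores exactly 1
(the ADC split point), and the high-mixing group shows clearly worse
survival, as planted.

See `vignettes/mixed-lineage-methods.Rmd` for the model, parameter
rationale, and the generator's scope and limitations.

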