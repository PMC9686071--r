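# m6avar

Analysis toolkit for linking **m6A RNA methylation** to **gene expression
variability** in bulk RNA-seq / MeRIP-seq experiments, modelled on the
*Arabidopsis* setting where floral tissue shows strong m6A enrichment,
methylated transcripts show reduced expression variability, and
heat-responsive genes are consequently induced less strongly in flowers —
further so when an m6A demethylase is knocked out.

## Who it is for

Computational biologists analysing MeRIP/RIP-seq alongside matched input
RNA-seq who need, in one place:

* per-gene **m6A enrichment**: `E = log2((mean IP + c) / (mean input + c))`,
  with a methylation call at `E > 0`;
* per-gene **expression variability**: the squared coefficient of variation
  `CV² = (sd/mean)²` over biological replicates, with HVG/LVG
  classification on `log2 CV²` thresholds;
* peak-level operations: replicate-reproducibility filtering, midpoint
  peak-to-gene assignment, metagene density on a composite
  5'UTR/CDS/3'UTR axis, RRACH (R=A/G, H=A/C/U) motif scanning and a
  position frequency matrix from the top enriched regions;
* the association layer: methylated fraction across variability quartiles,
  one-tailed Wilcoxon rank-sum tests, hypergeometric set overlap,
  score comparisons against seeded size-matched random gene sets, and the
  heat-response fold-change matrix;
* a **seeded synthetic-data generator** that plants all of these effects
  with known ground truth, plus an end-to-end `run_pipeline()` driven by a
  YAML configuration with a checksummed manifest and JSON run report.

The methods vignette (`vignettes/m6a-variability-methods.Rmd`) documents the
model, every tunable parameter, and the design decisions.

## Worked example

Simulate a small dataset with all effects planted, then ask whether
methylated transcripts are concentrated among the least variable genes and
whether heat induction is attenuated in flowers:

```r
library(m6avar)

cfg <- sim_config(seed = 1, n_genes = 300, heat_genes = 40,
                  n_mutant_shifted = 30)
gen <- generate_genome(cfg)
ge  <- generate_expression(cfg, gen$models)
pk  <- generate_peaks(cfg, gen$models, ge$truth, gen$genome)

enr <- enrichment_table(ge$expr)
thr <- variability_thresholds(hvg_min = -2, lvg_max = -6)  # fixture scale
vt  <- variability_table(ge$expr, thr)
vrec <- vt[vt$group == "flower.CS.wt", ]

fraction_methylated_by_quartile(
  variability_quartiles(vrec),
  call_methylated(enr, group = "flower.CS.wt"))
#>   quartile n_genes n_methylated  fraction
#> 1       Q1      75           72 0.9600000
#> 2       Q2      75           68 0.9066667
#> 3       Q3      75           59 0.7866667
#> 4       Q4      75           39 0.5200000
```

Q1 holds the least variable quarter of genes: 96% of them are methylated,
falling monotonically to 52% in the most variable quarter — the planted
negative methylation–variability association, recovered from the data.

```r
rp <- reproducible_peaks(pk$peaks[["flower.CS.wt_rep1"]],
                         pk$peaks[["flower.CS.wt_rep2"]])
metagene_density(rp, gen$models)
#> <metagene_profile> 100 bins, 160 peaks; argmax at 0.735

heat_response_matrix(ge$expr)
#> <heat_response_matrix> 45 heat-activated genes (wt-leaf FC >= 2)
#>       wt.leaf     wt.flower   mutant.leaf mutant.flower
#>         2.894         1.351         2.611         0.696
```

The metagene density peaks at composite position 0.735, just 5' of the
CDS/3'UTR junction at 0.75 — the stop-codon-proximal placement typical of
m6A. The heat-activated genes (selected by at least two-fold induction in
wild-type leaves) show mean log2 fold changes ordered
wild-type leaf > wild-type flower > mutant flower: heat response is
attenuated in flowers and further in mutant flowers.

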