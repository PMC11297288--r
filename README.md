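# cpbench

A desk-scale benchmark framework for **batch-effect correction of
well-level image-based morphological profiles** (Cell Painting style
data). It is aimed at method developers and profiling groups who want to
ask, under controlled conditions: *how much confounding batch variation
does a correction method remove, and how much biological signal does it
keep?*

Image-based profiling data are hierarchical — source laboratory →
experimental batch → plate → well — and each level injects technical
variation that can swamp the morphological signal of the chemical
perturbations being studied. cpbench provides the full loop needed to
score correction methods:

- a validated `profile_table` container (wells × features plus
  source/batch/plate/well/compound/control metadata), with CSV and
  Parquet readers/writers and single-cell → well aggregation;
- the standard four-step preprocessing pipeline ("baseline"):
  low-variation feature removal by robust coefficient of variation
  (C_var = |σ̃/X̃| from plate-wise DMSO controls, threshold 1e-3),
  plate-wise MAD normalization X̂ = (X − X̃)/σ̃ on negative controls,
  rank-based inverse normal transform Y = Φ⁻¹((r − c)/(N − 2c + 1)) with
  Blom offset c = 3/8, and |r| > 0.9 correlation-threshold feature
  selection;
- correction methods behind one fit/apply contract: sphering (ZCA
  whitening on negative controls), ComBat (via sva), mutual
  nearest-neighbour correction, a Harmony-style iterative cluster
  correction, and a plugin registry for external methods;
- ten integration metrics, each normalized to [0, 1]: four batch-removal
  (batch silhouette, graph connectivity, iLISI, kBET) and six
  bio-conservation (label silhouette, cLISI, Leiden ARI/NMI, and
  replicate-retrieval mean average precision with non-replicate or
  DMSO-control negatives), aggregated as
  overall = 0.4 · mean(batch) + 0.6 · mean(bio);
- a hierarchical synthetic-profile generator with exact ground truth and
  an oracle correction, plus five scenario presets of increasing
  technical heterogeneity (one lab → five labs with three microscope
  types);
- scenario orchestration producing tidy metric tables, a summary report,
  a reproducibility manifest, and UMAP diagnostic panels.

## Worked example

```r
library(cpbench)

cfg <- scenario_config("s2",        # three-laboratory simulated preset
  methods = list(baseline = list(), combat = list(), harmony = list(),
                 oracle = list()),
  seed = 7, name = "demo")
report <- run_benchmark(cfg)
print(report)
```

```
benchmark_report 'demo'
   method batch_score bio_score overall_score rank
  harmony       0.948     0.956         0.953    1
   oracle       0.976     0.928         0.947    2
   combat       0.967     0.919         0.938    3
 baseline       0.847     0.909         0.884    4
```

Reading the table: the preset injects per-batch response gains that
plate-wise control normalization cannot remove, so the uncorrected
baseline mixes batches worst (batch score 0.847). The ground-truth oracle
bounds batch removal (0.976). ComBat recovers most of it but cannot touch
the compound-by-batch interaction; the Harmony-style method corrects
cluster-wise and additionally benefits on bio-metrics from scoring in its
denoised 20-dimensional embedding — which is why its overall score can
exceed the oracle's. `write_benchmark(report, "results/demo")` writes the
tidy `metrics.csv`, a `report.md` summary and a `manifest.json`;
`rank_methods()` averages method ranks across scenario reports;
`plot_embedding()` draws per-batch / per-compound UMAP panels.

A thin command-line wrapper over the same functions is installed at
`inst/cli/cpbench.R`
(`Rscript cpbench.R simulate|preprocess|correct|evaluate|run ...`).

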