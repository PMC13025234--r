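# nucmorph

Quantitative nuclear-architecture analysis for variant-driven remodeling
studies, with a fully synthetic, ground-truthed test bed.

Oncogene variants expressed in epithelial cell models (for example KRAS
G12D versus G12R in pancreatic ductal cells) remodel the nucleus within
hours: nuclear size and shape change, nucleoli (marked by nucleolin and
fibrillarin) enlarge or reorganize, and spliceosomal speckles (SC-35)
expand. `nucmorph` implements the full measurement chain used to quantify
these effects, together with seeded simulators that produce images and
omics tables with exact known truth, so every stage of the chain can be
validated end to end:

* **Synthetic data** — multi-channel 2D images and 3D stacks of nuclei with
  nested subnuclear compartments (fibrillarin inside nucleolin inside the
  nucleus; SC-35 speckles in the nucleoplasm), rendered with PSF blur and
  noise at 16 bits. Per-object size and shape ground truth is computed from
  the analytic generator geometry, not the raster. Also: differential
  expression tables and antibody phospho-array spot tables with injected,
  recoverable effects.
* **Morphometry** — threshold segmentation (Otsu or frozen baseline
  thresholds applied uniformly across cohorts) and per-object measurement in
  physical units: area, perimeter and circularity `4πA/P²` in 2D; volume,
  iso-surface area and sphericity `π^{1/3}(6V)^{2/3}/SA` in 3D.
* **Omics scoring** — the nuclear transcriptional remodeling score (NTRS):
  filter DE genes at FDR < 0.05 and |log2FC| ≥ 0.75, subset to nuclear GO
  cellular-component categories, and average positive and negative log2 fold
  changes separately; plus cross-variant sign concordance. The phospho-array
  chain: duplicate-spot summarization, global-median normalization,
  phospho/total ratio, ±doxycycline fold change, classification at
  |log2FC| ≥ 1.
* **Reporting** — per-cohort mean ± SD and t-based 95% CI, percent change
  versus the 0-h baseline, one-way ANOVA contrasts with Sidak correction
  `p_adj = 1 − (1 − p)^m`, and star coding.

## Worked example

Simulate a cohort of nuclei calibrated to circularity 0.84, segment and
measure them, and compare against the generator truth:

```r
library(nucmorph)

spec <- nuclear_phenotype_spec(1, mean_size = 120, target_shape = 0.84)
cohort <- simulate_cohort_2d(40, spec, seed = 7)
round(c(mean_measured = mean(cohort$circularity),
        mean_truth   = mean(cohort$truth_circularity)), 4)
#> mean_measured    mean_truth
#>        0.8394        0.8400
```

Score a simulated expression experiment with the printed six-gene example
of the attenuated variant:

```r
panel <- data.frame(
  gene_id = c("SOX9", "NOS1AP", "CCD86", "HDAC5", "ABTB1", "SATB1"),
  condition = "G12R",
  log2fc = c(0.85, 0.84, 0.30, 0.16, 0.03, -0.05),
  fdr = 0.01, go_category = "chromatin_remodeling")
compute_ntrs(panel)
#>   condition ntrs_pos n_pos ntrs_neg n_neg
#> 1      G12R    0.436     5    -0.05     1
```

`ntrs_pos = 0.436` is the mean of the five positive fold changes; the single
negative gene gives `ntrs_neg = -0.05`. Percent-change reporting follows the
printed convention (half away from zero):

```r
report_round(percent_change(1.72, 2.43))      # nucleolin area, 0 h -> 24 h
#> [1] 41
report_round(percent_change(823.0, 773.3), 1) # nuclear volume, 0 h -> 48 h
#> [1] -6
```

An end-to-end run (simulate → segment → measure → report, plus the omics
arm) is driven by a YAML configuration:

```r
cfg <- read_run_config(system.file("extdata", "demo-config.yaml",
                                   package = "nucmorph"))
run_imaging(cfg, outdir = "runs/demo")
run_omics(cfg, outdir = "runs/demo")
read.csv("runs/demo/report_2d.csv")
```

The demo's 24-h nucleolin row reports `pct_change_vs_0h = 40.9` against the
configured 1.72 → 2.43 µm² growth. Identical `(config, seed)` pairs
reproduce byte-identical outputs. A thin command-line wrapper with
subcommands `run-all`, `run-imaging`, `run-omics` is installed at
`inst/scripts/nucmorph.R`.

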