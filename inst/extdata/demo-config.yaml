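# Demo run: two variant cohorts at three induction time points, 2D imaging
# plus omics scoring. Nucleolin means follow the printed baseline/24-h areas
# of the strongly remodeling variant (1.72 -> 2.43 um^2).
seed: 1
outdir: runs/demo
imaging:
  mode: 2d
  geometry2d:
    shape: [640, 640]
    spacing_um: [0.1, 0.1]
  noise:
    background: 0.05
    psf_sigma: 0.08
    gaussian_sigma: 0.005
    photon_scale: 0
  segmentation:
    smoothing_sigma: 0.1
    threshold: otsu
    freeze_baseline: true
    min_size:
      nucleus: 20
      nucleolin: 0.3
      fibrillarin: 0.1
      sc35: 0.15
    exclude_border: true
  cohorts:
    - condition: G12D
      timepoint_h: 0
      n_cells: 12
      n_images: 3
      nucleus: {mean_size: 120, size_cv: 0.15, target_shape: 0.84}
      compartments:
        - {marker: nucleolin, count_mean: 3, size_mean: 1.72, size_sigma: 0.45}
        - {marker: fibrillarin, count_mean: 2, size_mean: 0.35, size_sigma: 0.35, nesting: nucleolin}
        - {marker: sc35, count_mean: 10, size_mean: 0.9, size_sigma: 0.45}
    - condition: G12D
      timepoint_h: 24
      n_cells: 12
      n_images: 3
      nucleus: {mean_size: 120, size_cv: 0.15, target_shape: 0.88}
      compartments:
        - {marker: nucleolin, count_mean: 3, size_mean: 2.43, size_sigma: 0.45}
        - {marker: fibrillarin, count_mean: 2, size_mean: 0.46, size_sigma: 0.35, nesting: nucleolin}
        - {marker: sc35, count_mean: 10, size_mean: 1.18, size_sigma: 0.45}
    - condition: G12R
      timepoint_h: 0
      n_cells: 12
      n_images: 3
      nucleus: {mean_size: 130, size_cv: 0.15, target_shape: 0.86}
      compartments:
        - {marker: nucleolin, count_mean: 3, size_mean: 1.88, size_sigma: 0.45}
        - {marker: fibrillarin, count_mean: 2, size_mean: 0.32, size_sigma: 0.35, nesting: nucleolin}
        - {marker: sc35, count_mean: 10, size_mean: 0.9, size_sigma: 0.45}
    - condition: G12R
      timepoint_h: 24
      n_cells: 12
      n_images: 3
      nucleus: {mean_size: 130, size_cv: 0.15, target_shape: 0.86}
      compartments:
        - {marker: nucleolin, count_mean: 3, size_mean: 2.19, size_sigma: 0.45}
        - {marker: fibrillarin, count_mean: 2, size_mean: 0.40, size_sigma: 0.35, nesting: nucleolin}
        - {marker: sc35, count_mean: 10, size_mean: 1.04, size_sigma: 0.45}
omics:
  conditions: [G12D, G12V, G12R, S17N]
  reference_condition: G12D
  de:
    n_genes: 3000
    null_sd: 0.3
    fdr_hit_prob: 0.95
    effects:
      G12D: {mean: 1.1, sd: 0.35, frac_affected: 0.6}
      G12V: {mean: 1.0, sd: 0.35, frac_affected: 0.55}
      G12R: {mean: 0.85, sd: 0.3, frac_affected: 0.25}
      S17N: {mean: 1.1, sd: 0.35, frac_affected: 0.6, invert: true}
  phospho:
    n_sites: 120
    n_proteins: 90
    n_replicates: 3
    effects:
      G12D: {frac: 0.08, lfc_mean: 1.5, lfc_sd: 0.3}
      G12R: {frac: 0.02, lfc_mean: 1.2, lfc_sd: 0.3}
  threshold: 1.0
report:
  format: csv
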