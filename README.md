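# ctcscreen

Surface-marker screening for **live circulating tumor cells (CTCs)**.

Circulating tumor cells are rare cells shed from a tumor into the
bloodstream. Capturing them alive — no fixation, no permeabilization —
preserves RNA for single-cell sequencing, but requires staining with
cell-surface markers. The classic cocktail (EpCAM, HER2, EGFR) is epithelial
in character and misses mesenchymal CTCs, the dominant population in
triple-negative breast cancer. `ctcscreen` is an analysis pipeline for
discovering new surface markers from single-CTC RNA-seq and for quantifying
how well marker cocktails perform in validation experiments. It is aimed at
researchers running marker-discovery screens on their own CTC single-cell
data.

## What it computes

Starting from a gene-by-cell count matrix of $k_{gj}$ (raw count of gene $g$
in cell $j$):

1. **Quality control** — cells with < 50% uniquely mapped reads or > 50%
   mitochondrial counts are removed (strict inequalities; exactly-50% cells
   pass); genes expressed in < 5 cells are dropped.
2. **Normalization** — median-of-ratios size factors
   $s_j = \mathrm{median}_g\, k_{gj} / (\prod_{j'} k_{gj'})^{1/n}$,
   rescaled to geometric mean 1, with a positive-counts mode for sparse
   matrices; normalized expression $x_{gj} = k_{gj}/s_j$ and
   $\log_2(x+1)$.
3. **The marker cascade** — an ordered filter chain over genes: drop
   unexpressed → subtract PBMC-expressed genes (single-cell count > 0) →
   subtract whole-blood-expressed genes (> 15) → keep mean normalized CTC
   expression ≥ 8 → keep detection in ≥ 30% of CTCs → keep protein-coding →
   keep plasma-membrane-localized → intersect with a manual curation list
   (plus a known-marker whitelist such as EGFR).
4. **Panel statistics** — per-marker detection fractions and, for a
   cocktail, the number of CTCs in which *no* member is detected.
5. **Validation quantification** — nuclear-mask segmentation of IF images,
   per-cell mean gray values, tag⁺/CD45⁻ (CTC) vs CD45⁺/tag⁻ (immune)
   classification with an excluded ambiguous class, percent-positive
   staining; and rectangular tag⁺/CD45⁻ gating of flow-style event tables.
6. **Synthetic data** — seeded generators for all of the above with exact
   ground truth (planted markers, per-stage decoys, planted QC failures,
   planted staining fractions), so the entire pipeline is testable offline.

## Worked example

```r
library(ctcscreen)

bundle <- simulate_full_study(sim_config(seed = 1))
screen <- run_full_screen(bundle$counts, bundle$align_stats,
                          bundle$blood_ref, bundle$annotation,
                          curation = bundle$curation,
                          whitelist = bundle$whitelist)
print(screen)
```

```
screen: 47 cells in, 43 kept (37 CTCs); 16506 genes after filter
median detected genes per CTC: 7052
candidate-marker cascade:
  expressed                 16506 ->  16506
  pbmc_subtraction          16506 ->   7377
  whole_blood_subtraction    7377 ->   4866
  expression_filter          4866 ->   1162
  coverage_filter            1162 ->   1161
  protein_coding             1161 ->    581
  plasma_membrane             581 ->      7
  curation                      7 ->      6
final candidates: 6 (1 known)
```

Reading: of 47 simulated cells, the 3 planted low-mapping cells and 1
high-mitochondrial cell were removed, leaving 37 CTCs and 6 controls. The
cascade narrows 16,506 expressed genes to 7 plasma-membrane candidates (the
6 planted true markers plus the planted curation decoy), and the curation
stage yields exactly the 6 planted markers — AHNAK2, CAVIN1, ODR4, TRIML2,
S100A16 and the known marker EGFR. Panel statistics on the same bundle:

```r
print(screen$panels$published)
```

```
panel coverage over 37 cells:
  EPCAM      8 of 37 (21.6%)
  HER2       17 of 37 (45.9%)
  EGFR       33 of 37 (89.2%)
cells missed by the panel: 3 of 37
```

Three of 37 CTCs express none of the published markers — the coverage gap
the new markers close (`screen$panels$total` misses 0 of 37).

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the whole study on
a seeded synthetic bundle and write tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R      # bundle -> results/sim_study/
Rscript analysis/02_qc_normalization.R    # QC table, size factors
Rscript analysis/03_marker_cascade.R      # cascade counts, candidates
Rscript analysis/04_panel_detection.R     # cocktail coverage
Rscript analysis/05_validation_quant.R    # IF + flow quantification
```

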