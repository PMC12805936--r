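---
title: "Screening for live-CTC surface markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for live-CTC surface markers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcscreen)
```

## The problem

Circulating tumor cells (CTCs) are rare tumor cells shed into the
bloodstream. Capturing them *live* — without fixation or permeabilization —
preserves RNA quality for single-cell sequencing, but requires staining with
cell-surface markers. The classic markers (EpCAM, HER2, EGFR) are epithelial
in character and miss mesenchymal CTCs, which dominate in triple-negative
breast cancer. `ctcscreen` implements a transcriptome-driven screen for new
surface markers: starting from a gene-by-cell count matrix of single CTCs, it
subtracts everything the blood background expresses, keeps genes that are
highly and broadly expressed by the CTCs themselves, and restricts to
protein-coding genes localized to the plasma membrane. The package also
implements the quantification rules used to validate marker cocktails in
immunofluorescence (IF) images and flow-cytometry-style event tables, and a
synthetic-data module that generates all of these inputs with exact ground
truth.

## Quality control

Two per-cell filters precede everything else, both with *strict* inequality
semantics:

* cells with **less than** 50% uniquely mapped reads are removed
  (`unique_map_pct < 50`), and
* cells with **more than** 50% of counts on mitochondrial genes are removed
  (`mito_pct > 50`).

A cell sitting exactly at 50/50 passes both filters; the boundary belongs to
the kept side because the filters are phrased as "less than" / "more than".
Mitochondrial genes default to symbols starting `MT-` (the human convention)
and can be overridden with an explicit list. Cells with zero total counts are
a degenerate case the filters above do not address; they are removed with a
dedicated `zero_total_counts` reason. The per-cell feature floor (1,000
detected genes) is computed and reported but applied only as a flag by
default — in the study design it removes nothing, and `enforce_min_features =
TRUE` turns it into a hard filter. Genes expressed in fewer than 5 cells are
dropped (`filter_genes`), with "expressed in exactly 5" kept.

```{r qc-example}
sim <- simulate_ctc_counts(sim_config(n_genes = 1000, seed = 1))
qc <- compute_cell_qc(sim$counts, sim$align_stats)
flt <- filter_cells(qc)
length(flt$kept)          # 37 CTCs + 6 controls
flt$removed$cell_id
```

## Size-factor normalization

Sequencing depth is removed by median-of-ratios size factors. For gene $g$
with counts $k_{gj}$ in cell $j$, the reference is the geometric mean across
cells, and the factor of cell $j$ is

$$ s_j = \operatorname{median}_g \frac{k_{gj}}{(\prod_{j'} k_{gj'})^{1/n}}. $$

The textbook ("standard") estimator uses only genes positive in every cell.
Sparse single-cell matrices often have too few such genes, so the default
`positive` mode computes each gene's reference over the cells where it is
positive and takes each cell's median over that cell's positive genes. This
preserves the estimator's intent — a robust per-cell ratio to a pseudo-bulk
reference — while remaining defined on sparse data; the two modes agree
exactly on an all-positive matrix, which is asserted in the tests. The median
is taken on the ratio scale (arithmetic median of $k_{gj}/r_g$), and factors
are rescaled to geometric mean 1, fixing the estimator's arbitrary overall
scale (within 1e-10, asserted). Counts are divided by the factors to give the
normalized linear scale $x_{gj} = k_{gj}/s_j$; the log scale is
$\log_2(x_{gj}+1)$ with the pseudocount fixed at 1.

## The candidate-marker cascade

The screen is an ordered sequence of filters over genes, each recorded with
its input and surviving sets:

| stage | rule (defaults) | boundary |
|---|---|---|
| expressed | mean raw count over CTCs > 0 | any nonzero count keeps |
| PBMC subtraction | PBMC single-cell max count ≤ 0 | any count > 0 removes |
| whole-blood subtraction | whole-blood expression ≤ 15 (TPM-like) | exactly 15 kept |
| expression | mean normalized CTC expression ≥ 8 | exactly 8 kept |
| coverage | detected in ≥ 30% of CTCs | exactly 30% kept |
| biotype | `protein_coding` | missing annotation removes |
| location | locations contain `plasma_membrane` | membership, not exclusivity |
| curation | intersect with user-supplied keep list | whitelist appended as `known` |

Design choices where the procedure was genuinely open:

* **Scale of the expression threshold.** The value 8 is applied on the
  *linear* normalized scale. The log transform is used downstream for
  plotting, while the filter is stated on "normalized average expression", so
  the linear reading is the operative default; `scale = "log2"` in
  `mean_normalized_expression` gives the alternative for sensitivity
  analysis.
* **Cell subset.** Averaged expression and coverage are computed "across
  CTCs": the CTC subset only, not the cultured controls. The subset is an
  explicit argument throughout.
* **Threshold vs percentile.** A top-5% percentile mode is available as an
  alternative to the absolute ≥ 8 threshold. The two disagree in general;
  the threshold form is the default because it is the form the filter
  chain's survivor counts are stated in. In percentile mode all genes tying
  the cutoff value are retained, so the survivor count can exceed the
  nominal 5%.
* **Filter order.** Expression precedes coverage. Except for the percentile
  mode (whose cutoff depends on the input set), all six membership filters
  are pointwise, so the final set is invariant under any permutation of
  them — asserted on 100 random inputs in the tests; only the per-stage
  bookkeeping depends on order.
* **Missing records.** Genes absent from the blood reference *pass* the
  subtraction steps (absence of evidence of blood expression), while genes
  absent from the annotation *fail* the biotype/location steps (unknown is
  not evidence of a protein-coding surface gene). The asymmetry follows each
  filter's direction of risk: a blood-expressed false candidate is caught at
  the validation stage, whereas an unannotated gene cannot be stained at
  all. Both cases are surfaced (the location/biotype filters attach an
  `unannotated` attribute).
* **Join key.** Gene symbols join counts, annotation and references, exact
  and case-sensitive by default; `ignore_case = TRUE` on the lookup helpers
  handles mixed-case reference tables.
* **Curation.** The antibody-availability / surface-staining assessment is
  manual by nature and enters as a keep list. Established markers (EGFR by
  default) are appended by a whitelist and flagged `known = TRUE`.

With the study's versioned external references (human protein atlas
single-cell PBMC data, whole-blood expression, biotype tables), the chain
produces the survivor counts reported for the original screen; those counts
are reference-snapshot-dependent and are therefore not asserted by this
package's tests, which validate the cascade on synthetic data with exact
ground truth instead.

## Panel detection statistics

Detection of a gene in a cell means raw count ≥ 1 (configurable). Because
size factors never map a zero to a nonzero value, detection is invariant
under normalization, which is why it is defined on raw counts.
`panel_coverage` reports per-marker detection plus the number of cells in
which *no* panel member is detected — the cells a staining cocktail built
from that panel would miss entirely.

## Image and event quantification

The IF quantification mirrors a mask-plus-connected-components macro:

1. **Segmentation**: the nuclear channel is thresholded (fixed cutoff, or
   Otsu as a convenience), connected components are labeled (4-connectivity
   by default, 8 available) and components below `min_area` pixels are
   discarded. Touching nuclei are *not* split — the generator places
   non-overlapping cells, and watershed splitting is out of scope.
   A `dilation_radius` parameter can grow the nuclear mask to capture
   membrane signal around nuclei; it defaults to 0 because the source
   procedure applies none.
2. **Measurement**: per object, the mean gray value of every channel over
   the object's mask pixels.
3. **Classification**: per-channel positivity is `mean gray ≥ cutoff`, with
   cutoffs uniform across all images of a batch. The default rules are
   `ctc = tag+ ∧ cd45−` and `immune = cd45+ ∧ tag−`. Cells satisfying no
   rule or more than one (e.g. tag+/CD45+) are `ambiguous` and excluded
   from population denominators — "unambiguously immune" implies an
   excluded middle, not a forced assignment.
4. **Percent positive**: `100 × positive / population` within one class.

Flow-style event tables are gated rectangularly (`tag ≥ cutoff` and
`cd45 < cutoff`) and the marker-positive fraction is computed within the
gate; an empty gate yields an explicit `undefined` flag rather than a
silent `NaN`.

## The synthetic-data module

The generators encode the study conditions as defaults: a 41-cell CTC cohort
of which 3 fail the mapping bound and 1 the mitochondrial bound (leaving 37),
6 cultured control cells, and a 20,000-gene matrix. Background counts are
negative-binomial with log-normal gene means (`meanlog 0.2`, `sdlog 2.2`,
dispersion `size 0.25`), chosen so a cell detects a realistic several
thousand genes (median ≈ 7,000 of 20,000) at full-length single-cell
chemistry; zeros arise from low means, with no separate dropout process.
Per-cell depth factors are log-normal (`sdlog 0.25`), giving the size-factor
estimator real work to do.

Marker and decoy genes receive *exact* planted detected-cell sets among the
kept CTCs rather than Bernoulli draws, so the class contracts hold for every
seed: the published markers reproduce the study's detection pattern (EpCAM
8/37, HER2 17/37, EGFR 33/37, with exactly 3 CTCs negative for all three),
and the six true markers (AHNAK2, CAVIN1, ODR4, TRIML2, S100A16, EGFR) are
each detected in at least 45% of CTCs. Each decoy violates exactly one
cascade stage — PTPRC (CD45) is PBMC-expressed, HBB is whole-blood-high,
HER2 is dimly expressed (counts near 2 per detected cell keep its mean far
below 8), EPCAM is strongly expressed but in too few cells, one decoy is a
lincRNA, one lacks a membrane location, ATP23 clears every computable filter
and fails only manual curation, and one gene has no counts at all. Every
background gene is given at least one disqualifying reference property
(PBMC-positive 55%, blood-high 15%, non-coding 15%, non-membrane 15% — a
mix resembling how a real transcriptome falls to these filters), which makes
planted-marker recovery exact: precision = recall = 1 is a property of the
construction, and the tests assert the pipeline achieves it.

Image and event generators place well-separated intensity populations
(bright 0.8 vs dim 0.05, cutoffs at 0.4) with optional additive Gaussian
noise (the stated noise level for the noisy test suites is σ = 0.05,
attenuated further by averaging over each object's ~45 mask pixels), and
plant exact positive counts (`round(fraction × n)`), so recovered
percentages equal planted ones exactly at σ = 0.

What the generators deliberately do **not** emulate: gene–gene correlation,
batch effects, ambient RNA, doublets, amplification-length biases, touching
or overlapping cells, illumination gradients, autofluorescence, or spectral
overlap. Passing tests therefore demonstrate that the *rules are implemented
exactly as specified* and are recoverable under the stated noise — not that
the thresholds themselves are optimal for any particular real dataset.
Likewise, the generator's cell-to-cell variability in detected genes is
narrower than real CTC data, where library quality varies far more.

## Numerical choices

* All filter boundaries are closed on the kept side (strict-inequality
  removal), matching the screen's wording; this is asserted for every
  threshold in a dedicated boundary test suite.
* Percentile-mode ties at the cutoff are all retained (no arbitrary
  tie-break).
* Size factors are rescaled to geometric mean 1; the log2 pseudocount is 1.
* Unparseable numeric fields in reference tables raise errors rather than
  coercing to 0 — silent coercion would quietly move filter boundaries.
* Missing-gene lookups in the blood reference return (0, 0) by contract,
  never an error.

## Problem sizes used by the test suite

The acceptance-style tests run the full screen on a 20,000-gene, 47-cell
bundle (about 2 s), the cascade-property tests on 100 seeded 150-gene
bundles, the size-factor oracle on 50 random matrices up to 20 × 6, and the
image suites on 200–1,000 planted cells per image — sizes chosen so each
property is exercised at meaningful scale while the whole suite stays fast.

## Known limitations

* The cascade's reference content (PBMC counts, whole-blood expression,
  biotypes, locations) is user-supplied; the package does not download or
  version external atlases, and survivor counts depend on those snapshots.
* Segmentation is a plain threshold-plus-components procedure; confluent or
  overlapping cells will merge.
* The positive-counts size-factor mode is a documented deviation from the
  textbook estimator and equals it only when all genes are positive in all
  cells.
* Detection uses raw counts; with a detection threshold above 1 the choice
  of raw versus normalized counts would begin to matter.
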