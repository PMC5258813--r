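# colonycyto

Imaging cytometry of human pluripotent stem-cell (hPSC) colonies: a tested,
fully simulatable implementation of the whole-well image-analysis chain —
nuclear segmentation, per-cell fluorescence quantification, negative-control
gating into marker-expression profiles, concordance with flow cytometry,
and spatial backtracking of marker phenotypes within colonies.

## Who this is for

hPSC cultures are *quasi-undifferentiated*: mostly undifferentiated cells
(OCT-3/4+, SSEA3+, SSEA4+, TRA-1-60+) mixed with spontaneously
differentiated ones (SSEA1+), the latter typically at colony edges. Imaging
cytometry characterizes such cultures like flow cytometry does — one
intensity per marker per cell, gated into percent-positive profiles — but
non-destructively and with positions retained, so any point of the profile
can be backtracked to its cell in the colony. This package is for people
who want that analysis chain as plain, inspectable R, with a synthetic
colony-image generator providing per-cell ground truth so every stage can
be verified without proprietary instrument software or a deposited image
set.

## The core quantities

For cell *i* with segmented nucleus area *A<sub>i</sub>* the per-channel
statistic is the mean intensity over exactly that area. Gates come from a
negative control (stained without primary antibody): the threshold is the
empirical 99.5th percentile of the control cells' intensities, and

> % positive = 100 · #{ cells with intensity > threshold } / n

Two-marker quadrant classification (OCT-3/4 vs one surface marker) yields
`double_pos / x_single_pos / y_single_pos / double_neg` percentages summing
to 100. Imaging-vs-flow concordance is the Pearson r between the two
modalities' five-marker percent-positive profiles, one r per replicate,
summarized per line as mean ± SE. Spatial heterogeneity is scored by the
edge-enrichment statistic

> E = Pr(edge | phenotype) − Pr(edge)

over in-colony cells, with a label-permutation p-value.

## Worked example

Simulate one double-stained field (OCT-3/4-like marker on channel `x`,
SSEA1-like on channel `y`, 201B7-style mixture), segment, measure, gate
against a matched negative control, and test edge enrichment:

```r
library(colonycyto)

cfg <- sim_config(seed = 1)            # 660x660 px, 5 colonies, ~430 cells
sim <- generate_colony_field(cfg)
an  <- analyze_field(sim$field)        # segment + measure

ctl <- generate_colony_field(control_config(cfg))
ctl_cells <- analyze_field(ctl$field)$cells
gate_x <- fit_threshold(ctl_cells, "x")
gate_y <- fit_threshold(ctl_cells, "y")
#> <gate_spec> x > 147.80 (q = 0.995 from 455 control cells)
#> <gate_spec> y > 156.23 (q = 0.995 from 455 control cells)

qr <- classify_quadrants(an$cells, gate_x, gate_y)
qr
#> <quadrant_result> 431 cells
#>   double_pos        65   15.08%
#>   x_single_pos     307   71.23%
#>   y_single_pos      59   13.69%
#>   double_neg         0    0.00%
```

So 86.3% of cells are positive for the nuclear pluripotency marker and
28.8% for the differentiation marker — against ground-truth marginals of
86.3% and 28.7% for this field. The differentiated single-positive class
sits at colony peripheries:

```r
scored <- edge_scores(assign_colonies(qr$cells, field_shape = cfg$field_shape))
phenotype_edge_enrichment(scored, "y_single_pos", seed = 1)
#> <edge_enrichment> y_single_pos: E = 0.258 (edge 71.7% vs 45.9% overall),
#>   p = 0.0005 [416 cells, 1999 permutations]
```

`autoplot(qr)` draws the two-marker scatter with quadrant percentages,
`plot_expression_histogram()` the gated one-dimensional profile,
`plot_colony_overlay(scored)` the backtracked colony map, and
`backtrack()` returns per-cell image crops with nucleus outlines.
`run_pipeline(cfg, "out/")` runs all stages and writes TIFFs, CSVs and a
checksummed JSON manifest; `simulate_study()` runs the full four-line,
five-marker, three-replicate imaging-vs-flow comparison and
`concordance_summary()` reduces it to per-line mean ± SE Pearson r.

## Package layout

| | |
|---|---|
| `sim_config`, `generate_colony_field`, `simulate_flow_readings` | synthetic colonies + both instruments' measurement contracts |
| `segment_nuclei`, `stitch_tiles`, `match_centroids` | nuclear segmentation (watershed split of touching nuclei) |
| `measure_cells` | per-nucleus multichannel quantification |
| `fit_threshold`, `classify_quadrants`, `percent_positive`, `expression_histogram` | negative-control gating |
| `pearson_r`, `concordance_summary` | imaging-vs-flow concordance |
| `assign_colonies`, `edge_scores`, `phenotype_edge_enrichment`, `backtrack` | spatial analysis |
| `run_pipeline`, `simulate_study` | orchestration, artifacts, manifest |

The methods vignette (`vignettes/imaging-cytometry.Rmd`) documents the
models, parameter choices, numerical conventions and limitations.
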