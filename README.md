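# invadotrack

Automated detection, tracking and quantification of matrix-degrading
**invadopodia** in two-channel fluorescence time-lapse microscopy.

Invasive cancer cells assemble actin-rich protrusions — invadopodia — that
locally proteolyse the extracellular matrix (ECM).  In the fluorescent-
gelatin assay, cells carrying an F-actin reporter (e.g. LifeAct-GFP) sit on
a thin dye-labeled gelatin layer and are imaged in two co-registered
channels for many hours.  Candidate invadopodia are bright compact actin
*puncta* in the marker channel; functional invadopodia additionally carve
dark holes into the ECM channel beneath them.  `invadotrack` turns such
movie pairs into per-invadopodium and per-cell measurements:

* **preprocessing** — flat-field correction, translation registration,
  photobleach correction estimated only from pixels *outside* the cell
  bodies (so degradation is never mistaken for bleaching), and ECM
  normalization to an outside-cell mean of 1000;
* **puncta segmentation** — high-pass filter, then seed-based region
  growing: seeds are ≥ 6-px components above 3 standard deviations of the
  filtered frame, expanded at 1.75 standard deviations, filtered by area
  and major/minor axis ratio, and restricted to the cell mask;
* **tracking** — greedy largest-pixel-overlap linking between adjacent
  frames, with an inclusive lifetime filter (≥ 1 h, i.e. 12 frames at
  5 min);
* **degradation measurement** — per frame, the local difference
  `L_t = mean(ECM in a 5-px border ring) − mean(ECM under the puncta)`,
  the pre-birth difference `P_t` (same pixel sets on the ECM image just
  before the track appeared), and the corrected difference
  `C_t = L_t − P_t`;
* **classification** — two-sided one-sample t-tests on the means of `L`
  and `C`, Bonferroni-corrected over the batch, plus a positivity gate on
  both means (α = 0.05); called invadopodia get dynamic properties: mean
  area, distance to the cell edge, lifetime, and time to 90% of maximum
  smoothed degradation;
* **population mode** — whole-cell analysis of 20×-style fields: cell
  segmentation with a 1,500–20,000 px size window, ≥ 10 h tracks,
  background-corrected per-frame and overall degradation percentages
  (40-px border), degrader cutoffs calibrated on a negative control, the
  ≥ 2.5 h *area of influence*, the ≥ 20% per-pixel *degraded area* and the
  degradation rate (area / lifetime);
* **synthetic scenes** — a two-channel generator with full ground truth for
  both regimes, used throughout the test suite.

## Worked example

Analyse a synthetic single-invadopodia field (10 puncta, half degrading)
end to end:

```r
library(invadotrack)

sc  <- generate_scene(scene_params("single", image_shape = c(160L, 160L),
                                   n_frames = 36L, n_puncta = 10,
                                   cell_radius = c(55, 60),
                                   min_puncta_sep = 16, rng_seed = 7))
res <- run_single_mode(marker = sc$marker, ecm = sc$ecm)
res$calls
```

```
   track_id n_obs mean_L mean_C  p_adj_C is_invadopodia
 1        1    36  0.301  1.39  1.29e- 3 FALSE
 2        2    36 31.6   29.1   2.99e-10 TRUE
 3        3    36 -0.605  1.02  9.38e- 2 FALSE
 5        5    36 25.0   20.5   6.03e-10 TRUE
 6        6    36 30.7   29.9   5.75e-11 TRUE
 7        7    36 24.4   20.8   2.34e- 9 TRUE
 8        8    23 18.8   20.7   4.11e- 7 TRUE
 ...
```

Degrading puncta show corrected differences of ~20–30 fluorescence units
(on the 1000-unit normalized ECM scale) and tiny adjusted p-values; track 1
illustrates the positivity-and-significance gate: a 1.4-unit mean with a
significant p-value is still rejected because its `mean_L` evidence is not
jointly significant and positive at the corrected level.

```r
res$properties
```

```
  track_id mean_area_um2 mean_edge_distance_um lifetime_min time_to_max_min
1        2         0.355                  2.20          180             170
2        5         0.232                  1.48          180             175
3        6         0.193                  2.46          180             165
4        7         0.239                  1.40          180             170
5        8         0.359                  3.90          115              95
```

Areas are in µm² (0.1075 µm pixels), edge distances in µm, lifetime and
time-to-max in minutes.  Scoring against the generator's ground truth:

```r
score_against_truth(res$tracks, res$calls, sc$truth,
                    frame_dim(sc$marker), min_truth_frames = 12L)
# recall 1.00, sensitivity 1.00, false positives 0
```

Population mode works the same way: run a negative-control field through
`run_population_mode()`, derive cutoffs with
`calibrate_degrader_cutoffs(control$per_cell, fp_budget = 0)`, and pass
them via `default_config("population", cutoffs = ...)` when analysing the
treated fields.  A thin command-line wrapper with `single`, `population`,
`calibrate` and `synth` subcommands is installed at
`inst/scripts/invadotrack.R`.

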