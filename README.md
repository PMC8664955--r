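# mirtarprobe

Deep learning classifiers for miRNA target prediction — hybrid stacks of
convolutional and recurrent layers over the one-hot-encoded miRNA:target
pair — predict well but explain nothing by themselves. `mirtarprobe` asks
what such a model has learned, using perturbation rather than gradients:

* **In silico mutagenesis** — occlude a region (to `N`, `G`, or zero rows)
  or slide a k-nucleotide mutation window along the miRNA (`L` track,
  5'→3') and target (`LT` track, 3'→5') and record the change in the
  model's prediction probability at each window's stop position, with
  Mann–Whitney U significance and Bonferroni correction.
* **Accumulative per-nucleotide impacts** — isolate the contribution of a
  single position inside a mutated neighbourhood by differencing scans of
  adjacent widths: the impact of p with k−1 left neighbours mutated is
  `delta_k(p) − delta_{k−1}(p−1)`, with the right-hand analogue
  `delta_k(p+k−1) − delta_{k−1}(p+k−1)`; the per-position average over
  widths 1..K gives an impact profile, from which high-impact feature
  regions are selected greedily.
* **Duplex energetics** — a transparent affine-gap aligner (G:C 3, A:U 2,
  G:U wobble 1, mismatch −1, gaps −4/−1; energy = −score) yields binding
  energies and region base-pairing percentages (wobble counts as pairing).
* **Activation–energy correlation** — Spearman correlation of every unit,
  every summed feature map, and the whole-layer sum of any registered
  layer (`embedding, cnn, pool, birnn, dense1, dense2`) against binding
  energy, with dead-unit exclusion and Bonferroni adjustment.

Because real benchmark datasets and trained weights are not redistributable
by accession, the package is self-contained: a synthetic generator plants
complementarity with known ground truth (seed L2–L7, 3'-supplementary
L13–L16, configurable probabilities), and a compact trainable surrogate
network (embedding → conv → max-pool → BiGRU → dense, written in
RcppArmadillo with explicit backprop) stands in for the published models.
Every interpretation stage is therefore testable against planted truth and
analytic oracles.

## Worked example

```r
library(mirtarprobe)

profile <- dataset_profile("deepmirtar")          # 26 + 53 nt geometry
ds <- generate_dataset(n_pos = 500, n_neg = 500, planted_rule(), profile,
                       seed = 42)
model <- train_surrogate(ds$pairs, profile, model_config(train_seed = 42))
model
#> <mitar_surrogate: profile 'deepmirtar', 16 filters, GRU 16/dir, held-out accuracy 0.935>

positives <- subset(ds$pairs, label == "positive")[1:200, ]

# Does the seed region drive the prediction?
region_effect(model, positives, region_positions("L", 2, 6),
              replacement = "N", family_size = 2, profile = profile)
#> <region_effect L2-6 (N): ref 0.980+/-0.009 -> mut 0.718+/-0.026, U=36713.0, p_bonf=4.61e-47 (family 2)>

# Which positions matter? k = 1..6 scans -> averaged impacts -> regions
scans  <- multi_scan(model, positives[1:100, ], ks = 1:6, profile = profile)
impact <- build_impact_profile(scans, mode = "mean")
find_feature_regions(impact, window_len = 4, n_regions = 2)
#>   label track start len     score summit
#> 1 LT8-4    LT     8   4 0.1149855   LT11
#> 2  L3-4     L     3   4 0.1014033     L5

# Do internal units track duplex stability?
energies <- binding_energies(positives)
correlate_with_energy(model, positives, "birnn", energies,
                      levels = c("raw_unit", "all_units"),
                      profile = profile)$raw_unit
#> <correlation_report birnn/raw_unit: 32 units (0 constant excluded), MinCor -0.173 (p_adj 0.461), MaxCor 0.203 (p_adj 0.123)>

# How much do the feature regions actually base-pair?
basepairing_table(positives, builtin_regions()[c("seed2-6", "L13-4")])
#>   subset   n  seed2-6  L13-4
#> 1    all 200 90.83333 80.375
```

Reading the output: occluding the seed drops the mean prediction
probability from 0.98 to 0.72 (Bonferroni-adjusted Mann–Whitney
p ≈ 5e-47); the two top impact windows sit on the planted seed — `L3-4` on
the miRNA face and `LT8-4` on its target-side mirror (the generator's fixed
register plants complementarity on both faces); and the aligner reads back
the planted pairing rates (seed ≈ 91%, supplementary ≈ 80% at its planted
0.8/0.85-level probabilities).

The full pipeline — simulate → train → scan → impact → duplex → correlate
→ joint, with TSV outputs, figures, and a JSON run manifest — runs from one
config:

```r
run_pipeline(pipeline_config(seed = 7), "out/")
render_report("out/")
```

or from a shell via `inst/scripts/run-pipeline.R` with a YAML config
(`inst/extdata/config.yaml` is a template).

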