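---
title: "Interpreting miRNA-target classifiers by in silico mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting miRNA-target classifiers by in silico mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Hybrid convolutional/recurrent classifiers predict, from a miRNA sequence
and a candidate target-site sequence, the probability that the site is a
true target. They perform well, but what they have *learned* — which
nucleotide positions carry the decision, whether the biophysics of duplex
formation is reflected in their internal activations — is not visible from
the predictions alone. `mirtarprobe` implements an occlusion-style
interpretation pipeline for such models: perturb the input in controlled
ways, watch the output probability move, and correlate internal unit
activations with an independent biophysical quantity (duplex binding
energy).

Every stage runs against a synthetic benchmark with *known* ground truth,
so the pipeline's recovery claims are checkable, not anecdotal.

## Coordinates and encoding

A pair is one miRNA written 5'→3' and one target site written 3'→5', so
equal offsets face each other in the duplex. Positions are 1-based on two
tracks: `L<i>` on the miRNA, `LT<j>` on the target. The model input is the
one-hot encoding of the concatenated pair, miRNA rows first
(`position_to_row()` hides the concatenation). Two built-in geometries are
provided: `deepmirtar`-like (miRNA padded to 26 nt, variable-length target
padded to 53 nt) and `miraw`-like (26 + 40, a 30-nt site extended 5 nt per
side). `T` and `U` are distinct letters in IO but one pairing class
everywhere; `N` is a letter with its own one-hot column, distinct from the
all-zero padding row, because mutation-to-N and edge zero-padding are
different operations. Padding is appended after the written sequence on
each track so that the L/LT indices of real nucleotides are stable across
pairs.

## The synthetic generator

`generate_dataset()` plants complementarity with known structure. A
positive target is built letter-by-letter opposite its miRNA
(`L,i ↔ LT,i+flank`): inside planted regions the letter complements with
the region's `complement_prob` (drawing the G:U wobble partner with
probability `wobble_prob` when it exists), elsewhere with
`background_match_prob`; a non-complementing position draws a letter that
pairs with nothing at that register, so the per-pair ground truth — the set
of complemented L positions — is exact. Negatives permute the miRNA's seed
6-mer until it matches no seed in use and carry background complementarity
only.

Defaults (the study conditions): seed L2–L7 at complement probability
0.95, a 3'-supplementary region L13–L16 at 0.85, background 0.25, wobble
0.1, miRNA lengths 19–26 nt, a 30-nt site with 5-nt flanks. These mirror
the canonical description of real positive pairs: near-obligate seed
pairing, strong-but-imperfect supplementary pairing, and appreciable chance
complementarity elsewhere.

What the generator deliberately does **not** emulate: real sequence
composition (letters are uniform), the variable binding register of real
sites (the register is fixed at the flank offset), 3'UTR context, and
experimentally validated negatives. Two consequences matter for reading
results. First, with a fixed register the planted structure exists
symmetrically on both faces of the duplex — L2–L7 on the miRNA track *and*
its mirror LT7–LT12 on the target track — so attribution methods may
surface either face; recovery checks accept both. Second, passing tests
show the pipeline recovers *planted* structure; they do not show that any
particular real model's features are correct.

## The surrogate model

The interrogated object is a compact trainable network with the
conventional layer stack — embedding, 1-D convolution (ReLU, valid
padding), max pooling, bidirectional GRU, two dense layers ending in a
sigmoid — exposed through a named-layer registry
(`embedding, cnn, pool, birnn, dense1, dense2`). The interpretation stages
depend only on `predict_proba()` and `layer_outputs()`, so any model
honouring that surface can be probed; analytic toy models (`fn_model()`)
plug into the same seam for oracle tests.

Design choices that came out of desk-scale experiments, and their
rationale:

* **Junction-spanning kernel (default 40 nt).** The discriminative signal
  is a *relation* between tracks: letter at `L,i` versus letter at
  `LT,i+flank`, 31 rows apart in the concatenated encoding. A short kernel
  confines every filter to one track and forces the recurrent layer to
  carry letter identity over ~15–30 pooled timesteps; across a wide grid of
  training regimes (weight decay, occlusion augmentation, self-supervised
  letter reconstruction, memory-friendly gate initialisation, short kernels,
  wide pooling) every such variant memorised 2,000 training pairs instead
  of generalising. A kernel long enough to span the junction lets a single
  ReLU filter express a match conjunction (`relu(x_a + x_b - threshold)`),
  which gradient descent finds readily: held-out accuracy ~0.95 in 60
  epochs.
* **Mean-pooled recurrent readout.** The dense head reads the BiGRU output
  averaged over timesteps. A flattened per-timestep readout (~17k
  parameters) interpolated the training labels without learning the
  comparison.
* **Training regime.** Adam on binary cross-entropy, batch 32, learning
  rate 2e-3, decoupled weight decay 1e-3, gradient-norm clipping at 5;
  80/20 train/held-out split and all initialisation, shuffling and dropout
  driven by `train_seed`. Occlusion augmentation (`input_mask_prob`, default
  0.15) masks random non-pad rows to `N` during training — it blocks
  verbatim memorisation and matches the occlusion regime under which the
  model is later interrogated. An optional masked-letter reconstruction
  head (`mlm_weight`, default 0) is available for experiments with dense
  self-supervision.
* **Interpretation passes are deterministic.** Dropout and masking act only
  during training; `predict_proba()` is a pure function of (model, input)
  and `layer_outputs()` captures activations on the identical forward pass.
* **BiRNN units.** The per-unit summary exposed for correlation analyses is
  the final hidden state of each direction (one value per hidden unit per
  pair), matching the per-unit (not per-timestep) unit counts conventional
  in such reports.

## The mutagenesis engine

`apply_mutation()` replaces listed positions with the `N` one-hot, the `G`
one-hot, or the all-zero row. Padding rows are left untouched: mutating a
position beyond a pair's true length is a no-op, so scans over the padded
tail contribute zero change for that pair.

`region_effect()` compares the reference and mutated probability samples
with a two-sided, *unpaired* Mann–Whitney U test, Bonferroni-corrected over
an explicit `family_size` recorded in every result (the family is a
reporting choice, so it is logged rather than guessed). The U statistic is
exact — by a subset-sum dynamic programme over average ranks, which handles
ties exactly — whenever `n1*n2 <= 400`, and tie-corrected normal beyond.

`sliding_scan()` mutates, for each stop position on each track, the k
positions ending at that stop; the mean probability change is recorded *at
the stop*. Windows never cross the miRNA/target junction (the two tracks
are different molecules), and window slots before a track's start are
realised as zero padding — only the existing positions are occluded.
`multi_scan()` runs several widths against one set of reference
probabilities.

## Accumulative per-nucleotide impacts

Single-width scans confound a position with its mutated neighbours. The
accumulative analysis isolates position p at width k by differencing
adjacent widths: the left-context impact is
`delta_k(p) - delta_{k-1}(p-1)` (p with k−1 mutated left neighbours), the
right-context impact `delta_k(p+k-1) - delta_{k-1}(p+k-1)`. Both are
undefined (marked `NA`, never an error) where a window leaves the track.

Combining the two sides is the one place where the method's published
description is internally inconsistent: the printed combination is
`(l - r)/2`, while the surrounding account calls for an average. On any
model whose response is additive in the mutated positions the printed
formula cancels identically to zero — the package proves this against an
analytic model in its test suite — so the default is `mode = "mean"`
(`(l + r)/2`), which recovers the additive model's per-position weights
exactly; `mode = "paper"` preserves the printed formula verbatim for
fidelity runs. `build_impact_profile()` averages the width-1 delta with all
defined contextual impacts, recording per-position component counts so
edge positions are auditable.

`find_feature_regions()` selects feature regions greedily: the contiguous
single-track window of given length with the largest summed `|e_avg|`,
then the best window not overlapping a previous choice; ties prefer the
smaller start and the L track. Defaults (window 4, top 2) match the
convention of reporting two 4-nt features per dataset; the 5-nt target-side
feature of the second geometry is reachable via the per-call window length.

## Duplex energetics

Binding energies come from a transparent affine-gap alignment
(`align_duplex()`): global over the miRNA, free end-gaps on the target
flanks (the site window is wider than the binding register), G:C = 3,
A:U = 2, G:U wobble = 1, mismatch −1, gap open −4, gap extend −1, and
`free_energy = -score`. This is a linear score-to-energy map, not
nearest-neighbour thermodynamics: downstream analyses use the energy
ordinally (Spearman) and as a pairing detector, so rank fidelity is what
matters. The dynamic programme is verified against exhaustive enumeration
on short sequences.

`region_basepairing()` counts a region position as paired if it appears in
the optimal alignment, wobble included. `basepairing_table()` reports mean
region percentages for all pairs and for "extracted" subsets — pairs whose
absolute probability change for a named region exceeds the mean absolute
change, the standard extraction convention. One estimation property is
worth knowing: for weakly bound pairs the *optimal* alignment may sit off
the planted register (chance pairings elsewhere can outscore a sparse
planted site), so construction rates are reproduced exactly only when the
duplex is strongly bound; at realistic backgrounds the seed column lands a
few points below 100%, just as alignment-based tables on real data do.

## Activation–energy correlation

`correlate_with_energy()` computes the Spearman correlation of every
aggregated unit with per-pair binding energy at three levels: `raw_unit`
(every unit), `per_feature_map` (convolutional unit outputs summed over
positions within a map), and `all_units` (one summed regressor — reported
as a single unit, whatever the layout of comparable published tables).
Constant (dead) units have no defined rank correlation; they are excluded
and counted rather than assigned zero. P-values use the t-approximation
and are Bonferroni-adjusted within level over the post-exclusion unit
count; method and family are recorded in the report header. The
within-level family is a choice (the alternative — adjusting across levels
jointly — is defensible too) and is therefore logged.

## Pipeline, determinism, and scale

`run_pipeline()` drives simulate → train → scan → impact → duplex →
correlate → joint from one config (R object or YAML), writes each stage's
outputs as TSV under one directory, and finishes with a JSON manifest
listing outputs, per-stage wall time, and first-class warnings (dead
units, empty extracted subsets, short feature lists). One global seed
drives every stage through a fixed splitting scheme, so identical
config+seed reproduces identical TSVs. `render_report()` draws the scan
profiles (stop positions ordered L1..Lmax then LT1..LTmax, with the
unmutated reference leftmost), impact bars, and effect bars from the TSVs.

Problem sizes in the shipped tests and acceptance script are chosen for a
single desk CPU: 2,000 pairs for training, 150–500 positives for scans and
effects, widths k = 1..6, 10 replicate seeds for the recovery check. The
mutagenesis stages scale linearly in pairs × stops × widths; the network
code is vectorised across the batch, so larger runs are a matter of
minutes, not code.

## Known limitations

* The surrogate is an interpretable stand-in sharing the layer family of
  the published hybrid models, not a reproduction of any trained weights;
  correlation magnitudes and probability reductions are therefore
  qualitative analogues, not comparable numbers.
* The energy model is ordinal; absolute kcal/mol values are not meaningful.
* The generator's fixed register makes target-side mirrors of planted
  regions genuinely informative; real data with variable registers would
  concentrate attribution on the miRNA track.
* `mode = "paper"` is retained for fidelity but documents, rather than
  resolves, the printed-formula sign issue.
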