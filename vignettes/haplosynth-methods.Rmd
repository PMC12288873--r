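---
title: "Generating synthetic haplotypes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating synthetic haplotypes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

haplosynth generates novel, privacy-preserving synthetic phased haplotypes
from a reference panel in four stages: recombination-hotspot segmentation,
per-section autoencoder compression, Wasserstein-GAN generation in the
concatenated latent space, and a validation suite. This vignette is the
package's own account of the underlying models, the parameters that
matter, the numerical choices we made where the design was open, and what
the bundled synthetic fixtures do and do not demonstrate.

## Why segment at recombination hotspots

A densely connected network over a whole chromosome is computationally
infeasible: parameters grow quadratically with the number of variant
sites. The pipeline instead cuts the variant list into sections and
compresses each section independently. The cut points are recombination
hotspots — narrow loci with elevated crossover rates (cM/Mb). Mutations
on the same side of a hotspot tend to be co-inherited and therefore
correlated (linkage disequilibrium, LD); mutations on opposite sides are
inherited nearly independently. Cutting at hotspots loses as little
correlation structure as possible, which is precisely the structure the
per-section autoencoders exploit for compression.

`filter_hotspots()` turns a cM/Mb interval map into single-base loci in
three steps: intervals at or below `rate_threshold` (default 5 cM/Mb) are
discarded as low signal; survivors are reduced to their centre
`floor((start + end) / 2)`; and, scanning in decreasing intensity order,
any locus within `proximity_radius` (default 5 kb, boundary inclusive) of
an already-retained stronger locus is dropped as diffuse signal around a
single event. Equal-intensity ties retain the smaller position — a
deterministic, order-independent rule.

`segment_by_hotspots()` then scans variants left to right. Crossing a
hotspot closes the current section if it holds at least `min_mutations`
variants (default 500); otherwise the short run is appended to the
previous section and the hotspot is counted as ignored. A section that
reaches `max_mutations` (default 5000) closes immediately at an
*artificial hotspot* placed midway between the last included and the next
variant. "Appending a short run to the previous section" is ambiguous
about whether accumulation restarts after the ignored hotspot or
continues across it; both readings are implemented
(`merge_mode = "backward"` — the default, literal reading — and
`"forward"`), and the package reports both counters so the sensitivity of
a segmentation to this choice can be checked directly. Two further
conventions the source never states: a hotspot exactly on a variant
position lies *after* that variant, and the final run closes as a
`chromosome_end` boundary (merging backward when below the minimum).

`segment_naive()` provides the equal-size binning baseline, and
`flag_split_bins()` marks bins with a hotspot strictly inside — the
stratification used to show why naive binning loses reconstruction
accuracy (`split_bin_accuracy_test()` applies the one-sided
Wilcoxon–Mann–Whitney comparison).

## Per-section autoencoders

Each section's binary haplotype-by-variant block is compressed by a dense
autoencoder:

* bottleneck size `ceiling(input_dim / 100)` — a fixed 100x compression
  target;
* three hidden layers on each side, geometrically interpolated between
  input and bottleneck size (the interior points of a five-point
  geometric progression, rounded, floored at 1), decoder mirroring the
  encoder;
* hidden activation one of relu, sigmoid, tanh, leaky_relu (slope 0.01
  by default);
* output activation ReLU capped at 1, so reconstructions live in
  `[0, 1]`;
* dropout between consecutive hidden layers: 20% for the classical AE,
  40% for the variational one;
* classical AE: bottleneck uses the hidden activation, loss is mean
  binary cross-entropy (BCE);
* VAE: linear mean and log-variance heads with reparameterised sampling;
  loss is BCE summed over sites plus the KL divergence to a standard
  normal, both averaged over the batch, with KL weight 1 and no
  annealing.

The loss balance deserves a note. With BCE *averaged* over sites, the KL
term (summed over latent dimensions) dwarfs the reconstruction signal and
the posterior collapses immediately; summing the reconstruction over
sites is the standard variational objective and the only balance under
which a unit KL weight is meaningful.

Training uses Adam (learning rate `1e-3`, configurable), a seeded random
80/20 haplotype-row split, and early stopping on validation loss with
patience 10 (30 for the slow-converging sigmoid and tanh), restoring the
best-performing weights. Validation loss for a VAE is computed with the
deterministic `z = mu` forward pass so that early stopping is
reproducible. The reported performance metric is validation
reconstruction accuracy: the fraction of entries equal to the input after
mean-decoding and binarising at 0.5 (a threshold the package fixes; see
`binarize()`).

### Numerical choices that matter

These were found the hard way and are deliberate:

* **Elementwise gradient clipping for BCE.** With a capped-linear output
  unit the raw BCE gradient factor `(a - x) / (a (1 - a))` is unbounded
  as `a` approaches 0 or 1. A single ~1e7 spike inflates Adam's
  second-moment estimate enough to freeze the affected parameters for
  thousands of steps, and desk-scale models visibly stall. The gradient
  (not the reported loss) therefore clamps predictions to
  `[0.01, 0.99]`, bounding the factor near 100.
* **Output bias starts at 0.5.** With zero bias, roughly half of the
  capped-ReLU output units start outside their active region and receive
  no gradient, ever.
* **VAE log-variance bias starts at −5.** The posterior starts narrow
  (sd ≈ 0.08) so the decoder sees signal rather than unit-variance noise
  during its first epochs; the KL term then widens it. This mitigates —
  but does not eliminate, see Limitations — posterior collapse.
* **Batch size 32 by default.** Early-stopping patience is measured in
  epochs; smaller batches perform more optimizer steps per epoch and
  reach materially better reconstructions before patience fires.
* **Glorot-uniform initialisation, zero hidden biases** otherwise,
  matching common dense-network defaults.

`encode_sections()` trains one model per section (child seeds derived
from one master seed, so runs are reproducible and sections independent)
and concatenates the per-section codes into a `latent_matrix` whose
column ranges are tracked per section; `decode_sections()` inverts the
mapping.

## The Wasserstein GAN

The generator maps `noise_dim = 1000` i.i.d. standard-normal variables
to the concatenated latent space (dimension T); its hidden layers are
T/10, T/5 and T/2 wide (ReLU), and its output layer uses the latent
space's own size and activation — linear when the codec is variational,
since the WGAN is trained on latent means. The critic's hidden layers
are T/10, T/50 and T/100 wide with a single linear output; widths use
floor division, floored at 1 with a warning (at desk scale, T ≈ 20
genuinely floors the deeper critic layers). A small positive bias (0.05)
on hidden ReLU units keeps those width-1 layers from starting dead.

Training follows the classic weight-clipped recipe: per epoch, five
critic updates — each on a fresh real batch and a fresh generated batch,
critic loss `mean(scores_fake) − mean(scores_real)`, all critic
parameters clipped to ±0.01 afterwards — then one generator update with
loss `−mean(scores_fake)`; RMSProp at learning rate 5e-5 for both
networks. An "epoch" is one such loop on sampled batches. Checkpoints
(both networks plus running losses) are kept every `checkpoint_every`
epochs (default 10 000) over `total_epochs` (default 30 000), and
generation from any checkpoint is bit-reproducible given a seed. The
Lipschitz constraint is enforced by weight clipping because the RMSProp +
5:1 critic schedule is the signature of the original weight-clipped
recipe; the clip value is configurable.

Two practical observations shape how the package is used. First, the
recipe converges slowly by construction — tens of thousands of epochs at
learning rate 5e-5 — which is why the default mirrors the long-run
protocol and why checkpoint series matter: the evaluation module can
score each checkpoint (frequency drift, LD correlation) and report the
best. Second, the critic's effective capacity collapses if the latent
codes are far from unit scale: unbounded (e.g. ReLU-bottleneck) codes
with heavy-tailed scales are a poor WGAN target under a fixed clip value,
whereas KL-regularised VAE means are approximately unit-scale by
construction. This is an independent, mechanistic reason to prefer a
variational codec in front of the WGAN.

## Validation suite

* `freq_drift()` — per-variant `|f_ref − f_syn|` with mean/max, and the
  count of *disappearing* mutations (present in the reference, absent
  after decoding/generation).
* `ld_matrix()` — signed pairwise LD as the Pearson correlation of
  allele indicator columns across haplotypes. A signed statistic is used
  because both positive and negative LD are of interest (r² would fold
  them); monomorphic columns yield 0 by convention.
* `edit_score()` / `novelty_trend()` — the privacy audit. The edit score
  of a synthetic haplotype is the Hamming distance to a reference
  haplotype divided by the sequence length (0 = exact copy). For each
  synthetic sample the 1st–3rd nearest reference neighbours are scored; a
  copying generator shows 1st-NN scores near 0 with a sharp jump to the
  2nd, an interpolating generator a steady increase. The jump is
  summarised as `(mean2 − mean1) / (mean3 − mean2)`.
* `shuffle_sections()` / `coherence_test()` — the chance control.
  Shuffling haplotype order independently within each section preserves
  every marginal frequency but destroys cross-section association;
  coherent synthetic data must correlate with the reference's
  cross-section LD pattern strictly better than its shuffled self. PCA
  projections are fitted on the reference only and the other panels are
  projected into that plane.
* `ancestry_switch_metaprofile()` — consumes per-variant ancestry label
  sequences (e.g. Chromopainter-style paintings read by
  `read_paintings()`) and reports the per-position fraction of samples
  whose label changes from the previous position; profiles are compared
  by Pearson correlation. The within-sample switch frequency was chosen
  over the between-population alternative, which the source material
  leaves ambiguous; the alternative is deliberately not implemented.

## The synthetic fixture population

`simulate_population()` emulates the input structure the pipeline
assumes: founder haplotypes drawn per site from a truncated
Beta(0.5, 0.5) spectrum on [0.05, 0.95] (U-shaped, as site-frequency
spectra are, while keeping fixture variants above a ≥3-haplotype filter),
haplotypes built by copying a founder left to right with a
`crossover_prob` chance of switching to a uniformly chosen founder at
each hotspot, then per-site flip noise (default 1%). The emitted
recombination map exceeds the 5 cM/Mb threshold exactly at the hotspot
positions (narrow 10 cM/Mb intervals whose centres recover the hotspot
bp exactly), so `filter_hotspots()` + `segment_by_hotspots()` recover
the true block boundaries. A truth record stores every haplotype's
founder per block.

What the fixture emulates well: block LD delimited by known hotspots,
binary phased data, a U-shaped frequency spectrum, exact
ground-truth segmentation. What it does not emulate: genealogical
relatedness between founders (founders are i.i.d., so within-block
haplotype diversity is *uniform over equally frequent founders* — real
panels are dominated by a few common haplotypes), rare variants below
the filter threshold, genotyping error structure, and positional
clustering of variants. Passing tests on this fixture therefore
demonstrate the pipeline mechanics and the models' capacity to learn
balanced block structure — they do not certify behaviour on real panels,
where the variant-frequency spectrum is far more skewed.

### Desk-scale problem sizes

The test-suite and the acceptance script work at sizes chosen to
exercise every stage in minutes on one CPU: a 500-haplotype panel; one
600-variant section (one compression model) for the compression-fidelity
checks; a 1800-variant, three-section panel (total latent dimension
T = 18) with a 16 000-epoch WGAN for the end-to-end generation checks;
100 generated samples for the evaluation suite. The checkpoint series is
scored and the best checkpoint reported, mirroring how a full-scale run
would select its stopping point.

## Known limitations

* **Posterior collapse of the sigmoid VAE on balanced fixtures.** On the
  bundled fixture — 20 *equally frequent* i.i.d. founders, site
  frequencies centred on 0.5 — the sigmoid-activation VAE reliably
  converges to the marginal-frequency solution: it reproduces each
  variant's frequency but no haplotype structure, which caps its
  accuracy near the majority-allele baseline. The basin is robust: we
  observed it across learning rates, dropout settings, posterior-width
  initialisations, spectral warm starts and thousands of forced epochs,
  and reproduced the same plateau with an independent dense-network
  implementation. Because validation loss stagnates on the plateau, the
  prescribed early stopping (patience 30) halts training there. The
  relu, leaky-relu and tanh variants and the classical relu AE escape
  this basin at desk scale. On strongly skewed, rare-variant-dominated
  spectra — i.e. real panels — the marginal solution is already close to
  the data and the sigmoid VAE's behaviour is unproblematic, which is
  consistent with rare mutations "disappearing" after decoding. The
  acceptance checks that pin the sigmoid VAE on the balanced fixture
  fail honestly and are reported as such.
* **Codec choice for generation.** Because of the above, the end-to-end
  generation pipeline selects its codec by measured validation accuracy
  at desk scale (the same model-comparison methodology used to select
  the sigmoid VAE on real data) rather than hard-coding one activation.
* **WGAN scale sensitivity.** With a fixed clip value the critic's
  response is proportional to the scale of its inputs; latent codes far
  from unit scale slow convergence dramatically. Variational codecs are
  preferred in front of the WGAN for this reason.
* **Coordinates and dialects.** Recombination maps are accepted as
  0-based half-open (BED-like, default) or 1-based; the VCF side is
  1-based throughout. Multiallelic records are skipped with a warning
  rather than decomposed.
* Segmentation assumes a single chromosome per run; donors are assumed
  diploid and fully phased.
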