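---
title: "Dual-branch spatial EEG features and domain-adversarial training: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch spatial EEG features and domain-adversarial training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

EEG-based emotion classifiers generalise poorly across people: two subjects in
the same affective state produce band-power patterns that differ by per-channel
gains, offsets and idiosyncratic topography. `eegadapt` implements a
cross-subject classification pipeline that attacks this from two sides at once:

1. **Two complementary spatial representations** of the same per-window
   differential-entropy (DE) features — a scalp-grid *activity map* for a
   convolutional branch, and an electrode *topology graph* for a
   graph-attention branch — fused by concatenation into one feature vector.
2. **Domain-adversarial training**: a domain classifier tries to tell the
   labeled training subjects (source) from the held-out subject (target,
   unlabeled), while a gradient-reversal layer pushes the shared feature
   extractor toward representations the domain classifier cannot separate.

Evaluation is leave-one-subject-out (LOSO): every subject is the test target
exactly once, and only that subject's *unlabeled* windows enter training,
through the domain loss (a transductive protocol — target labels are never
touched before scoring).

## Feature pipeline

Raw recordings (62 channels, nominally 200 Hz, microvolts) are band-pass
filtered into the five conventional rhythms — delta 1–4, theta 4–8, alpha
8–14, beta 14–31, gamma 31–50 Hz — with a 5th-order Butterworth applied
forward and backward (`signal::filtfilt`), so filtering is zero-phase. Each
band-filtered trial is cut into non-overlapping 4-s windows (trailing
remainder dropped), and per window and channel the differential entropy is
computed with the Gaussian closed form

$$h = \tfrac12 \ln(2\pi e \hat\sigma^2)\ \text{nats},$$

where $\hat\sigma^2$ is the sample variance of the band-filtered window. This
is the standard DE estimator for short band-limited EEG windows, and it gives
the package an exact calibration handle: multiplying a channel's amplitude by
$a$ shifts its DE by exactly $\ln a$, which the tests exploit throughout.

The 62×5 DE matrix is then rendered twice:

* **Activity map** — each electrode's five band values are placed at its cell
  of a 9×9 scalp grid (row 0 = frontal edge); empty cells are exactly zero.
  The map is lossless: the grid placement is injective, so the 62×5 matrix is
  recoverable by inverse lookup, and the tensor total equals the matrix total.
  9×9 is the smallest lattice that admits an injective placement of the
  62-channel 10–20 montage shipped with the package.
* **Topology graph** — electrodes are nodes carrying the same 5-band features;
  edges come from a configurable rule. The default is 4-nearest-neighbour on
  planar scalp coordinates, OR-symmetrised, with self-loops. The edge set is a
  deliberate design choice (sparse local connectivity, swappable via
  `build_adjacency()`); nothing in the method constrains it, and `radius` and
  `full` rules are provided.

Before entering the model, each of the 62×5 entries is z-scored with
statistics fitted on the training (source) split only and stored with the
checkpoint.

## The extractor (SATFEM)

**Graph-attention branch.** Single-head graph attention layers: with node
features $h_i$, weight $W$ and attention vector $a = [a_1; a_2]$,

$$e_{ij} = \mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j]), \qquad
\alpha_{ij} = \mathrm{softmax}_{j \in \tilde N(i)}(e_{ij}), \qquad
h_i' = \sigma\!\Big(\sum_{j \in \tilde N(i)} \alpha_{ij} W h_j\Big),$$

over the self-looped neighbourhood $\tilde N(i)$. Defaults: two layers
5→32→32, ELU output nonlinearity, LeakyReLU slope 0.2, mean-pool readout over
nodes. Depth, widths, readout (`mean` or `flatten`) and $\sigma$ are
configuration; the defaults are the canonical single-head choices, since only
the single-layer attention arithmetic is fixed by the method. Self-loops
guarantee no neighbourhood is empty, so the softmax is always well defined.

**Residual activity branch.** A modified 8-block BasicBlock ResNet whose stem
takes 5 input channels directly: 7×7 convolution, stride 2, padding 4, no
bias, then batch-norm → ReLU → 3×3 max-pool (stride 2, padding 1). On a 9×9
input the stem yields 6×6 then 3×3 feature maps. Each BasicBlock is
Conv3×3→BN→ReLU→Conv3×3→BN on the main path plus a shortcut, summed and
ReLU'd. Two shortcut conventions are implemented:

* `standard` (default): identity when shapes match, stride-matched 1×1
  convolution + BN otherwise — the ordinary residual-network convention,
  consistent with a shortcut that "bypasses the convolutional layers";
* `printed`: a 3×3 convolution followed by a 1×1 convolution and BN on every
  shortcut. This composition appears in one published formula for the block
  but contradicts both the standard architecture and the accompanying prose;
  it is kept as an option for comparison rather than as the default.

A 9×9 spatial budget cannot survive stride-2 entries at all four stages (it is
already 3×3 after the stem), so stage entries use stride 2 only while the
incoming map is larger than 3×3 and fall back to stride 1 otherwise. This
preserves the 8-block depth without degenerate shapes. Global average pooling
produces the branch vector (512 for the default widths 64/128/256/512).

**Fusion** is plain concatenation, activity branch first; it is lossless by
construction (both inputs are recoverable by slicing). Dropout (default rate
0.7, the published training recipe's value) is applied to the fused vector —
the rate is specified by the recipe but not its placement, and the fused
feature is the natural single point upstream of both heads.

## Domain-adversarial training

The emotion head is a single fully connected K-way layer; the domain head is a
2-layer MLP (fused→64→2) with ReLU — a minimal nonlinear discriminator, since
its architecture is otherwise unspecified. The adversarial objective is

$$E(\theta_f, \phi_y, \psi_d) = L_{\text{emotion}} - \lambda\, L_{\text{domain}},$$

with mean cross-entropies: the emotion loss over the labeled source batch, the
domain loss over source ∪ target. Two realisations are provided:

* `grl_joint` (default): one optimiser minimises
  $L_{\text{emotion}} + L_{\text{domain}}$, with the $-\lambda$ factor
  realised inside the gradient-reversal layer (identity forward, gradient
  multiplied by $-\lambda$ backward). This is the canonical single-pass
  realisation of the minimax.
* `alternating`: an explicit feature/emotion update (with reversed domain
  gradient, domain head frozen) followed by a domain-head-only update, per the
  two-step argmin/argmax description. Both are exposed because the method is
  described both ways; the joint form is the default as the simpler device.

$\lambda$ follows the standard warm-up ramp
$\lambda(p) = 2/(1+e^{-10p}) - 1$ over training progress $p$ (a constant
schedule is available); neither a value nor a schedule is prescribed by the
method, and a constant λ is unstable early in training. Optimisation is Adam
at learning rate 5e-4, batch 64 — half source, half target per adversarial
step — per the published recipe; the epoch budget (default 100) is a package
default, with the final-epoch model selected so no target-label peeking can
occur.

Each step forwards the source half-batch and the target half-batch
separately. This keeps batch-norm statistics per forward pass and makes a
useful identity exact: with $\lambda = 0$, adversarial training is
*step-for-step identical* to plain supervised training with the same seed
(the tests assert equality at tolerance zero). To make that hold, every
randomness source has its own named stream derived from the base seed —
parameter init per component, batch shuffling per domain, dropout per domain
— so e.g. target-side draws never advance source-side streams.

## Synthetic cohort

The generator emulates the *shape* of a 62-channel, 200 Hz, 15-subject,
3–4-class emotion study, with two switchable kinds of class signal and a
controlled domain shift:

* **Amplitude signal** (activity-detectable): per class, one (band, scalp
  region) cell's band-limited noise amplitude is multiplied by 1.8
  (e.g. class 0 boosts posterior alpha). The induced DE shift is exactly
  ln 1.8 ≈ 0.59 nats on affected channels — large against the ≈0.05-nat
  sampling noise of an 800-sample DE estimate, so the cohort is solvable
  (a nearest-centroid oracle on the true generative pattern exceeds 90%
  accuracy, asserted in tests).
* **Correlation signal** (topology-detectable): per class, four electrode
  pairs share an additional alpha-band component (amplitude 0.9), which both
  correlates the pair and raises its alpha DE in a class-specific spatial
  pattern.
* **Domain shift**: per subject, a per-channel multiplicative gain
  (log-normal, sd 0.4 on the log scale) and additive offset (sd 1 µV). The
  gain moves every band's DE of a channel by ln(gain) — a shift that source
  z-scoring cannot remove for an unseen subject, which is exactly the gap
  adversarial training is meant to close. The offset is DC and mostly
  removed by band-pass filtering; it is included as the simplest realistic
  sensor-level shift.

Band-limited noise is synthesised by FFT masking of white noise (exact band
edges, no filter transients), normalised to unit variance. Everything is
derived from one seed via named streams, so cohorts are bitwise reproducible
and a trial can be regenerated in isolation.

What the generator does **not** emulate: 1/f background spectra, artifacts
(blinks, muscle), event-related dynamics, or stimulus timing. Passing the
package's tests therefore demonstrates that the pipeline recovers the kinds of
structure it models — band-power patterns, spatially correlated components,
multiplicative subject shifts — not that it reaches any particular accuracy on
real recordings.

## Scaled study conditions

The acceptance checks and `scripts/acceptance.R` run a desk-scale version of
the cross-subject study, chosen once as the smallest configuration in which
the qualitative comparisons are meaningful on one CPU:

* cohort: 6 subjects × 3 classes × 3 trials × 16 s (216 windows), strong
  gain shift (sd 0.4);
* model: graph branch 5→16→16, residual branch widths 8/16/16/32 with one
  block per stage, dropout 0.3 (the full-width 0.7 rate is too destructive
  for a 48-dimensional fused feature);
* training: 15 epochs, batch 32, Adam 5e-4, λ ramp; 5 seeds; full LOSO
  (6 splits) per seed.

Reported statistics are per-seed means over the LOSO splits, compared via the
median over the 5 seeds — a seed-robust ordering statistic, not a per-seed
guarantee. The tested qualitative pattern is: fusion ≥ either single branch,
and adversarial training ≥ fusion alone, both above the 33.3% chance level.
One structural caveat applies to the first comparison: both branches consume
the same 62×5 DE matrix, so no class signal can be strictly exclusive to one
branch — the generator's correlated-pair components, for instance, also leave
a DE signature either branch can read. Fusion therefore adds capacity and a
second inductive bias but no information the stronger branch lacks, and
"fusion ≥ best single branch" is a tendency that a particular cohort draw can
violate, unlike the adaptation comparison, which targets a shift the
no-adaptation model structurally cannot correct.

## Numerical choices and edge cases

* Filters are applied over whole trials (then windowed), avoiding per-window
  transients; recordings shorter than the filtfilt warm-up raise a
  `too_short` error rather than returning garbage.
* Zero-variance windows make the DE undefined (−∞); the package raises a
  `degenerate_signal` error instead.
* Attention softmax subtracts the row maximum before exponentiation; masked
  (non-neighbour) entries are excluded exactly.
* Batch-norm uses biased batch variance with running-statistic momentum 0.1
  and ε = 1e-5; evaluation always uses running statistics.
* The k-nearest-neighbour rule breaks distance ties by electrode index, so
  adjacency construction is deterministic.
* Cross-entropies clamp probabilities at 1e-12; a non-finite loss aborts
  training with a `numerical` error rather than continuing silently.
* `knn` with k = 0 degenerates to the self-loop-only graph (useful as a
  no-message-passing control) rather than erroring.

## Known limitations

* The neural-network core is plain R matrix code. It is exact (gradients are
  verified against finite differences) but sized for scalp-map inputs; it is
  not a general-purpose deep-learning substrate, and full-width training at
  the published scale is outside its intended envelope.
* Raw input is the package's delimited matrix + JSON sidecar format; EDF
  ingestion is not provided.
* Single-head attention only; no learned or weighted adjacency.
* The LOSO harness scores 4-s windows independently by default. A
  majority-vote-per-trial option exists but is off, since window-level DE
  samples are the evaluation unit throughout.
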