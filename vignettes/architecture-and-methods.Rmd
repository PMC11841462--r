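---
title: "Model, training procedure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, training procedure and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciacnet)
```

## The decoding problem

Motor imagery (MI) — the mental rehearsal of a movement — modulates the
sensorimotor rhythms of the EEG: imagining a left-hand movement attenuates
mu/beta band power over the contralateral motor cortex (event-related
desynchronization, ERD) and can enhance it elsewhere (ERS). A motor-imagery
brain–computer interface must decode, from a single trial
$X_i \in \mathbb{R}^{C \times T}$ of $C$ channels and $T$ samples, which of
$N$ imagined movements produced it. This package implements a compact
convolutional classifier for that task: two parallel EEGNet-style
convolutional branches, a channel/spatial attention block whose pooling set
is extended with stochastic pooling, a dilated causal temporal convolutional
network (TCN), and multi-level feature concatenation into a dense softmax
head. Everything — layers, attention, TCN, manual backpropagation and the
Adam training loop — is implemented in the package (R with C++ kernels for
the convolution, batch-normalization and ELU inner loops).

## Preprocessing

The only preprocessing is per-channel Z-score normalization,
$X' = (X - \mu)/(\sigma + \varepsilon)$, with $\mu$ and $\sigma$ pooled over
all trials and time points of the *training* set (population variance). No
filtering, re-referencing or artifact rejection is performed; robustness to
artifacts is a property the architecture itself is expected to supply. One
printed form of the normalization divides by the variance $\sigma^2$, while
the accompanying text requires unit standard deviation; `zscore_apply()`
divides by the standard deviation, which is the only reading that actually
standardizes the data. A zero-variance guard `epsilon` (default `1e-8`)
maps constant channels to zero.

## The convolutional branches

Each branch (`build_branch()`) follows the EEGNet lineage:

1. temporal convolution, kernel `1 x K_temporal`, length-preserving
   padding — a learned filter bank (CV1: 16 filters of length 32, CV2: 32
   filters of length 64, i.e. a longer time window and richer bank);
2. depthwise convolution with kernel `C x 1`, depth multiplier `D = 2`,
   valid padding — learned spatial patterns that collapse the electrode
   axis;
3. pointwise temporal convolution, kernel `1 x 16` (CV1: 32 filters, CV2:
   64).

Batch normalization follows every convolution; ELU, average pooling
(`1 x 8`) and dropout (rate 0.3) follow stages 2 and 3; every convolution
kernel carries a ridge (L2) penalty added to the training loss. With
length-preserving temporal convolutions, downsampling comes from the pools
alone, so the output length is the double floor division implemented by
`out_len()`: $1125 \to \lfloor 1125/8 \rfloor = 140 \to
\lfloor 140/8 \rfloor = 17$. These printed lengths are what fixes two
otherwise open choices: temporal convolutions must use "same" padding and
pooling must floor-divide (discarding the remainder), because no other
combination reproduces 140 and 17 from an 1125-sample trial. The default
trial window of 1125 samples (4.5 s at 250 Hz) is likewise the only window
consistent with those lengths, although the benchmark description speaks of
4-s trials; the package treats the window as a user-facing parameter with
1125 as default. Layer ordering inside a stage (conv → BN, ELU only after
stages 2 and 3, dropout after each pool) follows the cited architecture
family; the original figure does not fully order BN/ELU/dropout.

Convolutions immediately followed by batch normalization carry no bias term
(the BN shift absorbs it); the TCN's 1x1 residual projection keeps its
bias.

## The attention block

The block gates a feature map $F \in \mathbb{R}^{C_f \times H \times W}$
twice: $F' = M_c \odot F$ (channel gate, broadcast over positions), then
$F'' = M_s \odot F'$ (spatial gate, broadcast over channels).

*Stochastic pooling.* Alongside the usual global average and max pooling, a
third descriptor pools by chance: activations in a region are clamped at
zero and normalized to probabilities $p_i = a_i / \sum_k a_k$; `"sample"`
mode draws one element from that multinomial, `"expectation"` mode returns
$\sum_i p_i a_i$. Clamping is required because BN/ELU produce negative
activations while the original stochastic-pooling formulation assumes
non-negative ones; an all-zero region falls back to uniform probabilities
and pools to 0. During training the block samples (the gradient is routed
to the selected element, as in max pooling); at inference it uses the
deterministic expectation, whose exact gradient
$\partial/\partial a_k \left(\sum b_i^2/\sum b_i\right)$ is also
implemented, making the whole network finite-difference checkable.

*Channel gate.* Average, max and stochastic pooling each reduce $F$ to a
$C_f$-vector; a shared two-layer perceptron (hidden width
$\lceil C_f/r \rceil$ with reduction ratio $r = 8$, ReLU) scores each, and
the three scores are summed and squashed by one sigmoid. The printed
formula instead sums three separate sigmoids; the surrounding prose
("summed, followed by the application of a sigmoid") and the standard CBAM
convention keep the gate in $(0,1)$, so `sum_then_sigmoid` is the default
and the literal `sum_of_sigmoids` variant (gate in $(0,3)$) remains
available via `channel_combine_mode` — the package asserts neither as
authorial intent. The ceiling in the hidden width keeps it at least 1 for
small $C_f$.

*Spatial gate.* At every position the channel fiber is pooled three ways,
the three maps are stacked and convolved with a `7 x 7` kernel
(length-preserving padding) and squashed by a sigmoid.

In the default mode both gates lie in $(0,1)$, so the block is an
elementwise contraction — a property the test suite verifies on random
inputs.

## The temporal convolutional network

The TCN (`build_tcn()`) stacks `L = 2` residual blocks of two dilated
causal convolutions each (kernel `K_T = 4`, 32 filters, BN + ELU + dropout
after each convolution, ELU after the residual sum). Causality is enforced
by left-padding each convolution with $(K_T - 1) \cdot d$ zeros. Block
$\ell$ uses dilation $2^{\ell-1}$ in both of its convolutions — the
schedule under which the closed-form receptive field

$$\mathrm{RFS} = 1 + 2 (K_T - 1)(2^L - 1)$$

is exact (19 for the defaults, enough to cover the 17-step sequences the
branches emit). The dilation schedule is not stated explicitly by the
source architecture; it is chosen here precisely so that this formula is
exact, and the test suite confirms it by measuring the gradient reach of
built networks. The residual connection is the identity when input and
output channel counts match and a 1x1 convolution otherwise; the
post-addition ELU follows the cited TCN lineage.

## Topology and training

The full model (`build_ciacnet()`) routes the input through CV1 →
attention → TCN, with the attention output also skipped directly to the
classifier, and CV2 in parallel: the flattened attention output
(32 x 17), TCN output (32 x 17) and CV2 output (64 x 17) are concatenated
(2176 features for the default geometry) into a dense softmax layer. Full
flattening before concatenation is the least-assuming reading of
"concatenated and fed into the FC layer". `make_variant()` excises any
subset of {CV2, IAT, TC} and re-wires the concatenation, which reproduces
the eight ablation topologies; removing the attention block routes the CV1
output directly to the TCN and the skip.

Training (`train_ciacnet()`) is mini-batch Adam on categorical
cross-entropy plus the ridge penalties, with the reference recipe as
defaults: learning rate 0.001, batch size 64, up to 1000 epochs, early
stopping after 300 epochs without validation-accuracy improvement, weights
checkpointed only on validation-accuracy improvement, and the learning
rate multiplied by a factor (default 0.9, patience 20 — both unstated in
the source and therefore configurable) when the validation loss plateaus.
When no validation set is given, a stratified 20% of the training set is
held out (the source does not define its validation split). Batch-norm
running statistics use momentum 0.9 so that at desk-scale epoch counts the
inference statistics track the batch statistics closely enough for
validation metrics to be meaningful. Predictions (`predict()`) use running
statistics, no dropout and expectation-mode pooling, and are therefore
deterministic.

## The synthetic generator

`generate_mi()` emulates the physics the classifier exploits, not the full
richness of EEG. Every channel carries a band-limited oscillation — eight
sinusoids drawn uniformly from `rhythm_band` (default 8–13 Hz, the mu
band) with random phases, amplitude-modulated by a smooth within-trial
envelope and normalized to RMS `rhythm_amplitude` (default 10 µV, a
realistic sensorimotor-rhythm magnitude). On the target channels of a
trial's class the amplitude is scaled by `1 - erd_depth`, so band power
drops by $(1-\texttt{erd\_depth})^2$ — the ERD signature. Class-to-channel
assignment is a deterministic round-robin (`mi_target_channels()`), so
tests can address the modulated channels. Independent Gaussian broadband
noise (default SD 5 µV) is added everywhere, and optional exponentially
decaying high-amplitude bursts (`artifact_rate`, default 0 — artifacts are
exercised explicitly in tests rather than by default) mimic the transients
the preprocessing deliberately keeps. Defaults mirror the small benchmark
geometry (22 channels, 1125 samples at 250 Hz, 4 classes, 40 trials per
class, `erd_depth` 0.7).

What the generator does *not* model: a physiological forward head model,
1/f spectral shaping, inter-subject variability, eye/muscle artifact
morphology. Tests passing on this data therefore demonstrate that the
architecture, gradients and training loop are correct and that the model
can exploit class-dependent spatio-spectral structure — not that it
attains any particular accuracy on real recordings.

## Desk-scale study sizes

The acceptance suite trains the full-size network (22 x 1125, four
classes) on 40 trials per class with a 75/25 train/test split, 12 epochs
at batch size 16, and reports the median held-out accuracy over five
seeds; a permuted-label control (6 epochs) verifies that accuracy collapses
to chance when the labels carry no information. Twelve epochs at batch 16
is the point where training on this generator has reliably passed its
steep initial learning phase; the reference recipe's 1000-epoch budget
remains the package default for real use.

## Numerical choices and degenerate inputs

* Average pooling floor-divides and discards the remainder
  ($1125 = 8 \cdot 140 + 5$: five samples are dropped), matching the
  printed lengths; the discarded tail receives zero gradient.
* Zero-variance channels normalize to zero; all-zero pooling regions pool
  to zero with zero gradient.
* Batch normalization guards variance with $10^{-5}$; kappa is undefined
  (an error) when the expected agreement is 1; empty trial sets, label
  mismatches, channel-count mismatches and too-short windows raise errors
  naming the offending quantity.
* Weight initialization is Glorot-uniform; `build_ciacnet(seed = )` makes
  initialization reproducible, and all stochastic elements (shuffling,
  dropout, pooling samples) run off the single R RNG seeded by the
  training control.

## Known limitations

* The EDF adapter covers the single-sampling-rate subset of EDF used for
  epoching experiments; GDF files are rejected with an explicit error.
* Fixtures are stored as RDS (bit-exact, validated on load), a
  single-language container.
* Training is single-threaded CPU R/C++; it is intended for method study
  and desk-scale experiments, not for full benchmark sweeps.
* The SE and multi-head-self-attention substitutions reported alongside
  the architecture's ablations are out of scope; `make_variant()` covers
  block removal only.
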