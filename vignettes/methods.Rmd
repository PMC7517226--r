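---
title: "Speaker-level depression screening from speech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speaker-level depression screening from speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(depvox)
```

## The problem

Clinical depression leaves audible traces in speech: depressed speakers
tend to talk in a flatter, more monotonous way, with reduced prosodic
modulation and altered voice quality. `depvox` implements an end-to-end
screening pipeline that maps a long, per-speaker interview recording to a
binary decision — depressed or not — where "depressed" is defined by a
PHQ-8 questionnaire score of 10 or more. The pipeline operates at two
levels: the **sample level** (4-second crops of one recording) and the
**speaker level** (the final decision, aggregated over all of a speaker's
crops).

Clinical interview corpora of this kind are small (on the order of a
hundred speakers), imbalanced (roughly 100 non-depressed to 42 depressed
in a typical training roster), and access-restricted. The package
therefore ships a synthetic corpus generator with the same statistical
structure, so that every stage — and the pipeline as a whole — is testable
without restricted data.

## Balanced crop sampling

Recordings vary widely in length (after interviewer removal and silence
trimming, think 547 ± 238 s). Training directly on whole recordings would
give few, unequally sized inputs and a strong class bias. Instead each
recording is cut into non-overlapping 4-s crops aligned to multiples of
4 s from the recording start, and a subset is selected under two
constraints: the same number of crops `c` from every selected speaker, and
the same number of speakers `k` from each class. Among all feasible
`(c, k)` the plan maximizes the total `2·k·c`. Only the distinct available
crop counts need to be considered as candidate `c` values, so the search
is exact and instant; ties are broken toward smaller `c`, which retains
more speakers and reduces per-speaker bias. On the published roster
structure (31 speakers per class with 89 available crops, the rest with
fewer) this yields 89 crops × 62 speakers = 5518 training samples.

Design choices made here, where the procedure was open:

* Crops are non-overlapping and grid-aligned; random placement among the
  aligned offsets (seeded) decides *which* crops are used when a speaker
  has more than `c`. Overlapping or jittered windows would leak
  near-duplicates between samples.
* Test speakers are never dropped: each contributes
  `min(cap, available)` crops (cap 89 by default), taken deterministically
  from the recording start.

## Log-spectrogram features

Each crop is represented as the log-magnitude short-time Fourier
transform: Hamming windows of 64 ms every 32 ms, 1024 FFT points, keeping
the 513 non-redundant frequency bins. A 4-s crop at 16 kHz therefore
becomes a 513 × 125 matrix.

The frame-count convention deserves a note. `floor(64000/512) = 125`
matches neither plain non-centered framing (124 frames) nor fully centered
framing (126). We use centered frames — frame *t* is centered on sample
`(t-1)·hop`, zero-padded at the edges — and drop the final boundary frame,
which reproduces `T0 = floor(n/hop)` deterministically for any crop
length. The window is the symmetric Hamming form; the periodic/symmetric
distinction changes the spectrum by well under 0.1% and is erased by the
normalization below.

Each spectrogram is min-max normalized to `[0, 1]` **independently**
(per-crop). Together with the logarithm this makes the feature invariant
to any positive gain applied to the waveform — a property the test suite
checks exactly — so loudness carries no class information. The log floor
is `eps = 1e-10`, far below any voiced magnitude; a fully silent crop maps
to a constant `log(eps)` matrix and normalizes to all zeros. Corpus-level
(standard) normalization is deliberately not implemented.

## The 1d-CNN

Spectrograms are not images: the two axes mean different things, and
frequency correlations matter at every time slot. The classifier therefore
uses **one-dimensional** convolution: `N` filters of size `F0 × 1`, each
spanning the whole frequency axis and one time slot, sliding along time
with stride 1. Because the kernel covers a full frame, the layer is
exactly a linear map applied per frame — one matrix multiplication per
batch — which is how the package implements it (base BLAS, no
deep-learning framework). The rest of the network:

* max-pool along time, kernel `(1, k)`, stride `(1, s)`, padding `p = s`
  (defaults k = 5, s = 4);
* flatten to `n3 = T1 · N` where `T1` is the pooled length;
* dense layer of `n4` ReLU units;
* one sigmoid output: the probability that the crop belongs to a depressed
  speaker.

ReLU activations everywhere except the sigmoid output; no dropout and no
batch normalization. Canonical widths are `N = n4 = 128`, giving parameter
counts 65 792 (conv), 524 416 (hidden dense) and 129 (output).

For the pooled length we adopt the same-padding convention
`T1 = ceil(T0/s)` (32 for the canonical geometry); the padding value `p`
is then implied by the output size, which matches how a single `p`
parameter alongside "preserve the extremes" is normally meant. The
explicit textbook formula `floor((T0+2p-k)/s)+1` (which gives 33) is
implemented and switchable via `pool_convention = "explicit"`.

Training: Adadelta (rho 0.95, eps 1e-7 — the Keras defaults, the framework
this family of systems is normally built in), binary cross-entropy, 50
epochs, batch 80, and a learning rate decaying **exponentially** across
epochs from 1 to 0.01 (the schedule endpoints are fixed; the exponential
shape is our choice). Every crop inherits its speaker's label. Weight
initialization is seeded Glorot-uniform with zero biases, and batch order
is reshuffled each epoch from the same seed, so a training run is
deterministic on a fixed BLAS. Training aborts with an error at the first
non-finite loss.

## From samples to speakers, and ensembles

A single machine yields per-sample probabilities `P_i = {p_il}` and hard
labels `y_il = [p_il >= 0.5]` for speaker *i*. Two speaker rules are
implemented: the **mode** of the hard labels, and the **mean** of the
probabilities thresholded at 0.5. They usually agree but need not (e.g.
probabilities 0.4, 0.4, 0.9 give mode 0 but mean 0.567 → 1). All
thresholds use `>=`; exact mode ties fall to a fair coin seeded by
`(tie_seed, speaker_id)`, so tie decisions are random by design yet
reproducible, and independent across speakers.

An ensemble trains `M` machines with identical architecture and data but
different initialization seeds, and fuses them one of three ways:

* **Method 1** — average probabilities over machines per sample, then over
  a speaker's samples, threshold 0.5. Both steps are plain means over a
  rectangular table, so this equals thresholding the grand mean of all
  `M·L_i` probabilities — an identity the tests assert exactly.
* **Method 2** — pooled mode over all `M·L_i` hard labels.
* **Method 3** — per-machine speaker mode, then mode across machines.

With `M = 1` all methods collapse onto their single-machine rules. The
default operating point is Method 1 with `M = 50`, the configuration that
performs best for this family of systems. The `f1_vs_M_curve()` helper
traces mean and sd of per-class F1 against `M` by drawing random machine
subsets (without replacement within a draw, with replacement across draws;
at `M` equal to the pool size only one subset exists and the sd is zero).

## Evaluation

Speaker-level accuracy plus per-class precision, recall and F1 (each class
in turn treated as positive, reported "depressed (non-depressed)"). A
never-predicted class reports precision 0 with a warning, keeping metrics
total on degenerate runs. Cross-validation splits **speakers** (never
samples) into stratified folds; per fold, an ensemble trained on the
remaining speakers predicts the fixed test set, and the per-fold
speaker-level prediction lists are concatenated — each test speaker
counted once per fold — before computing metrics. We read "concatenating
the partial results" this way; the per-fold-average alternative is
available via `pool_folds = FALSE`.

## The synthetic generator

`generate_speaker_audio()` produces a voice-like harmonic complex:
fundamental near 120 Hz (per-speaker spread ±10 Hz), 20 harmonics with 1/h
roll-off, slow random pitch modulation (three sinusoids in 0.5–3 Hz),
high-pass shaped noise above 3 kHz, and a low broadband floor. The class
signal lives in exactly two places — pitch-modulation depth and high-band
energy, both scaled by `(1 - 0.8·effect)` for the depressed class — i.e.
in slow temporal modulation and spectral tilt, quantities visible in a
log-spectrogram and *not* erased by per-crop min-max normalization. Mean
amplitude deliberately carries nothing. With `effect = 0` the classes
share one generative law; with `effect = 1` a simple spectral-tilt
threshold separates crops almost perfectly, which bounds what a trained
classifier can achieve and makes end-to-end recovery testable.

Durations follow a truncated normal (default 547.29 ± 237.58 s, truncated
at one crop) so the sampler's heterogeneous-duration logic is exercised;
PHQ-8-like scores are drawn per class consistently with the threshold-10
labels. One global seed expands into per-speaker seeds through a
counter-based scheme, so a corpus is stable under roster growth.

What the generator does **not** emulate: real phonetic content, speaker
turns, channel/microphone effects, or the within-speaker variability of
real interviews. Passing end-to-end tests on it shows the pipeline
recovers a class-dependent acoustic signature of the kind described —
not clinical performance on real corpora.

## Problem sizes used by the test suite

The heavier end-to-end checks run on deliberately scaled-down corpora,
chosen once as the package's own test protocol:

* ensemble behavior: effect 1, 20 speakers/class, durations ~44 ± 10 s,
  pool of 16 machines with `N = 8`, `n4 = 16`, 30 epochs, batch 20;
* null recovery: effect 0, 8 speakers/class, 3 machines, 6 epochs,
  3 corpus seeds, decisions pooled into one binomial test against chance.

Batch 20 (rather than the canonical 80) keeps the optimizer step count
per epoch in a regime comparable to full scale: ~200 training samples at
batch 20 give 9–10 steps/epoch versus ~69 at full scale, whereas batch 80
would give 3. The canonical defaults in `cnn_config()` are unchanged.

## Known limitations

* The diarization step is consumed as an interface (segment CSV or
  pre-cleaned audio), never computed; the energy-based silence trimmer is
  a stated fallback, not a reconstruction of any particular tool.
* Which "low-quality" recordings a given corpus curator removed cannot be
  reproduced; an exclusion list hook is provided instead.
* Training determinism holds on a fixed BLAS/platform; exact weight
  equality across different BLAS builds is not guaranteed.
* The CNN is CPU-bound pure R; it is sized for corpora of hundreds of
  samples per machine, not for GPU-scale experiments.
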