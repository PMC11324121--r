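---
title: "Masked-autoencoder pretraining for 12-lead ECGs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked-autoencoder pretraining for 12-lead ECGs: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgmae)
```

## The problem

Left-ventricular systolic dysfunction (LVSD) — an echocardiographic
ejection fraction (EF) below 40% — is common, dangerous, and invisible on
casual inspection of a 12-lead ECG, yet deep networks can detect it from
ECG voltage alone. Training such detectors normally demands large labeled
ECG–echocardiography archives. `ecgmae` implements the alternative studied
in recent ECG representation-learning work: *self-supervised* pretraining
of a Vision Transformer (ViT) with a masked autoencoder (MAE), which learns
reusable ECG representations from unlabeled records, followed by supervised
fine-tuning on a (possibly small) labeled set.

## Signal model and patch grid

A record is a 12 × 5000 voltage matrix: the standard leads (I, II, III,
aVR, aVL, aVF, V1–V6) for 10 s at 500 Hz, in millivolts. The only
preprocessing is a per-lead z-score (`normalize_ecg()`); there is no
band-pass filtering or baseline-wander removal. A lead with degenerate
variance (below `max(1e-8, 1e-8 * max|x|)`) becomes all zeros rather than
amplified quantization noise. Whether normalization should be per lead or
per record is genuinely open; per lead was chosen so that low-amplitude
precordial leads are not drowned by high-amplitude ones, and it makes
`normalize_ecg()` idempotent.

`patchify()` cuts each lead into 20 non-overlapping patches of 250 samples
(0.5 s), 240 patches per record, ordered lead-major with 0-based half-open
sample windows. The inverse `unpatchify()` is exact, bitwise. Masking
plans (`make_mask()`) support the three studied strategies at any ratio
(random; independent-per-lead; and a regular grid pattern defined for the
0.75 ratio only, keeping one time slot in four at a seed-derived phase —
the grid variant has no single canonical definition, so this regular
analogue of classic grid subsampling is a documented interpretation, as is
the per-lead variant's `round(20 r)`-per-lead rule).

## Architecture

The encoder is a standard pre-LayerNorm ViT: a linear projection of each
250-sample patch to the embedding width, a classification token, fixed
(non-trained) 2-D sine/cosine positional embeddings over the (lead, time)
grid, transformer blocks (multi-head self-attention + 4× MLP with GELU),
and a final LayerNorm. Size presets follow the standard ladder — Tiny
(192-d, depth 4, 3 heads), Base (768/12/12), Large (1024/24/16), Huge
(1280/32/16). The Base encoder here counts 85,249,536 trainable
parameters: slightly below the canonical "about 86 million" of the image
ViT-Base because the ECG patch projection consumes 250 inputs rather than
the 768 of a 16×16×3 image patch, and positions are fixed sinusoids rather
than learned. The block stack itself (85.05 M) is identical.

During pretraining only the visible patches enter the encoder — with the
default 75% random masking, 60 of 240 patches plus the classification
token. This is a hard contract, tested bitwise: altering masked-patch
voltages cannot change the encoder output. The decoder projects encoder
tokens to its own width, inserts a learned mask token at every masked
position, restores canonical grid order, adds its own fixed positional
embeddings, runs its blocks, and linearly maps every token back to 250
voltage samples. The loss is mean squared error over masked patches only.
Per-patch target normalization is available behind a flag but off by
default, since records are already lead-normalized upstream.

The full-scale decoder default (512-d, depth 8, 16 heads) follows the
original MAE; desk-scale runs use a 64-d, single-block decoder — the MAE
design principle is precisely that the decoder can be light, and at Tiny
encoder scale a large decoder would dominate runtime without changing any
tested property.

Initialization: Xavier-uniform for the patch/token projections, the
reconstruction head and the classifier head, truncated normal (sd 0.02)
for block weights and the class/mask tokens, zeros for biases. The Xavier
choice for projections matters in practice: with all-0.02 initialization
the content part of each token is small against the positional part,
record-to-record differences in pooled features nearly vanish, and
downstream heads collapse to the label base rate.

## Training protocols

**Pretraining** (`pretrain()`): AdamW (betas 0.9/0.95, weight decay 0.05),
base learning rate scaled by batch/256, linear warmup then cosine decay,
global gradient-norm clipping at 1.0, no mixed precision, a fresh random
mask per record per epoch from a seeded stream. The full-scale protocol
(1600 epochs, batches 1536/1280/768 for Base/Large/Huge) is the config
default; it is not run in tests.

**Fine-tuning** (`attach_head()` + `finetune()`): a pooled representation,
two fully connected layers (embed → 128 → outputs, GELU between) and a
per-output sigmoid, Adam on binary cross-entropy. The plateau rule is
implemented as a pure function (`scheduler_step()`): a strict improvement
of the monitored loss resets the counter and snapshots weights; otherwise
the learning rate halves whenever the counter hits a positive multiple of
3, and training stops at 10, restoring the best weights. Two readings of
the plateau rule are possible (halve repeatedly within one plateau vs
once per episode); the multiples-of-3 reading was chosen and is
exhaustively unit-tested, ties counting as non-improvements. The monitored
quantity is the *validation* loss — saving best-epoch weights only makes
sense against held-out data. Grid search over batch ∈ {32, 64, 128, 256}
and initial rate ∈ {1e-3 … 1e-6} selects the cell with the lowest
best-epoch validation loss (`finetune_grid()`).

Three fine-tuning choices deserve explanation, because each was forced by
measurement rather than taste:

* *Pooling.* The classification token is the default pooled
  representation. Masked-reconstruction pretraining concentrates
  record-level summary information there, while the mean over the 240
  patch tokens averages local morphology into a nearly record-independent
  vector: on a pretrained Tiny encoder, a linear probe of the
  classification token separates LVSD at AUROC ≈ 0.99 where the
  mean-pooled probe sits near 0.5–0.67. Mean pooling remains available
  (`pool = "mean"`).
* *Feature whitening.* `finetune()` fits a fixed, rank-truncated ZCA
  whitening of the pooled training features in front of the head
  (`whiten = TRUE`). The discriminative directions of the pretrained
  representation carry very little variance; a gradient-trained head is
  variance-biased and cannot reach them (train AUROC stalls near 0.8),
  while after whitening the same head separates the training set within a
  few epochs. Principal directions with near-zero training variance are
  projected out rather than amplified (relative floor 1e-4).
* *Encoder freezing and layer decay.* With very few labeled records
  (the low-label desk regime), any practical end-to-end learning rate
  degrades the pretrained features faster than the head can exploit them
  — Adam's scale-free updates move every coordinate regardless of
  gradient magnitude. `freeze_encoder = TRUE` therefore trains only the
  head on frozen pooled features (the desk-scale protocol of the
  reference experiment); for end-to-end runs, layer-wise learning-rate
  decay (`layer_decay`, default 0.75) trains the head at the full rate
  and block *i* at `decay^(depth + 1 - i)`, with the final encoder norm
  moving with the top block so the fitted whitening basis is not
  invalidated from above.

## The synthetic cohort

Hospital ECG–echo archives are private, so every downstream stage is
exercised on a synthetic cohort (`synth_cohort()`) built from a five-bump
Gaussian beat model (P, Q, R, S, T amplitudes/centers/widths), jittered RR
intervals, a fixed 12-entry lead-projection vector with rough
limb/precordial polarities, sinusoidal baseline wander (0.1 mV at 0.33 Hz)
and white noise (0.05 mV). Patients carry 1–3 ECGs (mean ≈ 1.6, matching
the multi-record-per-patient structure of hospital archives) and one echo
within 28 days. EF for non-LVSD patients is normal with mean 61.6 and SD
14.2 truncated to [40, 95]; LVSD patients draw EF uniformly from
[15, 39.5]; prevalence defaults to 8.3%. The LVSD morphology shift at
effect size $e$ multiplies the R amplitude by $1 - 0.4\,e\,(1 - EF/60)$,
the QRS widths by $1 + 0.5\,e$, and raises heart rate by $10\,e$ bpm —
an invented, version-pinned parameterization whose only purpose is a
controllable, learnable signal: at $e = 0$ the LVSD and non-LVSD signal
distributions are identical by construction.

What the generator does *not* emulate: real conduction physiology,
vectorcardiographic consistency across leads, arrhythmias, electrode
artifacts, device filtering. Passing tests on this cohort demonstrates
that the pipeline's mechanics work end to end — not that any clinical
performance level would transfer to hospital data.

## Desk-scale problem sizes

All tested experiments run on one CPU. The reference experiment
(`pretraining_benefit_experiment()`) uses 400 patients (≈ 640 records),
Tiny encoder with the 64-d single-block decoder, 30 pretraining epochs at
batch 16 with effective learning rate 1e-3 (warmup 3), then fine-tuning on
100 labeled records at batch 32, rate 1e-3, under the frozen-encoder
whitened-head protocol with the plateau rule (cap 50 epochs); the held-out
test split follows the 7 : 1.5 : 1.5 patient-level partition. Three
fine-tuning seeds per arm (pretrained vs randomly initialized encoder)
quantify run-to-run spread. Under this protocol the comparison isolates
representation quality: the pretrained encoder's features generalize from
100 labels while the random encoder's features only memorize them, which
is precisely the pretraining benefit the pipeline exists to demonstrate.

## Evaluation statistics

`auroc()` is the rank (Mann-Whitney) estimator with midrank ties — exactly
the all-pairs concordance count, and invariant under strictly increasing
score transforms. `auroc_ci()` uses the DeLong structural-components
variance with a normal interval clipped to [0, 1] — chosen over a
bootstrap for consistency with the paired comparison (`delong_test()`), which
uses the paired DeLong covariance and a two-sided normal reference.
Degenerate cases are defined, not left to chance: perfect separation gives
a flagged point interval; identical paired scores give z = 0, p = 1.
`macro_auc()` skips classes lacking both label values and averages the
rest; `format_run_summary()` renders repeated-run results as
`mean (SD digits)`, e.g. `0.960 (02)`.

The fast implementations are cross-checked in tests against brute-force
oracles (all-pairs concordance, O(mn) structural components), against
`pROC`, and — for the interval — against a 2000-resample bootstrap.

## Numerical choices and degenerate inputs

* float32 compute in the transformer core (single-threaded, deterministic
  given seeds); parameters and optimizer state in double precision.
* LayerNorm epsilon 1e-6; numerically stable softmax and
  log1p/softplus-based cross-entropy from logits.
* Empty masked set: reconstruction loss is an error (undefined), except in
  `reconstruct()` where a ratio-0 mask is a legitimate visualization case
  and yields `NA` loss.
* Single-class training labels warn and proceed (the loss is still
  defined); single-class evaluation labels are an error for AUROC.
* WFDB support covers the format-16 signal pathway used by the public
  500 Hz ECG distributions, with name-keyed channel remapping to the
  canonical lead order; other WFDB storage formats are rejected loudly.
* The one-to-one ECG–echo pairing processes echoes chronologically,
  consumes each ECG at most once, and breaks distance ties toward the
  earlier ECG — no canonical convention fixes these details; this rule is
  deterministic and documented.

## Known limitations

* The synthetic LVSD signal is strong and low-dimensional (rate, width,
  amplitude); it cannot measure clinical discrimination, only mechanism.
* Desk-scale pretraining (hundreds of optimizer steps) is far from the
  1600-epoch full protocol; reconstruction quality and representation
  strength are correspondingly modest.
* The PTB-XL adapter is exercised on a generated mini-fixture; running the
  real benchmark requires the dataset and full-scale compute.
* No arrhythmia/shunt exclusion logic and no echocardiography image
  handling: echo tables are used for EF labels only.
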