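---
title: "Methods: rPPG-based face anti-spoofing on synthetic pulsatile video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rPPG-based face anti-spoofing on synthetic pulsatile video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pulsegate)
```

## The problem

Remote photoplethysmography (rPPG) estimates the cardiac pulse from the tiny
periodic color changes that blood volume induces in facial skin, using nothing
but an ordinary RGB camera. Because a printed photograph has no pulse, rPPG is
an attractive liveness cue for face-recognition systems: a presentation attack
(photo, bent photo, replayed video) should lack the physiological signal a
live face carries. The catch is that *high-quality replay* attacks show a
recording of a live face, so a pulse-like signal is present, and *cut-out
photo* attacks let parts of the attacker's own (live, pulsing) skin show
through holes in a printed mask. `pulsegate` implements a full detection
pipeline for exactly this setting:

1. **Screening** — reject videos with gross motion or illumination changes
   (shaking, bending, moving lights) before any learning happens;
2. **Signal extraction** — per-frame skin-mean color signals in three face
   regions (whole face, nose area, eye area), CHROM pulse extraction,
   detrending, band-pass filtering and spectral heart-rate estimation;
3. **Clip classification** — compact LSTM/CNN/CRNN models over 90-frame
   clips of the 15 signal channels decide genuine vs. attack.

Real presentation-attack datasets are rarely redistributable, so the package
ships a first-class synthetic-video generator that renders face videos with a
*known* heart rate and attack type. Every experiment in the test suite and in
`scripts/acceptance.R` runs on this generator.

## The synthetic-video generator

`generate_video(scene_config(), attack_spec())` renders a flat skin-tone
ellipse with darker eye/mouth patches on a neutral background. No
photorealism is attempted — deliberately so: every downstream stage consumes
*color statistics* (skin-pixel means), not appearance, and a flat face with
the right statistical structure exercises the pipeline exactly as a real face
would exercise its color path.

The rendered processes, all seeded and deterministic:

* **Pulse.** Skin pixels are modulated along a G-dominant color axis
  (channel weights 0.5/1.0/0.3 for R/G/B) by
  `p(t) = sin(2 pi f t) + 0.5 sin(4 pi f t)` with `f = heart_rate/60` —
  a fundamental plus a half-amplitude first harmonic, a coarse cartoon of the
  asymmetric PPG waveform. The default fractional amplitude is 0.01
  (about 2.6 intensity units on an 8-bit scale), at the optimistic end of
  what rPPG sees in practice.
* **Respiration drift.** A slow luminance oscillation at
  `respiration_rate/60` Hz (default 0.25 Hz) that the detrending stage must
  remove.
* **Micro-motion.** The face center performs a reflected Gaussian random
  walk (default sigma 0.1 px/frame), emulating the involuntary head motion
  that remains after subjects are asked to hold still.
* **Surface texture.** A static, achromatic, smoothly interpolated random
  pattern rides on the face in face-local coordinates. It gives the
  Lucas–Kanade tracker gradients to grip (a perfectly flat ellipse would be
  untrackable through the aperture problem) and, being equal in R, G and B,
  leaves the chroma planes — and hence the skin mask — untouched.
* **Sensor noise.** Per-pixel, per-channel Gaussian noise (default sigma 2
  intensity units; the second simulated device profile uses 3 and a mild
  white-balance shift).

Attack kinds alter the rendering:

* `cutout_eyes_nose_mouth` / `cutout_cheek_chin` — the pulse (and
  respiration) is rendered only in the "live" sub-regions (eye/nose/mouth
  patches, or the cheek/chin band below 25% of the face half-height);
  elsewhere the face is a static print. This reproduces the attack logic of
  cutting holes into a photo so the attacker's own skin shows through.
* `replay` — the face keeps a pulse (it depicts a live person) but
  attenuated (x0.6), with the chroma ratio of the pulse deliberately
  distorted (R/G/B weights 0.25/1.0/0.8), an additive display/camera beat
  flicker at 3.3 Hz, and a doubled noise floor. The attack literature gives
  no quantitative signature for high-quality replay; this triplet is the
  package's own physically motivated assumption (display resampling distorts
  chroma, refresh-rate mismatch beats against the camera shutter, and
  re-imaging raises noise), documented here precisely because it is an
  assumption, not an observed fact.
* `shake` — circular jitter whose per-frame chord equals the magnitude
  (default 5 px/frame), so the motion-trace ground truth is exact.
* `bend_h` / `bend_v` — a time-varying achromatic shading gradient
  (default amplitude 0.2 of full scale at 0.8 Hz), as a bending photo
  catches the light.
* `light_sweep` — a Gaussian luminance band sweeping the frame at 0.5 Hz.

Defaults were chosen once, as the study conditions: 96 x 72 px, 30 fps, 10 s
(300 frames; enough for 22 sliding-window clips per video), heart rates drawn
uniformly from 48–120 bpm in benchmark suites. Shorter 5 s scenes are used
where only screening traces are needed. The generator ground-truths every
video with its region track, label and BPM, so downstream modules can be
tested against known answers.

What the generator does **not** emulate — and what passing tests therefore do
not show about real data: real facial geometry and specular shading,
compression artifacts, color-dependent camera response, pulse-rate
variability within a video, 3D masks, and the full diversity of real replay
hardware. Results on this benchmark validate the *pipeline mechanics and the
relative orderings* (e.g. multi-region beats face-only), not absolute
real-world accuracy.

## Color conversion and skin masking

RGB frames (normalized to [0, 1]) are converted with the BT.601
full-to-studio-swing transform, `Y' = 16 + 65.481 R' + 128.553 G' + 24.966
B'`, chroma centered at 128. One printed variant of this equation circulates
with all-positive chroma coefficients; that version would push chroma far
outside its [16, 240] range for bright pixels, so the package uses the
standard signs (the magnitudes are identical) and treats the all-positive
form as a typographic slip. An independent matrix-multiply oracle pins the
implementation to 1e-9.

Skin pixels are masked by the static chroma band `133 <= Cb <= 173` and
`77 <= Cr <= 127`, bounds inclusive, applied to the whole frame once per
frame. The generator's face color is chosen to sit mid-band (Y' 150, Cb 150,
Cr 100). Per-region signals are the means of R, G, B, Y', Cb, Cr over
skin-masked pixels inside each region box; frames whose box contains less
than 5% skin are flagged invalid and linearly interpolated over gaps of up to
5 frames (longer gaps abort — the series would no longer be trustworthy).

Region geometry, given a face box: the eye area spans face rows 20–40% of
the face height, the nose area rows 40–65%, both 60% of the face width,
centered. These fractions are a stated convention — deterministic and
landmark-free — because "the area around the nose/eyes" admits many
delimitations and the color statistics are insensitive to the exact one.
Face detection and tracking are injected contracts (`track_rois()`): tests
use the generator's ground-truth track; the default adapters locate and
follow the skin mask, which suffices for the synthetic faces; production
users can plug in a DNN detector and a KCF-style tracker without touching the
pipeline.

## Pulse extraction

**CHROM.** Each channel mean is standardized by its running mean over the
analysis window length (1.6 s, the standard choice for the chrominance
method) and projected onto `X = 3 R_n - 2 G_n` and
`Y = 1.5 R_n + G_n - 1.5 B_n`; both projections are band-filtered and
combined as `S = X_f - alpha Y_f`, `alpha = sd(X_f)/sd(Y_f)`, with alpha
computed per 1.6 s window (50% overlap, Hann overlap-add). This cancels
intensity-driven variation (motion, illumination) to first order while
keeping blood-volume chrominance. One numerical choice matters here: the
band-pass runs over the *full* series rather than over each 1.6 s snippet.
An order-4 IIR filter applied forward-backward to a 48-sample window is
dominated by edge transients at pulse periods comparable to the window
(~0.85 Hz, i.e. ~50 bpm), which attenuated low heart rates enough for the
waveform's first harmonic to win the spectral peak; filtering the whole
series removes that bias while leaving the windowed standardization and
adaptive alpha of the method untouched.

**Detrending.** The smoothness-priors method: the trend is
`(I + lambda^2 D2' D2)^{-1} z` (`D2` the second-difference operator), solved
with a sparse Cholesky factorization; the detrended signal is the residual,
scaled to zero mean and unit variance. `lambda = 300` at 30 fps puts the
effective cutoff well below the pulse band: a 0.05 Hz drift is removed to
under 1% residual while a 1.2 Hz tone passes with correlation > 0.99. Note
the parameter's direction: larger `lambda` means a *smoother* trend and
*less* removed; the degenerate small-`lambda` limit removes everything and is
rejected as a zero-variance error.

**Band-pass.** A digital Butterworth band-pass (order 4 per edge) between
0.7 Hz (42 bpm) and 4.0 Hz (240 bpm), applied forward–backward by default so
the phase is zero. The implementation's magnitude response is held to the
analytic prototype `|H|^2 = 1/(1 + ((Omega^2 - Omega_l Omega_h) /
(Omega (Omega_h - Omega_l)))^{2N})` at prewarped frequencies to 1e-6.

**BPM.** The pulse signal is Hann-windowed, zero-padded to the next power of
two at least 8x the signal length (sub-bpm peak resolution), and the power
spectral density's maximum in [0.7, 4.0] Hz times 60 is the heart rate. The
band restriction guarantees estimates never leave [42, 240] bpm. The
per-frame BPM *channel* is a sliding-window version of this estimator
(window 90 frames, stride 3, linearly interpolated to every frame and
edge-padded). Whether the original design used a constant-per-clip value or
a sliding trace is not documented anywhere; the sliding trace was chosen
because it preserves the channel's time alignment with the other four and
degrades gracefully to a constant for stationary pulses.

## Screening

Nine points on a 3 x 3 grid at 25/50/75% of the face box are tracked with
pyramidal Lucas–Kanade optical flow (3 levels, 15 px windows, iterative
refinement with bilinear subpixel sampling; a fast single-level path handles
the common sub-2 px case). The per-frame motion value is the mean Euclidean
displacement of the surviving points; lost points are dropped, and only the
loss of all nine aborts. The light value is `|Y_t - Y_{t-1}|` of the face
region's skin-mean luminance. Both traces are summarized by their video
mean.

Thresholds are calibrated on a genuine population as `mean + k sd` with
`k = 6` (degenerate zero thresholds are raised to a floor of 0.1). The rule
is a deliberate design choice: genuine and gross-motion attack distributions
are separated by an order of magnitude on this benchmark, so any k between
roughly 3 and 20 works; 6 sigma leaves the false-rejection probability of a
well-behaved genuine video negligible while keeping a wide margin below the
attack range. A video fails if either mean exceeds its threshold; equality
passes.

## Clips and classifiers

The 15 channels (3 regions x rPPG, BPM, Y', Cb, Cr) are cut into 90-frame
clips with stride 10 (`floor((T - 90)/10) + 1` clips for T frames) and each
clip channel is standardized to zero mean, unit variance (constant channels
map to zeros). Standardization removes device/brightness offsets and makes
channels commensurate; it is applied per clip so each sample is
self-contained. Splits are at the *video* level, stratified by class and
device profile, 5:1 train:test — clips of one video never cross the split,
which would otherwise leak nearly identical overlapping windows.

Three architectures are implemented in a compact, dependency-free neural
network core (im2col temporal convolutions, batch normalization, dropout,
LSTM with full backpropagation through time, Adam), all verified against
finite-difference gradients:

* **LSTM**: three stacked LSTM layers (width 32), last hidden state, a
  fully connected layer, dropout 0.5, sigmoid.
* **CNN**: five temporal-convolution stages (kernels 7,5,3,3,3; channels
  32,64,128,128,64) with batch norm and two time-halving max-poolings,
  global average pooling, dropout, sigmoid. The five-stage design follows
  the early-AlexNet intuition that a (90, 15) input is far too small for
  very deep stacks; the kernels are 1-D because the input is a short
  multichannel time series, not an image.
* **CRNN**: two convolution/pool stages feeding a two-layer LSTM.

`fusion = "per_signal_branches"` builds five parallel narrower branches, one
per signal type, each seeing that signal's three region channels (a 90 x 3
slice); their penultimate features are concatenated before the final layer.
This is the configuration that wins in the package's benchmarks, mirroring
the design in which each signal is learned separately and combined at the
last layer.

Training uses Adam (lr 1e-3), batch 64, binary cross-entropy, early stopping
on validation loss (patience 10 by default; the scripted experiments use 12
epochs with patience 4, which the learning curves show is already past
convergence on this benchmark). The seed fixes initialization, shuffling and
dropout, so two runs with the same seed produce bit-identical weights.
All default configurations stay under 5 million parameters and train on one
CPU core in minutes.

## Evaluation

Accuracy is reported in percent at threshold `tau = 0.5` (ties decide
"real", matching the predict contract). AUC is computed by the rank-based
pairwise estimator `P(s_pos > s_neg) + 0.5 P(tie)` and cross-checked to
1e-12 against an independently coded trapezoidal ROC integration (and
against `pROC` in the tests). Per-case tables group accuracy by attack kind
and device profile.

## Experiment sizes

The scripted experiments use desk-scale sizes chosen to exercise every claim
with comfortable statistical margins: 50 videos for heart-rate recovery
(acceptance test; 30 in `scripts/acceptance.R`), 20 + 20 + 3 x 20 videos for
screening (10s in the script), and a 60-video benchmark suite (3 classes x 2
device profiles x 10; 36 in the script) yielding ~1300 clips for
classification. The vignette states these sizes as the package's chosen
conditions; all are parameters of the exported runners and scale up
trivially.

## Known limitations

* The replay signature is an assumption (see above); a classifier trained on
  this benchmark learns *these* cues, not the cues of any particular real
  display/camera pair.
* The skin chroma band is a fixed heuristic; the synthetic face is built to
  satisfy it, so the mask's real-world failure modes (make-up, extreme
  illumination, diverse skin tones under unusual white balance) are out of
  scope here.
* The default detector/tracker adapters rely on the skin mask and are not
  meant for real footage; inject real implementations via `track_rois()`.
* Heart-rate variability, non-frontal pose, occlusions and 3D-mask attacks
  are not modeled.
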