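---
title: "Predicting farrowing onset from activity time series: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting farrowing onset from activity time series: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(farrowcast)
```

This vignette documents the models implemented in `farrowcast`, the
assumptions behind them, the tunable parameters that matter, and the design
decisions taken where several defensible options existed. It states no
empirical result beyond what the package's tests and `scripts/acceptance.R`
themselves compute.

## 1. From video to activity

Activity is quantified from dense optical flow between consecutive retained
frames. With per-pixel displacement components $(u_i, v_i)$ over $N$
pixels, the per-frame activity is the mean displacement magnitude

$$A = \frac{1}{N}\sum_{i=1}^{N}\sqrt{u_i^2 + v_i^2} \quad \text{(pixels/frame)},$$

and a 5-minute segment's activity is the sum $A' = \sum_t A_t$ over its
frames. The reference acquisition protocol keeps the 1st and 13th frame of
each second of 25-fps video (2 fps effective), so a 5-min segment holds 600
frames; `segment_activity()` accepts whatever frame count the extractor
produces, since flow between consecutive retained frames strictly yields
one fewer field than frames and the package does not silently resolve that
off-by-one. Activity series are min–max rescaled to $[0, 100]$.

**Normalization scope.** Whether the min–max reference is per sow or pooled
is genuinely ambiguous in practice, so both modes exist. The *model
pipeline* default is a pooled reference computed **from training sows only
and frozen**, with out-of-range values clipped to $[0, 100]$: a per-sow
reference maps each sow's baseline to a different normalized level (its
dynamic range differs), destroying cross-sow comparability of the very
level signal the regressor relies on, and any reference computed on
held-out sows would leak information. The subject split is therefore drawn
*before* preprocessing.

**Smoothing.** A centered moving average with edge truncation
(`smooth_series()`), default width 5 points (25 min). The width is a free
parameter; 5 points suppresses per-segment estimation noise while leaving
the 24-h rhythm and the pre-onset rise intact.

**Flow scoring.** `epe()` (mean per-pixel end-point error) and `fl_all()`
(percent of pixels with error above a threshold, 3 px by default) score
flow estimators against ground truth. Deep estimators such as RAFT are
external and plug in via `register_flow_backend()`; the built-in exhaustive
block-matching backend exists so the whole chain can be exercised against
synthetic frame pairs with known ground truth (`generate_flow_pair()`),
not as a production estimator.

## 2. Windowing and labels

Each activity point is stamped by its 5-min segment's **end**, so the final
point of a full 96-h pre-onset series sits exactly at onset and the final
window's label is 0 minutes. An alternative start-anchoring would shift all
labels by 5 min; end-anchoring gives the cleanest "remaining minutes"
semantics and is applied consistently. Windows of $w = 72$ points (6 h)
slide with step 1, giving $\lfloor (1152-72)/1 \rfloor + 1 = 1081$ windows
per sow; the window count formula is property-tested against brute-force
enumeration. Splits are strictly subject-level (12 train / 4 validation /
4 test sows, with 4-fold assignments over the 16 non-test sows), so no
window of a held-out sow can influence training.

## 3. CLA-PTNet

The regressor maps a 72-point window to the remaining minutes until onset
through three blocks:

* **CBE** — stacked 1-D convolutions (odd kernels, symmetric zero padding,
  hence length-preserving) with per-channel batch normalization and ELU.
  Defaults: two layers, 16 channels each, kernels 7 and 5.
* **LDE** — an LSTM over the feature sequence (hidden size $d = 32$, one
  layer by default), returning the full hidden-state sequence, followed by
  ELU and (training-mode only) inverted dropout at rate 0.1. Dropout sits
  after the ELU; the other order is a config flag away
  (`lstm_layers`, `dropout`).
* **PTW-SA** — the attention core. With hidden sequence $H \in
  \mathbb{R}^{t\times d}$ and a learnable positional matrix $P$ of the same
  shape, $H' = H + P$, $Q = H'W_Q$, $K = H'W_K$, $V = H'W_V$, each key row
  is rescaled by a learnable time weight, $K'_{i\cdot} = w_i K_{i\cdot}$,
  scores $QK'^T$ are divided by the scale and row-softmax-normalized, and
  the output is $O = WV$. With $P = 0$ and $w \equiv 1$ this reduces
  *exactly* to textbook scaled dot-product self-attention — the package's
  tests assert this against a brute-force double-loop oracle at $10^{-6}$.
* The $t \times d$ attention output is mean-pooled over time (last-row
  pooling by flag) and a linear head emits the prediction.

**Attention scale.** The natural reading of the scoring rule divides by
$\sqrt{d}$, the standard choice that keeps score variance independent of
$d$; dividing by $d$ itself is also seen in print and is available via
`attention_scale = "d"`. The default is $\sqrt{d}$.

**Implementation.** No deep-learning framework is used: forward passes,
analytic backpropagation and Adam are implemented in this package, with
the LSTM/attention/convolution inner loops in RcppArmadillo for speed. All
randomness (initialization, shuffling, dropout masks) is drawn on the R
side from a single seed, so training is bit-reproducible; compiled kernels
are purely deterministic arithmetic. Gradients of every parameter group are
verified against central finite differences in the test suite.

**Training protocol.** Adam (learning rate $2.5\times10^{-3}$, exponential
decay 0.96/epoch, batch 64, MSE on labels rescaled by the maximum training
label, 75 epochs). Early stopping on validation MAE is available
(`patience`) but off by default: with only four validation subjects the
epoch-to-epoch MAE is noisy enough that stopping decisions were effectively
random, while the decayed fixed schedule converges stably. Training and
validation windows are restricted to labels $\le 1440$ min and subsampled
at stride 2 (`train_max_label_min`, `train_step`): the activity ramp begins
about 24 h pre-onset, so windows further out contain no onset-anchored
signal, and the operational question is accuracy in the final day. Test
windows always keep the full horizon at stride 1, which is what makes the
far intervals of the report honest extrapolation tests.

**Evaluation.** `regression_metrics()` implements MAE, RMSE and
$R^2 = 1 - \sum(y_i-\hat y_i)^2/\sum(y_i-\bar y)^2$; $R^2$ may be negative
and is `NA` (with a warning, never silently 0) when all labels are equal.
`interval_report()` bins test predictions into 30–24, …, 6–0 h pre-onset
intervals. The headline comparison is against a predict-the-mean baseline
that answers the mean *training* label within the $\le 18$ h evaluation
range — the strongest constant predictor for that range.

## 4. The synthetic cohort

`sim_config()` defines the study conditions: 20 sows, 96 h at 5-min
resolution (1152 points). Each series is

$$\text{activity}(t) = \max\{0,\; b_i + D_i(t) + R_i(t) + B_i(t) + \varepsilon(t)\}$$

* $b_i$: baseline near 15 normalized units (between-sow SD 2).
* $D_i$: diurnal sinusoid, amplitude 6, period 288 points, **shared phase**
  across the cohort with per-sow jitter of SD 0.5 rad. Monitored batches
  farrow near-synchronously (induction is routine), so onset-anchored
  series share their day–night alignment; that alignment is what gives real
  cohorts their high cross-sow activity correlation, and it makes the
  diurnal position of a window genuinely informative about remaining time.
* $R_i$: a normalized sigmoid ramp over the final 288 points (midpoint
  0.65, steepness 7, magnitude 60): the trend is flat until ~24 h
  pre-onset, rises perceptibly from ~15 h, keeps rising until ~2 h before
  onset and flattens thereafter. Ramp start jitters between sows with SD 24
  points (~2 h), matching the spread of rise times across individuals.
* $B_i$: a per-sow AR(1) "bout" process (stationary SD 5, timescale 24
  points ≈ 2 h) — slow, autocorrelated fluctuations from feeding and
  posture changes. This is the *unshared* variance component; without it,
  synthetic cohorts correlate far more strongly than real ones.
* $\varepsilon$: white noise (SD 6), plus an extra SD-5 component over the
  final 288 points (the final-day dispersion burst).

These defaults were calibrated once, against the published descriptive
statistics of pre-farrowing activity — stable-day dispersion around 6–7
units, a final-day distribution with mean ≈ 37 / max ≈ 80 and strong right
skew, cohort mean pairwise correlation ≈ 0.85 — and are not tuned per
experiment. Determinism: per-sow streams derive from the master seed via a
multiplicative-hash XOR (`derive_seed()`), so cohorts are bit-identical
under a fixed seed and individual sows can be regenerated independently.

**What the generator does not emulate:** posture classes, dystocia or other
abnormal-labor dynamics, camera artifacts (occlusion, lighting), and any
coupling between litter size or parity and activity. Passing tests on this
cohort therefore demonstrate that the pipeline recovers remaining time when
the assumed activity signature holds, not that it will do so on any farm's
footage.

**Expected behavior of results.** Far from onset the windows carry no
onset-anchored information, so interval $R^2$ is strongly negative there
and rises toward onset, with the best bin at 6–0 h. Between the 18–12 h
and 12–6 h bins the improvement can fluctuate by a small amount: each bin
holds windows from only four test sows, and the 12–6 h windows face the
generator's hardest ambiguity (an early ramp looks locally like a bout
upswing). The acceptance suite asserts the improvement pattern up to a
0.25 allowance on adjacent-bin $R^2$ medians for exactly that reason.

## 5. Analysis tools

* `activity_pcc()` / `aacc()`: Pearson correlation matrix across sows and
  per-sow mean correlation with the others. The AACC denominator defaults
  to the off-diagonal count $N-1$ ("the other sows"); a literal-$N$ mode
  exists because both conventions circulate.
* `stl_trend()`: additive STL with periodic seasonal window; components
  reconstruct the input exactly, and only the trend is carried forward,
  isolating the pre-farrowing rise from the diurnal cycle.
* `daily_stats()`: per-day (288-point blocks counted back from onset)
  mean, min, max, quartiles (type-7 linear interpolation) and SD — the
  box-plot table format.
* `roi_calc()`: benefits $B_p = \Delta P \cdot V_p$ (stillbirth reduction)
  and $B_l = \Delta L \cdot W_l$ (labor savings); total cost combines
  equipment and operational cost by sum (default; the standard accounting
  reading) or product (a literal alternative seen in print), and
  $\mathrm{ROI} = (B_p + B_l - C)/C \times 100\%$.

## 6. Numerical choices and degenerate inputs

* Min–max normalization with a degenerate reference range errors unless
  `allow_constant = TRUE` (maps to 0); values outside a frozen reference
  clip to $[0, 100]$.
* Smoothing windows must be odd (centered); window 1 is the identity;
  edges truncate rather than pad.
* Softmax rows are max-shifted before exponentiation; attention row sums
  are asserted to 1 within $10^{-6}$.
* Batch-norm uses batch statistics in training and running statistics
  (momentum 0.1, $\varepsilon = 10^{-5}$) in evaluation, so evaluation-mode
  forward passes are deterministic.
* LSTM forget-gate biases initialize at $+1$; weights are Glorot-uniform;
  the positional matrix initializes near zero (SD 0.02) so attention starts
  close to its textbook reduction.
* $R^2$ with constant labels is `NA` with a warning, never silently 0.
* Problem sizes in the test suite: unit and property tests run on reduced
  cohorts (6 sows × 288 points) and tiny networks; the acceptance checks
  run the full study conditions (20 sows × 1152 points, three seeded
  replicates) — about 3.5 minutes per replicate on one CPU.

## 7. Known limitations

* The absolute scale of raw (pre-normalization) activity is arbitrary; the
  simulator works directly in normalized-like units and the pipeline's
  conclusions are scale-free by construction.
* The block-matching flow backend recovers integer displacements on
  interior blocks only; it is a test oracle, not a production estimator.
* Real-data performance claims are out of scope: no farm video ships with
  the package, and the synthetic cohort, however carefully calibrated,
  encodes the assumed activity signature rather than measured sow behavior.
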