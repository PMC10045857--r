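---
title: "Seizure recognition from EEG chunks with Extreme Learning Machines"
author: "elmeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure recognition from EEG chunks with Extreme Learning Machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmeeg)
```

## The problem and the data layout

Scalp EEG recorded from epilepsy patients and healthy controls is commonly
distributed, after preprocessing, as a flat table of one-second chunks: each
row holds 178 consecutive amplitude samples (ADC units, roughly −1415 to
2047) and a condition label in `{1..5}` — 1 = ictal (recorded during a
seizure), 2 = pre-ictal, 3 = inter-ictal, 4/5 = healthy with eyes
closed/open. Five hundred subjects × 23 chunks gives the canonical
11,500 × 178 table. The clinical task is binary: does a chunk show seizure
activity (label 1) or not (labels 2–5)? After binarization the data are
imbalanced, with prevalence 2300/11,500 = 0.2.

`elmeeg` implements this pipeline end to end: reading and writing the chunk
dialect (`read_eeg_csv()`, `write_eeg_csv()`), binarization
(`relabel_binary()`), unit-variance rescaling (`fit_rescaler()`),
stratified splitting (`split_dataset()`), the classifier, a feature-ranking
algorithm derived from the classifier's weights, the evaluation panel, and
an orchestrator (`run_experiment()`) for the canonical 80/20, 70/30 and
60/40 protocols.

## The classifier

The model is an Extreme Learning Machine: a single-hidden-layer feedforward
network

$$ f(x) = \sum_{j=1}^{L} \beta_j \, \sigma(w_j \cdot x + b_j) $$

whose input weights $w_j$ (drawn once, uniform on $[-1, 1]$) and biases
$b_j$ (uniform on $[0, 1]$) are **frozen**, and whose output weights
$\beta$ are obtained in closed form. Writing $H$ for the $n \times L$
hidden-layer output matrix $H_{rj} = \sigma(w_j \cdot x_r + b_j)$ and $Y$
for the encoded targets, training solves the least-squares problem
$\min_\beta \lVert H\beta - Y \rVert$ and takes the minimum-norm solution

$$ \beta = H^{+} Y, $$

with $H^{+}$ the Moore–Penrose pseudoinverse. There is no backpropagation
and no iteration; training is one linear solve, which is the method's
selling point for this task.

Assumptions worth stating: the random sigmoid layer is a generic nonlinear
feature map, so the method relies on the classes being separable in a
high-dimensional random-projection space, not on any EEG-specific feature
engineering; and the solve treats the 0/1 targets as regression targets,
so scores are not calibrated probabilities (they can leave $[0, 1]$).

### Target encoding and decision rule

Binary problems train one output column on 0/1 targets and label a row
positive when its score is at least 0.5 — the midpoint of the targets; the
boundary score itself counts as positive, a convention the tests pin down.
Multi-class problems (the pre-binarization five-condition view) use one-hot
columns and argmax, ties broken toward the lowest class index. The encoding
is the package's choice; nothing in the method constrains it.

### Numerical choices

* **Pseudoinverse.** `pinv_solve` uses the SVD of $H$ with a relative
  singular-value cutoff of $\max(n, L)\,\varepsilon$ (machine epsilon),
  the standard numerical-rank tolerance; it is configurable via
  `elm_config(pinv_rtol = )`. An optional ridge term exists
  (`ridge > 0` switches to regularized normal equations) but is off by
  default — the plain method has none.
* **Sigmoid.** Hidden activations use `stats::plogis`, which branches on
  the argument's sign internally, so $|w \cdot x + b|$ in the thousands
  saturates to 0/1 without overflow.
* **Zero-variance columns.** The rescaler drops constant training columns
  with a warning by default (`zero_variance = "error"` to refuse instead);
  a constant column carries no class information and would divide by zero.
* **Rescaling convention.** "Unit variance" uses the *population*
  denominator $n$, so a two-point column maps exactly to $\pm 1$; the
  sample convention is available (`variance = "sample"`). The rescaler is
  fitted on the training partition only and applied frozen to validation
  and test data, avoiding leakage.

### Hidden-layer size

Accuracy rises with $L$ until the model can express the decision boundary,
then flattens (and training cost grows as $O(nL^2)$). Two mechanisms are
provided:

* the default heuristic `default_n_hidden()` — one hidden neuron per ten
  training rows, which lands on $L = 920$, $805$ and $690$ for the
  9200-, 8050- and 6900-row training partitions of the canonical
  protocols; and
* `sweep_hidden_neurons()` — a validation sweep over a user grid, one
  fresh random layer per candidate (seeded deterministically from
  `(seed, L)` so sweeps are reproducible yet layers independent), returning
  the **smallest** $L$ attaining the best validation accuracy — the
  cheapest adequate model.

ELM as implemented has no pruning of hidden neurons; the fitted layer is
exactly the drawn layer.

## Connection-weight feature selection

Although $W$ is random, the learned $\beta$ encodes which hidden neurons
matter, and back-projecting $\beta$ through the (squashed) input weights
recovers, to first order, the learned discriminant direction in input
space. For feature $i$ and output node $k$:

* significance: $C_{ik} = \sum_{j=1}^{L} \beta_{jk} \tanh(W_{ji}/2)$
  (the $\tanh(x/2)$ form equals $(1-e^{-x})/(1+e^{-x})$ and is the
  numerically stable way to write it — the suite verifies agreement to
  $10^{-12}$);
* magnitude: $R_{ik} = \lvert\tanh(C_{ik}/2)\rvert \in [0, 1)$;
* influence share: $S_{ik} = R_{ik} / \sum_{i'} R_{i'k}$, so each output
  node's column sums to 1;
* feature weight: $\bar S_i = \frac{1}{K}\sum_k S_{ik}$.

The normalization in $S$ is computed on the non-negative $R$ values —
normalizing signed coefficients would let cancellation produce negative or
undefined "shares". Averaging $S$ over *features* instead of output nodes
would return the constant $1/m$ for every node and rank nothing; that
degenerate variant is kept available (`feature_weights(printed_form =
TRUE)`) purely so the difference can be audited.

Two selection policies are offered, neither privileged: `threshold-mean`
(parameter-free: keep features with at least the mean weight) and `top-k`.
Selection is a one-shot weight analysis — no wrapper-style refitting per
subset.

The canonical experiments run on all 178 features by default;
`experiment_config(feature_selection = TRUE)` inserts a select-and-retrain
step.

## The synthetic data generator

`generate_bonn_like()` reproduces the *shape* of the chunk table — 5
classes × 100 subjects × 23 chunks × 178 samples, clipped to
[−1415, 2047] and rounded to integers — with an invented signal model
chosen once:

| parameter | default | meaning |
|---|---|---|
| `ar_coef` | 1.2, −0.36 | stable AR(2) filter giving EEG-like temporal correlation |
| `class_scales` | 60, 55, 45, 30, 18 | innovation SD (ADC units) per class |
| `burst_amplitude` | 600 | peak of the ictal spike–wave component |
| `burst_freq` | 3 Hz | classic generalized spike–wave rate |

Class 1 (ictal) adds a random-phase 3 Hz spike–wave burst to its noise, so
its per-row variance exceeds the other classes' medians by an order of
magnitude (~17× at the defaults; the suite asserts ≥ 5×) — a caricature of
the high-amplitude rhythmic discharge of real ictal EEG. Under these
defaults the reference configuration (80/20 split, $L = 920$) tests at
≳ 99% accuracy and AUC ≈ 1.

What the generator does **not** emulate: electrode montage, 1/f spectra,
artifacts, inter-subject variability beyond independent draws, or any
overlap structure between the pre-ictal/inter-ictal/healthy classes.
Passing tests on this data therefore demonstrate that the pipeline's
machinery is correct and that the classifier solves a task of the right
shape and scale — not that it attains any particular accuracy on clinical
EEG. Results on the real UCI export will differ; the package reads it
directly (`read_eeg_csv()`) when the user supplies it.

`generate_separable()` is the oracle fixture: two unit-variance Gaussian
clouds `margin` apart along a random direction (`margin = 0` is an exact
null). In its planted-feature mode (`informative = k`) the separating
direction uses equal-magnitude random-sign components on the planted set.
This is deliberate: with a Gaussian direction, some nominally informative
features receive near-zero weight and are undetectable by *any* method (an
ordinary-least-squares coefficient oracle recovers only ~7.6 of 10 planted
features at $n = 1000$), so a recovery experiment would measure the
fixture, not the ranking algorithm. With equal-magnitude components, each
planted feature carries signal $\text{margin}/\sqrt{k}$ and the
connection-weight ranking recovers 10/10 across seeds at $n = 1000$,
margin 6, $L = 200$ — the scale the recovery tests use.

## Splitting protocol

`split_dataset()` assigns `round(train_frac * n)` rows to training and, by
default, halves the holdout into equal validation and test partitions —
the 80/20 protocol on 11,500 rows yields 9200/1150/1150 with test
prevalence exactly 0.2 under stratification (on by default; each class is
sampled proportionally with a largest-remainder correction so the training
size is exact). `halve_holdout = FALSE` gives a plain two-way split. An
optional `balance_train` mode duplicates minority training rows to a 50/50
training prevalence; it is off by default — oversampling changes the
training distribution and is reported prevalence 0.5, which is only
appropriate when explicitly requested.

## Evaluation

`confusion_binary()` + `classification_metrics()` produce the standard
panel. Recall and sensitivity are the same quantity for binary
classification; the report stores one value under both names rather than
letting them drift apart. Metrics with zero denominators are reported as 0
with the metric name in the `degenerate` field and a warning — sweeps over
many folds must not abort on a fold with, say, no predicted positives.

`roc_curve()` sweeps all distinct scores as thresholds with tied scores
grouped into one step; `roc_auc()` integrates by the trapezoid rule, which
under grouped ties equals the Mann–Whitney statistic with half-credit for
ties. `auc_rank()` computes the same quantity independently from midranks,
and the suite checks the two routes agree to $10^{-12}$ and match
`pROC::auc` on random instances. The identity
$\text{acc} = \pi\,\text{sens} + (1-\pi)\,\text{spec}$ (with $\pi$ the
prevalence) is property-tested exactly.

## Determinism and problem sizes

Every random stage — generator, splits, hidden layers, sweeps, baselines —
derives its stream from one master seed via a 32-bit multiplicative hash,
and restores the caller's RNG state afterwards. `write_report()` drops the
recorded wall-clock column by default, so a repeated run writes a
byte-identical report; timings stay available in the in-memory report
(`include_time = TRUE` keeps them in the file, at the cost of
reproducible bytes).

The test suite runs the full-scale reference configuration once
(11,500 × 178, $L = 920$) plus reduced tables (10 subjects per class,
1150 rows) for protocol and determinism checks, and $n \le 1000$ fixtures
for the solver, AUC and recovery oracles; the complete suite finishes in
well under a minute on a laptop-class CPU.

## Known limitations

* Scores are uncalibrated least-squares outputs; threshold 0.5 is the
  natural midpoint, not an optimized operating point.
* With $L$ approaching $n$, the interpolating solve can overfit; the
  heuristic $L = n/10$ and the validation sweep are the guardrails, and no
  automatic neuron pruning exists.
* The connection-weight ranking reflects the *fitted linear read-out*
  through a random nonlinear map; strongly redundant or nonlinearly
  relevant features can be ranked below their marginal usefulness.
* Baselines (`knn`, `nb`, `lr`, `dt`, `rf`, `ann`) are thin adapters over
  established implementations for side-by-side reporting only; a stochastic
  gradient-descent linear classifier and an LSTM are not provided.
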