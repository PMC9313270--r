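---
title: "Quantifying proteins from qPCR amplification curves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proteins from qPCR amplification curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakfluo)
```

## The assay in one paragraph

The package processes real-time PCR fluorescence from an aptamer–adaptor
displacement assay. Aptamer–adaptor complexes are pre-formed; the target
protein (the motivating application is salivary leptin) displaces complexes
in proportion to its concentration, and the *leftover* complexes are the
qPCR template. Concentration therefore maps *inversely* to template: a
0 ng/mL negative control retains maximal template and amplifies earliest,
and higher protein concentrations amplify later. Because of this inversion,
all the machinery of qPCR quantification (threshold cycles, standard
curves) applies with the sign of the slope flipped relative to ordinary
template dilution series.

## The PeakFluo statistic

For well $n$ with raw fluorescence $f_n(c)$ at cycle $c$:

1. **Background.** $B_n$ is estimated from the first 10 cycles of each well
   (default: the mean; the maximum is available via
   `peakfluo_params(background_mode = "max")`). Processing starts at cycle
   11 so the background window never overlaps processed cycles.
2. **Control subtraction.** The plate's replicate-averaged negative control
   $f_0$ carries the *process* fluorescence — noise introduced by the
   biochemistry itself, shared by all wells. The cleaned signal is
   $$\tilde f_n(c) = \bigl(f_n(c) - B_n\bigr) - \bigl(f_0(c) - B_0\bigr),
   \qquad c \ge 11 .$$
   Since the control amplifies first and all wells share a plateau,
   $\tilde f_n$ is approximately zero early, dips to a negative minimum
   while the control rises ahead of the sample, and returns toward zero at
   the common plateau.
3. **Early-stopping peak.** The *peak* is $|\min_c \tilde f_n(c)|$. Because
   the cleaned signal is convex-ish around its minimum, the minimum can be
   detected in a stream: maintain the running minimum and stop once
   `persistence` consecutive cycles exceed it (default 3). On an instrument
   this is the point where the run can be aborted — typically 10+ cycles
   before the programmed end. Ties keep the first occurrence, which stops
   earliest and is deterministic.
4. **Calibration.** The standards' peaks are regressed on
   $\log_{10}(\text{concentration})$; unknowns are quantified by inverting
   the fitted line in log space,
   $\hat{\text{conc}} = 10^{(\text{peak} - b)/m}$. With exactly two
   standards this is the two-point construction. The original pseudocode's
   raw-concentration arithmetic is retained as
   `quant_mode = "twopoint_raw"` for comparison, but note it is not a
   consistent inversion (a peak equal to standard 1's peak does not map
   back to standard 1's concentration), which is why the log-space
   inversion is the default.
5. **Validity gate.** A sample whose cleaned signal rises *above* the
   control before its peak indicates interference by leftover free
   sequences; the cartridge must be discarded. A cleaned trace is flagged
   when it exceeds `+validity_tolerance` (default 50 a.u., an order of
   magnitude above the cleaned-noise level at default noise settings) at
   any cycle up to its minimum. The minimum is located at its *last*
   occurrence: a purely positive excursion that returns to zero has its
   numerical minimum (~0) at both ends of the window, and anchoring at the
   last occurrence is what lets the rule catch that case in noise-free
   data.

### Sign convention

The running minimum is tracked on the *signed* cleaned signal and reported
as an absolute value. Comparing the signed signal against a stored absolute
peak (as a literal reading of the original pseudocode would) conflates the
two scales; tracking min-then-abs reproduces the intended "absolute value
of the global minimum".

### The persistence parameter

A streaming minimum detector that stops on the first non-improving cycle is
only safe for noise-free convex signals; a single noise upset would stop it
prematurely. `persistence = 3` requires three consecutive cycles above the
running minimum. At the simulator's default noise this keeps the streamed
peak equal to the full-trace global minimum in about 99% of wells
(exactly 100% in noise-free wells), at a cost of at most two extra cycles
before stopping.

## The amplification-curve simulator

No raw data from the motivating assay is deposited, so the simulator is the
package's stated world: every property test and acceptance criterion runs
against it.

### Curve family

A qPCR curve has four phases: flat background, exponential take-off, a
quasi-linear growth phase, and a plateau. We model the noise-free curve as

$$f(c) = B + d\,c + A\, g(c - c_{on}), \qquad
g(x) = \frac{s_k(x) - s_k(x - R)}{R}, \qquad
s_k(x) = k \log\bigl(1 + e^{x/k}\bigr),$$

a *smoothed trapezoidal ramp*: $g$ is 0 far below the onset, rises with
unit slope over $R$ = `ramp_cycles` cycles, and saturates at 1. The
smoothing scale is tied to the reaction efficiency, $k = 1/\log(1+E)$, so
the early tail grows by exactly $(1+E)$ per cycle — the exponential-phase
growth law $y_n = y_0 (1+E)^n$ — and the doubling law holds exactly: at
$E = 1$, halving the template delays every landmark of the curve by one
cycle.

A 4-parameter logistic was considered and rejected. For two logistics with
common plateau separated by an onset shift $\Delta$, the cleaned-signal
peak is $A \tanh(\Delta / 4k)$, and since $\Delta/k$ is independent of $E$
the peak *saturates* across a 2-decade concentration panel: analytically
the best achievable peak-vs-log-concentration linearity is marginal and
off-grid unknowns invert with errors up to ~0.1 log10. The observed assay
behaviour — near-perfectly linear peak-vs-log(conc) standard curves — is
the behaviour of curves that are, to good approximation, *translated
copies* over an extended quasi-linear phase, which the softplus ramp
provides (peak $\approx A\,\Delta/R$, linear in the onset shift). The ramp
is also the more faithful rendering of the four-phase description: a pure
logistic has no linear phase.

### Concentration → template → onset

Displacement is Langmuir-like with half-displacement constant $K_d$:
$y_0(\text{conc}) = y_{0,\text{ctrl}} / (1 + \text{conc}/K_d)$, floored at
one copy. The onset is where exponential growth reaches the optical
detection threshold $T$: $c_{on} = \log(T/y_0)/\log(1+E)$. For
$\text{conc} \gg K_d$ the onset shift is linear in
$\log(\text{conc})$ — the classic linear standard curve.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `n_cycles` | 40 | conventional qPCR run length; exceeds the ~35-cycle early-stop point |
| `baseline_level` / `plateau_level` | 100 / 1100 a.u. | arbitrary instrument units; amplitude 1000 |
| `baseline_drift` | 0.2 a.u./cycle | mild photobleaching/lamp drift |
| `efficiency_E` | 0.9 | typical good qPCR efficiency (90%) |
| `y0_control`, `detection_threshold_copies` | 1e4, 1e8 | control onset ≈ cycle 14, panel onsets 14–24 |
| `displacement_Kd` | 0.02 ng/mL | below the assay's 0.1 ng/mL detection limit, so the whole validated 0.1–10 ng/mL range sits in the log-responsive regime of the displacement curve — consistent with the linear standard curves the assay reports |
| `ramp_cycles` | 14 | linear phase long enough that the largest panel onset shift (~10.8 cycles) stays inside it, keeping peak vs log(conc) linear |
| `noise_sd_well` | 5 a.u. | 0.5% of amplitude; photodiode/LED reader noise |
| `noise_sd_process` | 2 a.u./cycle step | shared random walk; the component control subtraction removes |

These were frozen from a forward design analysis before any test was
written and are not tuned to test outcomes.

### Noise structure

Process noise is one Gaussian random walk per plate added to *every* well —
the "process fluorescence" that negative-control subtraction cancels
exactly. Per-well reader noise is iid Gaussian — the component replicate
averaging shrinks by $\sqrt{n}$. Replicates are averaged on *raw*
fluorescence before cleaning.

### What the simulator does not emulate

Melting curves, multiplexing, per-well efficiency variation, plateau
heterogeneity, pipetting/volume errors, inter-day chemistry drift, and the
optics of any real instrument. Consequently a green test establishes that
the algorithms are correct *for the stated statistical structure*; it does
not reproduce the R² values the original assay reports on its own
(undeposited) data, and no test here claims to.

## Classical threshold-cycle estimators

For comparison, the package implements the surveyed Ct estimators, all
derived from a fitted 4-parameter logistic
$F(c) = F_b + F_\max \,\sigma((c - c_{half})/k)$ rather than raw finite
differences (which amplify noise):

* **Scaled threshold**: cycle where the curve scaled to [0,1] crosses a
  fraction (default 0.1); at 0.5 it equals $c_{half}$ exactly.
* **Derivative maxima**: $d1_{max} = c_{half}$,
  $d2_{max} = c_{half} - k\log(2+\sqrt3)$; located on a dense grid of the
  fitted model.
* **Cy0**: intersection of the inflection tangent with the cycle axis,
  $c_{half} - 2k$ for the logistic; scale-invariant.
* **F0 back-projection**: logistic fitted on cycles up to a cutoff,
  evaluated (baseline-subtracted) at cycle 0. F0 is template-proportional
  only when the cutoff sits in the exponential phase and the baseline is
  drift-free; an uncorrected linear drift biases the back-projection
  severely. This is a property of the method, not of the implementation,
  and it is documented and tested.

Fit initialization: $F_b$ = minimum, $F_\max$ = range, $c_{half}$ = first
half-range crossing, $k = 2$; bounded `nls(port)` with an `optim`
(L-BFGS-B) fallback. A trace without dynamic range refuses to fit.

`compare_methods()` runs PeakFluo and the Ct estimators on the same plate
and tabulates standard-curve R² — the comparison design used to benchmark
the algorithm against commercial Ct software.

## The high/low classifier

Beyond quantification, amplification curves can be classified directly:
curves are rasterized and a small CNN labels them *high* or *low* around
the clinically meaningful 5 ng/mL leptin threshold (leptin-deficient
obesity presents below ~5 ng/mL).

Design choices, all of which were open:

* **Rendering**: 32×32 grayscale line plots, no axes or ticks. Axes limits
  are fixed *per dataset* (`axes_for_traces()`), so per-well scale cannot
  leak calibration into the classifier; a global multiplicative rescale of
  all traces leaves the images bit-identical when the axes follow the
  data. 32×32 (rather than a larger raster) keeps a pure-R convolution
  engine fast enough for two full 10-fold cross-validations on one CPU;
  a 40-cycle curve keeps its geometry at that resolution.
* **Network**: the six-layer stack conv(16, 3×3, ReLU) → maxpool(2×2) →
  conv(32, 3×3, ReLU) → maxpool(2×2) → flatten → dense(1, sigmoid);
  binary cross-entropy, Adam (1e-3), minibatch 32, ≤ 12 epochs with an
  early stop when training loss falls below 0.02. No deep-learning
  backend exists in the target environment, so convolution, pooling,
  backpropagation and Adam are implemented natively (im2col + BLAS matrix
  multiplication); the backward pass is verified against numerical
  gradients in the test suite.
* **Corpus**: the validation corpus is emulated with 278 curves, 201 high
  and 77 low. The underlying panel concentrations {0.1, 1, 10} ng/mL
  contain only one value above 5 ng/mL, so the generator draws
  concentrations log-uniformly from [0.1, 1] (low) and [8, 12] (high)
  ng/mL to give the corpus realistic within-class variation.
* **Validation**: stratified k-fold cross-validation (default 10). Fold
  assignment shuffles within class and deals round-robin, rotating the
  dealing start between classes so fold sizes stay within one of each
  other while each fold's class counts match the global ratio within one
  sample. Class imbalance is handled by stratification only, as in the
  source design. A permutation control (labels shuffled) collapses mean
  accuracy to the majority-class fraction (201/278 ≈ 0.72), confirming
  the accuracy on intact labels is signal, not imbalance.
* **Threshold ties**: a concentration exactly at 5 ng/mL is labeled low
  and reported via a message; the panel never hits the threshold exactly.

## Determinism

Every stochastic operation draws from a private RNG stream seeded from a
single user-facing seed via an FNV-1a–based splitter
(`peakfluo:::derive_seed`), and restores the caller's RNG state. Identical
configuration + seed give byte-identical plate CSVs and results JSON;
every results report embeds the package version and a hash of the full
configuration.

## Numerical and degenerate-input choices

* Background window must end before the first processed cycle (enforced).
* Peak ties: first occurrence; a tie with the running minimum neither
  updates the minimum nor counts as a rising cycle.
* Standard curves need ≥ 2 distinct positive concentrations; R² is
  reported only from 3 points; slopes below 1e-8 a.u./decade are treated
  as flat and refuse to quantify (a pure-baseline plate errors rather than
  returning arbitrary concentrations).
* An assay flagged invalid withholds all concentrations.
* Plate CSVs round-trip at 6 significant digits; re-writing a read plate
  is byte-identical.

## Known limitations

* The simulator's common-plateau assumption is favourable to the peak
  statistic; real plates show plateau dispersion that would add variance
  the tests do not see.
* The F0 estimator requires a drift-corrected baseline (see above).
* The CNN is validated only on simulated corpora; nothing here speaks to
  clinical samples.
* The early-stop economy claim (stopping "around cycle 35" on the original
  chemistry) depends on that chemistry's onsets; here stopping cycles are
  a consequence of the simulator's parameters (high 20s to low 30s at the
  defaults) and the specific cycle number is not asserted.
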