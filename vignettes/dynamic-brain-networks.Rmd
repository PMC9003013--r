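---
title: "Static and dynamic EEG connectivity networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic EEG connectivity networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

## The problem

Two groups of people — here labeled `PC` (controls) and `PE` (patients) — are
recorded with multichannel scalp EEG. The working hypothesis is that the
*functional coupling structure* between channels differs between groups, and
that its *temporal dynamics* carry additional discriminative information that
a single whole-record ("static") network discards. `dynconn` implements the
full chain needed to test that hypothesis:

1. preprocess (down-sample to a common analysis rate, zero-phase band-pass
   into standard EEG bands);
2. estimate pairwise coupling between all channel pairs with one of four
   estimators (MSC, iCOH, PLI, |r|);
3. threshold the weighted network by a connectivity-preserving edge-removal
   rule;
4. extract five topological features per network — and, in the dynamic
   variant, their mean/SD/median/IQR over 3 s sliding windows;
5. screen features univariately, optionally compress with PCA, and evaluate
   six classifier families under leave-one-out cross-validation (LOOCV).

## Connectivity estimators

For channels $x(t)$, $y(t)$:

* **MSC** (magnitude-squared coherence): with cross- and auto-spectra
  $S_{xy}(f)$, $S_{xx}(f)$, $S_{yy}(f)$, the coherency is
  $K_{xy}(f) = S_{xy}/\sqrt{S_{xx}S_{yy}}$ and $\mathrm{MSC}(f) = |K_{xy}(f)|^2$.
  The reported weight is the unweighted mean of $|K|^2$ over the in-band
  frequency bins.
* **iCOH**: the mean over in-band bins of $|\mathrm{Im}\,K_{xy}(f)|$.
  Instantaneously mixed (zero-lag) signals have purely real coherency, so
  iCOH nulls out volume conduction by construction.
* **PLI** (phase lag index): instantaneous phases $\phi_x(t),\phi_y(t)$ from
  the analytic signal; $\Delta\phi(t)$ wrapped to $(-\pi,\pi]$; and
  $\mathrm{PLI} = |\langle \mathrm{sign}\,\Delta\phi(t)\rangle_t|$. PLI is 0
  for zero-lag coupling and 1 for complete locking at a consistent nonzero
  lag. Note that taking the *absolute* phase difference before the sign
  (as some write-ups do) would make the sign nonnegative everywhere and the
  index degenerate; `dynconn` uses the standard signed-difference form.
* **CORR**: $|r|$, the absolute Pearson correlation.

All weights are nonnegative (iCOH and CORR take absolute values — network
edge weights must be), lie in $[0,1]$, and are assembled into symmetric
zero-diagonal channel x channel matrices.

**Spectral estimation.** MSC/iCOH use Welch averaged periodograms with 1 s
Hann segments at 50% overlap. Inside a 3 s sliding window that yields 5
segments at 1 Hz resolution — short enough to be usable per window, long
enough that the coherence estimator's bias ($\approx$ 1/segments for
independent signals) stays well below the coupling effects of interest at
the full-record scale. The estimator is assembled directly from FFTs so the
test suite can pin it against a naive per-segment DFT oracle.

**PLI edge handling.** The analytic signal is distorted near record
boundaries; the first and last 10% of samples are discarded before
averaging the phase-difference signs. This matters most in 3 s windows.

## Preprocessing

* **Resampling** is Fourier-domain truncation of the spectrum at the new
  Nyquist bin: zero-phase and exact for band-limited content. Only
  down-sampling (e.g. 500 Hz to the 100 Hz analysis rate) is supported.
* **Band-pass** is a linear-phase (symmetric) Hamming-window FIR applied
  with exact group-delay compensation, so *no inter-channel phase shift* is
  introduced — the phase-based estimators depend on this. A forward-backward
  pass would also be zero-phase but squares the magnitude response; the
  single compensated pass keeps the designed response as-is. The transition
  bandwidth is 25% of the lower band edge, with the kernel capped at one
  third of the signal length (relevant only for very short inputs); long
  kernels are applied by FFT convolution. Filters are designed per band from
  the six standard bands: Delta 0.5-4, Theta 4-8, Alpha-1 8-10, Alpha-2
  10-12, Beta 12-30, Full 0.5-45 Hz.
* **Segmenting** long records into >= 100 s fragments enlarges the sample at
  the cost of within-subject correlation; a trailing remainder is folded
  into the final fragment rather than discarded, and sub-threshold records
  pass through whole with a warning (permissive plumbing; real cohorts
  satisfy the bound). `cv_unit = "subject"` exists precisely because
  fragment-level LOOCV leaks subject identity; the default `"sample"`
  replicates the common practice of treating fragments as samples.

## Thresholding: the connectivity-preserving rule

Weak edges are noise-dominated, but a fixed universal cutoff is arbitrary.
Instead, the group-average network (over participants for static networks;
over participants *and* windows for dynamic ones) is thresholded on a 1%
grid: edges are sorted ascending by weight and the lowest $\lfloor p\cdot
E\rfloor$ removed for $p = 0, 0.01, \dots$; the *disconnection point* is the
smallest $p$ that disconnects the graph. The applied proportion is one grid
notch below the smaller of the two groups' disconnection points, and that
single proportion is applied to every individual (and every window) network.
For example, with group disconnection points at 65% and 82%, 64% of each
network's edges are removed. Ties at the removal boundary are broken by the
lexicographic node-index pair, making removal deterministic; rounding is
$\lfloor\cdot\rfloor$. Individual networks may still disconnect — only the
group averages are protected — so the metrics handle components explicitly.

## Topological features

Five features per network, deliberately using mixed conventions (the
long-standing defaults of igraph-style graph analysis, which also make a
diameter *smaller* than the average path length possible — the pattern seen
in thresholded coupling networks where surviving weights are large but used
as lengths):

* average **vertex strength**: mean over nodes of summed incident weights;
* average **path length**: mean *unweighted hop* distance over connected
  pairs;
* **diameter**: maximum *weighted* shortest-path length, edge weight as
  length;
* **transitivity**: binary triangle density, $3\times$triangles/triples;
* **small-world index** $S = (C/C_{rand})/(L/L_{rand})$, with $C_{rand}$,
  $L_{rand}$ averaged over `n_random` (default 20) Erdős–Rényi $G(n,m)$
  graphs matched on node and edge counts. $S>1$ reads as small-world
  organization. The reference is an average rather than a single draw to
  tame Monte-Carlo noise; per-window seeds are derived from the base seed
  and window index so series are reproducible.

Disconnected graphs: path-based metrics use the largest connected component
(with a warning in direct calls; silently counted in pipeline outputs via
the per-window component counts), strength and transitivity use the whole
graph.

## Dynamic features

A 3 s window sliding in 1 s steps (2/3 overlap) yields
$\lfloor(T-3)/1\rfloor+1$ snapshots; each snapshot's thresholded network
contributes the five features, forming five time series summarized by mean,
sample SD ($n-1$), median and IQR (type-7 linear-interpolation quantiles) —
20 features per record, named `{stat}_{feature}`. The window width trades
noise (shorter) against temporal smearing (longer); 3 s/1 s is the package
default and the only configuration exercised by the shipped experiments.

## Selection, PCA, classification

Features are screened univariately: Shapiro–Wilk normality at 0.05 in both
groups decides between Welch's t-test and the Wilcoxon rank-sum test;
features with $p > \alpha$ (default 0.05) are dropped. No multiplicity
correction is applied by default (the screen is a filter, not an inference;
a Benjamini–Hochberg flag exists). With very small groups the screen is
conservative by construction — e.g. at $n=3$ vs 3 the most extreme rank-sum
two-sided $p$ is exactly 0.1, so *nothing* can pass $\alpha=0.05$; the
pipeline then falls back to the single smallest-$p$ feature so downstream
models remain defined, and logs that it did so.

PCA (on standardized features, components up to 85% cumulative variance as
an automated scree stand-in) is fit *inside each training fold* by default —
fitting it once globally before LOOCV leaks the held-out sample into the
projection. Both variants are run and, per model, the better accuracy and
better AUC are retained, flagged with which variant produced them.

Six classifier families run with their implementations' defaults: logistic
regression (`glm`), decision tree (`rpart`), SVM (`e1071`, RBF), random
forest (`randomForest`, 500 trees), naive Bayes (`e1071`), and a
single-hidden-layer back-propagation network (`nnet`, 5 hidden units — the
one parameter `nnet` does not default). Scaling is fit per training fold.
Accuracy is the fraction of correct held-out predictions; AUC comes from the
pooled held-out scores (probabilities, or SVM margins), with the usual
rank-based tie handling, so a constant score gives 0.5.

## The synthetic cohort generator

No public EEG cohort accompanies this design, so the generator produces the
study conditions directly: two groups whose *inter-channel phase-coupling
strength* differs. Each channel is

$$s_i(t) = g_i\,[\kappa\,c_i(t) + (1-\kappa)\,o_i(t)] + \sigma\,w_i(t)$$

with $c_i$ a shared narrow-band (center $\pm$ 2 Hz) Gaussian oscillation
advanced by a fixed per-channel phase offset in $(0,\pi/4]$, $o_i$
independent oscillations of the same band, and $w_i$ white (optionally
pink) noise. The phase offsets are essential: with zero-lag mixing, iCOH
and PLI are blind to the shared source by construction. Defaults, chosen
once as a realistic regime: 20 `PC` / 16 `PE` records, 19 channels, 100 s
at 100 Hz, $\kappa_{PC}=0.3$, $\kappa_{PE}=0.5$, 10 Hz center (alpha, the
dominant resting rhythm), $\sigma=1$ (broadband background comparable to
the rhythm), gains $U(0.9, 1.1)$.

What the generator does **not** emulate: seizure morphology, artifacts
(blinks, EMG), nonstationary coupling within a record, 1/f spectral shape
(unless `pink = TRUE`), or volume-conduction mixing matrices. Passing tests
therefore demonstrate that the pipeline *detects controlled coupling
contrasts and respects its own contracts* — ordinal claims (dynamic vs
static, estimator rankings) — not clinical performance on real EEG.

## Numerical choices and degenerate inputs

* Seeds fan out deterministically (`base -> record -> window/fold`) through
  a fixed integer map, so every cohort, series, and CV run is bit
  reproducible; all derived seeds stay below $2^{31}$.
* Coherency denominators are floored at the smallest positive double;
  weights are clamped to $[0,1]$ against rounding.
* Constant features get $p=1$ (warning) in the screen; constant columns are
  dropped before PCA; zero-variance scaling divisors are replaced by 1.
* An empty graph has strength 0, transitivity 0, diameter 0, and undefined
  (NaN) path length; graphs with no triples have transitivity 0.
* A group-average network disconnected before any removal is an error — the
  threshold rule is undefined there.

## Problem sizes in the shipped experiments

The packaged tests and the acceptance script run the full pipeline on the
default synthetic cohort (36 records of 100 s at 100 Hz, full band, MSC and
iCOH, static and dynamic) plus a matched null cohort
($\kappa_{PE}=\kappa_{PC}$), and the selection-calibration study on 40
small null cohorts (8+8 records, 10 channels, 30 s, CORR). These sizes keep
a complete run in the tens of minutes on a single core while leaving the
Monte-Carlo assertions (binomial chance band, ~5% null retention) with
usable resolution.

## Known limitations

* The EDF writer emits the 16-bit flavor only (no EDF+ annotations), one
  data record per second, and requires integer sampling rates.
* ICA artifact removal is not implemented; a pre-cleaned input is assumed
  (an external cleaning step can be applied before `read_recording`).
* No re-referencing or bad-channel handling: inputs are taken as referenced.
* Directed/causal measures and multitaper spectra are out of scope.
* Fragment-level LOOCV (the default, for comparability) optimistically
  biases accuracy when fragments share subjects; use `cv_unit = "subject"`
  for honest generalization estimates.
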