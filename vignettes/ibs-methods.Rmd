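---
title: "Speaker-listener brain synchrony: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speaker-listener brain synchrony: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ibsync)
```

## The scientific problem

When one person tells a story and another listens, their band-limited EEG
rhythms can phase-lock across brains. `ibsync` implements the full analysis
chain for such pseudo-hyperscanning designs — speaker and listener recorded
in separate sessions, aligned post hoc at stimulus onset — and a synthetic
dyad generator with analytically known coupling, so that every stage of the
chain can be validated against ground truth.

The pipeline mirrors a two-group design: dyads share either a happy or a sad
story, each group also hears a neutral story that serves as its own
baseline, and the quantities of interest are emotion-minus-neutral
contrasts of inter-brain synchrony per scalp region, their group
difference, directional speaker-to-listener information flow, and whether
dyad-level synchrony predicts a self-reported closeness rating.

## The synchrony statistic

For phases $\varphi_i(t)$, $\varphi_k(t)$ of speaker channel $i$ and
listener channel $k$, the phase-locking value is

$$\mathrm{PLV}_{i,k} \;=\; \frac{1}{N}\left|\sum_{t=1}^{N}
  e^{\,j(\varphi_i(t) - \varphi_k(t))}\right|,$$

the modulus of the mean unit phasor of the phase difference: 1 under
perfect locking, and decaying to 0 at rate $N^{-1/2}$ for independent
phases. Because the defining sum carries a single index, two averaging
conventions are defensible for epoched continuous listening data:

* **within-epoch** (default): the sum runs over time samples inside each
  1000 ms epoch and the per-epoch values are averaged over retained epochs —
  the standard convention for continuous-listening data; and
* **across-epoch** (`mode = "across_epoch"` in `plv_matrix()`): the sum runs
  across epochs at a fixed latency, averaged over latencies — the
  event-locked convention.

Both are implemented; all shipped analyses use the within-epoch default.
Regional synchrony is the mean of the PLV matrix over all speaker-channel
by listener-channel pairs whose labels both lie in the region
(homologous-pair-only averaging is available via `homologous_only`).

## The coupling model of the generator

The generator realizes coupling as a von Mises phase difference on a shared
narrowband carrier: for each coupled channel pair the listener's phase is
the speaker's carrier phase minus an i.i.d. draw from a von Mises
distribution with concentration $\kappa$. This choice is deliberate: the
population PLV then has the closed form

$$\mathrm{PLV}(\kappa) = \frac{I_1(\kappa)}{I_0(\kappa)},$$

the modified-Bessel ratio, so the whole estimation chain has an analytic
calibration curve ($\kappa = 0$: uniform phase difference, PLV 0;
$\kappa = 2$: PLV $\approx 0.698$; $\kappa \to \infty$: PLV $\to 1$).
`kappa_from_plv()` inverts the curve, which is how cohort-level PLV targets
(e.g. a frontal emotion-minus-neutral contrast of $0.32 \pm 0.10$ vs
$0.21 \pm 0.09$ across groups) are translated into per-dyad concentrations.

**What the waveform path can and cannot calibrate.** Each generated dyad
carries both waveform channels (carrier plus 1/f-shaped 1-45 Hz background
noise, in microvolts) and the exact ground-truth phase series
(`dyad_true_phases()`). The Bessel-ratio calibration is checked on the
ground-truth phases, not on phases re-extracted through the narrowband
filter, for a structural reason: within-epoch PLV over time samples
converges to the population value only when per-sample phase differences
are nearly independent, and band-limiting to 4-7 Hz at 250 Hz makes
neighboring samples strongly dependent. Concretely, the estimator's
expectation is approximately $\sqrt{R^2 + (1 - R^2)/N_\mathrm{eff}}$ with
$N_\mathrm{eff}$ of the order of the time-bandwidth product (3-6 per
second), so a filtered null pair sits near 0.5 rather than near 0 — a known
property of windowed PLV on narrowband signals, not an implementation
artifact. The waveform path is therefore validated for what it honestly
supports: the preprocessing contracts (attenuation, re-referencing,
decimation arithmetic, rejection calibration) and strict monotonicity of
recovered PLV in $\kappa$, while distributional calibration and cohort
statistics run on generated phase series. Group comparisons on the waveform
path remain valid (the bias is common to both groups) but regional means are
compressed toward the filtered-null level.

## Preprocessing

The chain is fixed and logged in this order: 1-45 Hz band-pass, 50 Hz
notch, re-reference to the mastoid average, downsample to 250 Hz, cut into
consecutive 1000 ms epochs, reject any epoch whose peak absolute amplitude
exceeds 75 microvolts on any channel. All filters are zero-phase
(forward-backward fourth-order Butterworth band-pass; second-order
band-stop), because group delay would corrupt phase differences. A long
finite-impulse-response design would also be zero-phase, but a 1 Hz edge at
1000 Hz sampling needs thousands of taps; the forward-backward IIR meets
every attenuation contract (verified in the test suite) at a fraction of
the cost. Two numerical details matter:

* `signal::filtfilt` starts its recursions from zero state, which leaks
  start-up transients. The package pads with mirror (even) reflection for
  pass filters and point-symmetric (odd) reflection for stop filters; each
  choice avoids the continuation whose spectral content the filter would
  pass (a DC pedestal through a low high-pass edge; a broadband cusp
  through a narrow stop band).
* Phase extraction trims 100 ms per epoch edge from the phase-locking sums
  (`edge_ms`), suppressing the per-epoch filter transients.

Ocular-artifact decomposition (ICA) is intentionally not reimplemented: it
is a standard published preprocessing tool, and the pipeline exposes a
`clean_hook` in `preprocess()` where externally cleaned data can be
inserted. The synthetic data carry no ocular artifacts; the optional
artifact injector produces rectangular supra-threshold excursions that
exercise the amplitude-rejection rule instead. Rejection is epoch-wise
across channels jointly (any channel exceeding the threshold rejects the
epoch), and epochs are anchored at the first sample of the task recording.
"Hilbert wavelet" phrasing in the field conflates two methods, so both are
offered: zero-phase band-pass plus analytic-signal angle (default) and a
complex Morlet wavelet mode (`method = "morlet"`).

## Group statistics

All two-group tests are Student (pooled-variance) t tests with
$df = n_1 + n_2 - 2$ and Cohen's d on the pooled SD — the variant consistent
with published regional tables whose df equals $15 + 17 - 2 = 30$.
`ttest_from_summary()` reproduces the test exactly from printed
mean/SD/n triplets; on the reference table it recovers the frontal row as
$t(30) = 3.28$, $d = 1.16$ against printed values 3.22 and 1.14 — the
residual is the two-decimal rounding of the printed summaries. (The
occipital row of that table is not internally consistent — its printed t is
not recoverable from its own summaries — and is excluded from numeric
checks.) Multiple-comparison correction defaults to Benjamini-Hochberg FDR
across the six regional tests, with Bonferroni available; the reference
analysis states Bonferroni in its methods but FDR in its results table, and
the package surfaces the chosen method in its run log. Moderation is
reported as unstandardized per-group OLS slopes with their standard errors;
published moderation coefficients of this design mix standardized and
unstandardized quantities inconsistently (beta/SE does not reproduce the
printed t), so no numeric target is asserted for them.

## Directional coupling

Granger causality is computed in the time domain as
$F_{x \to y} = \ln(\mathrm{RSS}_\mathrm{reduced} / \mathrm{RSS}_\mathrm{full})$
from least-squares VAR fits, after z-scoring each task series against the
mean and SD of that participant's resting segment and demeaning. The model
order is selected by information criterion (AIC default, BIC available) on
a jointly fitted bivariate VAR over a common effective sample. Which
channels enter the analysis is not fixed by convention; the package's
default is the ROI-mean broadband signal (frontal by default,
configurable via `roi_signal()`), and this setting is written to the run
log. A full multivariate conditional analysis over all 64 channels is out
of scope at 32-dyad scale — with 64 channels and realistic model orders the
regression dimension exceeds the sample size — so the pairwise reduction is
the supported estimator. The generator's VAR dyads make the estimator
testable: with white-noise $x$ and $y_t = c\,x_{t-1} + \varepsilon_t$, the
population statistic is exactly $\ln(1 + c^2\,\mathrm{var}(x))$. Note the
finite-sample property that the null-direction statistic has a positive
$O(p/n)$ bias (it is a log ratio of nested RSS), so group-level inference on
the *null* direction will eventually reject at large n; directional claims
rest on the forward-backward comparison and on the forward statistic's
magnitude.

## Closeness prediction

`fit_predict()` implements epsilon-SVR with an RBF kernel
($\varepsilon = 0.01$, the libsvm implementation via e1071), features being
the dyad-by-electrode-pair table of theta-band emotion-minus-neutral PLV. The
protocol is: seed-deterministic 70/30 split (stratified by group so both
groups appear on each side — the reference protocol draws the split
unstratified, which can place all test dyads in one group at these sample
sizes); grid search over $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$ in
powers of 4 by five-fold cross-validation on training rows only; refit on
the full training set; Pearson r between actual and predicted on the
held-out 30%. Feature standardization is fit on training rows only.
Significance uses label permutations: labels are shuffled across the whole
cohort before splitting, the full split/CV/fit pipeline is re-run per
permutation, and $p = (1 + \#\{r_\mathrm{perm} \ge r_\mathrm{obs}\}) /
(1 + B)$ — one-sided, with the add-one correction so p is never exactly 0.
Whether the original protocol re-drew the split per permutation is not
determinable; re-drawing is the conservative reading implemented here.
Published held-out accuracies near 0.98 on real 32-dyad data are not
reproducible without that data; the package's claims are calibration ones —
uniform permutation p under the null, and reliable detection when labels
are constructed as a noisy linear function of the frontal contrast.

## Synthetic cohort: the study conditions

`cohort_spec()` defaults encode the two-group design: 15 happy and 17 sad
dyads; per-region theta-band delta-PLV targets equal to the six regional
group means/SDs of the reference summary table; a per-dyad neutral-condition
PLV level of $0.30 \pm 0.05$ (a mid-range value chosen once so that even the
largest regional contrast keeps the emotion-condition PLV inside $(0,1)$);
carrier 5.5 Hz (theta mid-band); 240 one-second epochs per condition (a
4-minute story); and behavioral distributions chosen to match the reported
effect sizes — recall-quality delta $8.0 \pm 3.5$ vs $3.0 \pm 3.4$
($d = 1.45$) and IOS closeness $5.4 \pm 1.1$ vs $4.3 \pm 1.2$
($d \approx 0.95$) on the 1-7 pictorial scale (IOS draws are clipped to the
scale; recall scores are left unclipped so the delta identity holds
exactly). Behavioral draws are independent of the neural draws by default;
analyses that need a real neural-behavioral association (the prediction
stage) construct labels from the frontal contrast explicitly. Within a
condition the coupling is stationary; temporal nonstationarity of real
narration is not modeled, so passing tests demonstrate estimator
correctness under stationary coupling, not robustness to drift.

## Problem sizes used by the shipped tests and scripts

Simulation-heavy checks scale the per-dyad data down while keeping
replicate counts at their stated values: cohort power uses 100 replicate
cohorts of 32 dyads with one coupled channel per region, 24 epochs of 50
phase samples (per-dyad estimation noise ~0.02, negligible against the
0.09-0.10 between-dyad SDs); type-I control uses 400 single-region
replicates; direction recovery uses 1000 VAR dyads at n = 5000; permutation
calibration uses 200 replicates of 200 permutations with a single grid
point (hyperparameter search is irrelevant under the null), and signal
recovery 40 replicates of 99 permutations on a 2-by-2 grid. The analysis
scripts use 60 epochs of 200 samples with two channels per region. A
design-level caveat recorded here once: the frontal contrast's true power
under BH correction across the six regional tests, at the reference effect
sizes and n = 15/17, is approximately 0.76 — detection of the frontal effect
in a single 32-dyad cohort is expected but not guaranteed, which is the
main reason replicate cohorts are used throughout.

## Known limitations

* EDF I/O is not provided; recordings interchange as TSV matrices with a
  JSON sidecar (`write_recording()` / `read_recording()`), with channel
  labels normalized to canonical 10-10 spellings on read.
* Rational (non-integer factor) resampling is not supported.
* Waveform-path regional PLV levels are compressed toward the filtered-null
  level (see the coupling-model section); use the phase-level cohort for
  distributional calibration.
* No spectral, state-space or time-varying Granger variants; no wPLI or
  coherence alternatives to PLV.
* The montage accepts channels outside all six regions (a 64-channel cap
  lists 62 scalp positions here); such channels pass through preprocessing
  but never enter regional means.
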