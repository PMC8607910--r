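# ibsync

Speaker-listener interpersonal brain synchronization (IBS) analysis for EEG
pseudo-hyperscanning studies, with a ground-truth synthetic dyad generator.

## What this package is for

In story-sharing experiments one speaker narrates an emotional (happy or
sad) and a neutral story; listeners hear the recordings while both parties'
EEG is recorded in separate sessions and aligned at stimulus onset. The
scientific questions are whether the two brains phase-lock, where on the
scalp and in which band, whether the emotion condition changes the locking
relative to the neutral baseline, in which direction information flows, and
whether dyad-level synchrony predicts behavioral outcomes such as a
closeness rating. `ibsync` implements that entire chain for analysts
working with such dyadic designs:

* **Preprocessing** — zero-phase 1-45 Hz band-pass, 50 Hz notch, mastoid
  re-referencing, downsampling to 250 Hz, consecutive 1000 ms epochs,
  ±75 µV amplitude rejection.
* **Phase synchrony** — per electrode pair and band, the phase-locking value

  `PLV(i,k) = (1/N) | Σ_t exp(j(φ_i(t) − φ_k(t))) |`

  from band-limited analytic-signal phases; six-region scalp averages
  (frontal, frontal-central, parietal, left/right temporoparietal,
  occipital) and emotion-minus-neutral contrasts (δPLV).
* **Group statistics** — pooled-variance t tests with Cohen's d (also
  directly from published mean ± SD summaries), BH-FDR/Bonferroni
  correction, Pearson correlations, simple-slopes moderation.
* **Directional coupling** — time-domain Granger causality
  `F = ln(RSS_reduced / RSS_full)` on resting-baseline z-scored signals,
  with information-criterion VAR order selection.
* **Closeness prediction** — ε-SVR (RBF, ε = 0.01) on the dyad ×
  electrode-pair δPLV table: stratified 70/30 split, 5-fold CV grid search
  on the training set only, held-out Pearson-r accuracy, label-permutation
  significance.
* **Synthetic dyads** — von Mises phase-difference coupling on a narrowband
  carrier, chosen because the population PLV is the Bessel ratio
  `I1(κ)/I0(κ)`, giving every estimator an analytic calibration curve; plus
  unidirectional VAR pairs with an exact Granger value and a two-group
  cohort generator (15 vs 17 dyads) with per-region contrast targets and
  behavioral effect sizes.

## Worked example

```r
library(ibsync)

# recover a published group contrast from its mean ± SD summaries
tt <- ttest_from_summary(0.32, 0.10, 15, 0.21, 0.09, 17)
print(tt)

# generate a coupled dyad at kappa = 2 and estimate its synchrony
dyad <- make_coupled_dyad(coupling_spec("F", kappa = 2), fs = 250,
                          duration = 60, montage = c("Fz", "M1", "M2"),
                          seed = 42)
phases <- dyad_true_phases(dyad)
m <- plv_matrix(phases$speaker, phases$listener)
cat(sprintf("recovered PLV = %.3f, population value I1(2)/I0(2) = %.3f\n",
            m$values["Fz", "Fz"], plv_from_kappa(2)))

# directional coupling on a driven pair
vd <- make_var_dyad(n_samples = 10000, drive = 0.5, order = 1, seed = 7)
print(pairwise_gc(vd$x, vd$y, order = 1))
```

prints

```
t(30) = 3.276, p = 0.002663, d = 1.160, mean diff = 0.11
recovered PLV = 0.700, population value I1(2)/I0(2) = 0.698
<gc_result> order=1: F(forward)=0.2025 F(backward)=0.0001
```

The first line recomputes a regional happy-vs-sad δPLV contrast from its
printed summaries (t and d match the published two-decimal values up to
their rounding). The second shows the PLV estimator landing on the analytic
Bessel-ratio value for the generated coupling. The third recovers the
one-way drive: the forward statistic sits near the population value
`ln(1 + drive² · var(x)) ≈ 0.223` while the reverse direction is at
numerical zero.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic cohorts
and write tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R          # cohort + example waveform dyad
Rscript analysis/02_preprocess.R        # preprocessing + rejection report
Rscript analysis/03_phase_sync.R        # PLV matrices, ROI delta contrasts
Rscript analysis/04_group_stats.R       # group tests, correlations, moderation
Rscript analysis/05_granger.R           # directional coupling
Rscript analysis/06_predict_closeness.R # SVR + permutation test
```

`run_pipeline()` performs the same sequence end-to-end (waveform level)
from a single configuration list or YAML file and writes a run log carrying
the seed, configuration hash and every analysis-convention setting.

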