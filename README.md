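# rgstress

EEG analysis of stress and relief during a structured relaxation
experiment, built around the **relative gamma** biomarker. The package is
aimed at researchers who record multi-channel EEG over a protocol of the
form *rest → stress induction (MIST) → relaxation → rest* and want a
reproducible path from raw recordings (EDF or CSV) to group-level stress
curves and survey statistics — plus a synthetic-data generator that makes
the whole pipeline testable without any recordings.

## The biomarker

Per 2-second epoch and averaged across channels, band powers are
estimated in the classical bands (delta 1–4, theta 4–8, alpha 8–13, beta
13–25, gamma 25–45 Hz) and combined as

```
RG = P_gamma / (P_alpha + P_theta)
```

which rises with psychosocial stress in *direct responders* and falls in
*inverse responders*; inverse responders are detected (MIST-vs-relax
contrast) and their series reflected about their mean before group
averaging. The full chain per subject: concatenate blocks (central
minute of each resting state only) → zero-phase order-2 Butterworth
band-pass 1–50 Hz → zero-phase 50 Hz notch → 2 s epochs → zero any
epoch-channel exceeding 100 µV → detrend + z-score → periodogram band
power → RG → interpolate missing epochs → 19-point moving average →
resample to 480 points → classify and orient polarity. A standard 16-min
analysis window yields exactly 480 = 16·60/2 biomarker samples per
subject. Group curves (mean ± SEM) are fitted with degree-6 polynomials
and compared via Pearson correlation with Fisher-z 95% intervals;
self-perceived stress surveys (1–5 at four instants) are tested with an
exact Wilcoxon signed-rank test, gated by a Monte-Carlo Lilliefors
normality check.

## Worked example

Simulate the default study (20 subjects, 10 control / 10 test, 18-minute
sessions at 250 Hz) and run the full analysis:

```r
library(rgstress)
report <- run_pipeline(list(seed = 1))
print(report)
```

```
Relative-gamma stress pipeline report (rgstress 0.1.0)
  seed 1; 20 subjects (control n=10, test n=10)
  polarity split: direct 8, inverse 12
  epoch-channel masked fraction: mean 0.018 (max 0.028)
  correlations (PCC with CI bounds):
    RG control vs RG test        1.00  1.00  1.00
    RG control fit vs RG test fit 1.00  1.00  1.00
SPSL summary (mean (sd) per instant):
  control  T1 2.10 (0.99)  T2 3.60 (0.70)  T3 2.60 (0.52)  T4 1.90 (0.57)
  test     T1 2.00 (0.47)  T2 4.50 (0.85)  T3 2.20 (0.79)  T4 2.10 (0.74)
Within-group phase contrasts (Wilcoxon signed-rank):
  control  T1-T2 p=0.0078*  T2-T3 p=0.0156*  T3-T4 p=0.0312*
  test     T1-T2 p=0.0020*  T2-T3 p=0.0039*  T3-T4 p=1.0000
Between-group tests per instant:
  T1 p=1.0000  T2 p=0.0312*  T3 p=0.3438  T4 p=0.7500
  no multiple-testing correction applied
  SPSL-RG instant correlation: control 0.94, test 1.00
```

Reading the report: about 1.8% of epoch-channels were zeroed by the
100 µV rule; both groups' stress rose significantly from rest to MIST
and fell from MIST to relaxation (the asterisks mark p < 0.05, exact
signed-rank); the two groups' biomarker curves are nearly identical
(PCC ~1 between both the raw curves and their degree-6 fits — both
groups follow the same simulated stress arc); and the biomarker tracks
the surveys closely at the four instants. Individual pieces are
available directly, e.g. the Fisher interval machinery:

```r
fisher_ci(0.60, 480)
#> [1] 0.5394692 0.6543611
wilcoxon_signed_rank(c(2,2,3,1,2,2,3,2,1,2), c(4,5,4,3,4,5,4,4,3,4))
#> Wilcoxon signed-rank (exact): statistic = 0, p = 0.001953 * (alpha = 0.05, n = 10)
#>   note: tied ranks midranked
```

`run_pipeline(list(mode = "files", input = list(dir = "data/")))` runs
the same analysis on recorded EDF/CSV sessions plus a `surveys.csv`.
Fixture sets (EDF or long CSV with block annotations, surveys, ground
truth JSON) are written by `write_fixture_set()`; a thin command-line
wrapper lives at `inst/scripts/rg-pipeline.R`.

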