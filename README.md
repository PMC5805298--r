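# qtsalvage

Does the ECG know how much myocardium was saved?  After an anterior
ST-elevation myocardial infarction (STEMI) treated by primary PCI, cardiac
MR quantifies the tissue outcome — the edematous **area at risk** (AAR) on
T2-weighted imaging, the infarct on **late gadolinium enhancement** (LGE),
and their ratio, the **myocardial salvage index**

```
MSI = (AAR − infarct) / AAR        (1 = full salvage, 0 = none)
```

— but CMR is scarce, while serial 12-lead ECGs are universal.
Repolarization lengthens over injured myocardium, so the anterior–inferior
QTc dispersion

```
ΔQTc-AI-MA = max QTc over V2–V5 − min QTc over II, III, aVF
ΔQTc-AI-ME = mean anterior QTc − mean inferior QTc
```

is a candidate bedside surrogate for salvage.  `qtsalvage` implements the
full analysis chain connecting the two, for methodologists who want a
tested, reproducible reference implementation:

* **ECG**: isoelectric-baseline estimation from PQ segments, per-lead QT
  delineation (QRS onset → T-end on the baseline, with the T–U-nadir rule
  when a U wave follows), Bazett correction `QTc = QT/√RR`, dispersion
  statistics and their day-by-day timecourse;
* **CMR**: SD-threshold segmentation (edema > remote mean + 2 SD, infarct
  > mean + 5 SD, both strict), microvascular-obstruction detection (dark
  core enclosed by infarct, in-slice), mass conversion at 1.05 g/mL, MSI;
* **statistics**: paired t-tests, Spearman correlation, p < 0.1
  univariate screening, linear regression for log-LGE, logistic
  regression for MSI < 0.6 (odds ratios, explicit outcome coding),
  empirical ROC with the Youden cut-off, Cohen's kappa;
* **synthetic data**: analytic ECG beats, CMR signal phantoms and linked
  cohorts with known ground truth — every stage is validated by
  *recovering* programmed quantities, since no patient data ships with
  the package;
* **pipeline**: `run_pipeline()` runs exclusion filter → waveform
  measurement → phantom quantification → cohort merge → association
  suite, deterministically from one seed.

See `vignettes/qtc-dispersion-and-salvage.Rmd` for the models,
conventions and their rationale.

## Worked example

Measure a simulated recording whose anterior leads carry a longer
programmed QT than the inferior leads:

```r
library(qtsalvage)
rec <- simulate_ecg(qt_ms = c(V2 = 480, V3 = 470, V4 = 465, V5 = 460,
                              II = 410, III = 405, aVF = 408),
                    rr_s = 0.8, noise_sd_mv = 0.01, seed = 7)
measure_leads(rec)
#>   lead qt_ms  rr_s qtc_ms baseline_mv u_truncated
#> 1   V2   484 0.801  540.8  -0.0009011       FALSE
#> 2   V3   472 0.800  527.7  -0.0028847       FALSE
#> ...
#> 7  aVF   410 0.800  458.4   0.0010991       FALSE
qtc_dispersion(measure_leads(rec))
#>   timepoint delta_ma_ms delta_me_ms max_anterior_lead min_inferior_lead
#> 1 admission       87.15       70.26                V2               III
```

Each QT is recovered within a couple of milliseconds of its programmed
value (at 500 Hz one sample is 2 ms); after Bazett correction at RR =
0.8 s, the max-anterior minus min-inferior dispersion is ~87 ms.
Quantify a CMR phantom with a programmed infarct and MVO core:

```r
quantify_cmr(simulate_cmr_phantom(seed = 7))
#> <cmr_quantification> subject S01
#>   AAR 20.3 g (20.1% LV), LGE 16.2 g (16.2% LV)
#>   MVO present (1.2 g), LV mass 100.6 g, MSI 0.20
```

and run the whole chain on a synthetic cohort whose dispersion–salvage
link has a programmed negative slope:

```r
run_pipeline(n_subjects = 40, seed = 1, verbose = FALSE)
#> <qts_pipeline> 40 enrolled = 0 excluded + 0 dropped + 40 analyzed
#>   QTc peak at day3; paired admission->peak p = 2e-14
#>   Spearman dQTc(day6) vs MSI: r = -0.49 (p = 0.0015)
#>   ROC for MSI < 0.6: AUC 0.76, cut-off 33 ms
```

The dispersion measured from the waveforms correlates negatively with the
salvage index measured from the phantoms, higher dispersion predicts poor
salvage (AUC > 0.5), and the QTc timecourse peaks on day 3 — the
programmed behaviour, recovered by measurement rather than copied from
the generator.

A thin command-line wrapper lives at `inst/cli/qtsalvage-cli.R`
(subcommands `simulate`, `ecg`, `cmr`, `associate`, `run-all`).

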