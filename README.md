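# molliECV

Quantitative measurement of the myocardial extravascular extracellular
volume fraction (Ve, ECV) from cardiac MR T1 relaxometry, for researchers
studying diffuse myocardial fibrosis with gadolinium contrast.

Once plasma and interstitium reach exchange equilibrium, the partition
coefficient

    lambda = dR1_myocardium / dR1_blood,   dR1 = 1/T1_post - 1/T1_pre

is independent of the (slowly clearing) contrast concentration, and

    Ve = lambda * rho * (1 - hematocrit) - Vp      (rho = 1.05, Vp = 0.045)

is the extracellular volume fraction. The package implements the full
chain around this model:

* **T1/T2 fitting** — the three-parameter magnitude inversion-recovery
  model `|A - B exp(-TI/T1*)|` with polarity restoration, variable
  projection, Levenberg-Marquardt refinement, and the Look-Locker
  correction `T1 = T1* (B/A - 1)` (`fit_ir()`); monoexponential spin-echo
  T2 (`fit_t2()`).
* **MOLLI sampling schemes** — classic 3+3+5 and shortened hybrid 5+1 /
  4+2+1 cardiac-gated layouts and their effective inversion-time
  schedules at any heart rate (`molli_scheme()`, `ti_schedule()`).
* **Monte Carlo precision analysis** — RMSE of fitted T1 per scheme over
  heart-rate and T1 grids, with paired scheme comparison
  (`run_mc_simulation()`, `compare_schemes()`).
* **ECV pipeline** — serial lambda and Ve with steady-state window
  detection for infusion scans and the 12-minute rule for bolus scans
  (`ve_series()`, `steady_state_window()`).
* **Agreement statistics** — Bland-Altman, regression slope against
  unity, coefficient of variation, paired t-tests, and a Gaussian GEE
  with exchangeable working correlation and sandwich errors
  (`gee_exchangeable()`, `time_interaction_test()`).
* **Synthetic data** — bolus and constant-infusion contrast kinetics with
  known true lambda, paired-protocol cohorts, and the reference phantom
  T1/T2 set (`generate_scan()`, `generate_cohort()`, `phantom_set()`).

## Worked example

Simulate a bolus scan with known truth (lambda = 0.45, hematocrit 0.40,
1.4% T1 noise), then recover Ve from its serial T1 measurements:

```r
library(molliECV)

sc <- generate_scan(kinetics_config("bolus", true_lambda = 0.45,
                                    hematocrit = 0.40, seed = 7))
ve_series(sc)
#> ECV result: subject synthetic, bolus
#>   mean Ve = 23.3% (SD 1.36, SEM 0.43) over 10 timepoints; mean lambda = 0.441
```

The true Ve here is `0.45 * 1.05 * 0.6 - 0.045 = 0.2385` (23.85%); the
estimate from ten noisy serial timepoints lands within its standard
error. With `noise_frac = 0`, every timepoint returns exactly 23.85% even
though both tissues' T1 drift as contrast clears — the ratio structure of
lambda removes the common kinetics.

Fitting a single MOLLI acquisition directly:

```r
ti <- sort(ti_schedule(molli_scheme("hybrid_post"), rr_from_hr(68))$ti_eff_msec)
fit_ir(data.frame(ti_msec = ti, signal = ir_signal(ti, 250, 500, 400)))
#> Inversion-recovery fit (7 samples)
#>   A = 250  B = 500  T1* = 400 msec
#>   T1 (Look-Locker corrected) = 400 msec, RSS = 4.039e-27
```

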