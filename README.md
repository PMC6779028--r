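# thumbscreen

Tablet-based screening for carpal tunnel syndrome (CTS) from thumb-reach
kinematics, in R.

CTS is the most common compression neuropathy; in advanced stages the thenar
muscles atrophy and thumb opposition slows. A simple tablet game can expose
this: the player slides the thumb from a central circle to targets arranged
in the 12 clock directions, and the touch stream is reduced to three
kinematic parameters per direction — maximum speed (cm/s), average speed
(cm/s) and total reach time (s) — giving a 36-value feature vector per hand.
Group differences are assessed per direction with Welch's *t*-test
(t = (x̄₁ − x̄₂) / √(s₁²/n₁ + s₂²/n₂), Welch–Satterthwaite df) and medians
with percentile-bootstrap 95% CIs; hands are screened with a grid-search-
tuned support vector machine evaluated by leave-one-out cross-validation
(LOOCV), reporting sensitivity TP/(TP+FN), specificity TN/(TN+FP) and PPV
TP/(TP+FP).

`thumbscreen` implements that whole pipeline, plus a seeded synthetic-cohort
generator that produces full touch streams (not just feature tables) whose
per-direction group medians follow configurable impairment profiles. The
shipped profiles reproduce published per-direction medians for non-CTS and
CTS groups, so the entire analysis chain is exercisable without patient
data.

## Worked example

Simulate a cohort at the study's sample sizes (11 control hands, 29 CTS
hands), extract features, compare the groups, and evaluate the screening
classifier:

```r
library(thumbscreen)

cohort <- simulate_cohort(n_control = 11, n_cts = 29, seed = 42)
tab    <- features_to_table(lapply(cohort, extract_features))

cmp <- compare_groups(tab, n_boot = 2000, seed = 42)
cmp[cmp$parameter == "avg_speed" & cmp$direction %in% c(3, 6),
    c("direction", "median_control", "median_cts", "t_stat", "df", "p_value")]
#>   direction median_control median_cts t_stat   df  p_value
#> 1         3           6.89       5.60   3.26 13.1 0.006210
#> 2         6           7.40       5.19   5.14 13.7 0.000161
```

The CTS profile is calibrated to slower average thumb speed, and the 3 and
6 o'clock deficits come out clearly: CTS medians around 5.2–5.6 cm/s versus
6.9–7.4 cm/s in controls, with Welch p-values well below .05 (uncorrected,
one test per cell).

```r
res <- loocv_evaluate(tab, classifier_config(kernels = "linear",
                                             costs = 2^c(-5, 0, 5)))
res
#> <cts_screening> n = 40 (LOOCV)
#>   confusion: TP 29, FN 0, TN 11, FP 0
#>   sensitivity 100%, specificity 100%, PPV 100%
```

Perfect LOOCV here reflects the simulator, not the clinic: the synthetic
group profiles differ in all 36 features at once, which separates the
classes far more cleanly than real patients do. `tidy(res)` gives per-hand
predictions and decision values, `glance(res)` the one-row summary, and
`autoplot(res)` / `autoplot(cmp)` the decision-value and radar plots.

A command-line front end wrapping the same functions ships at
`inst/cli/thumbscreen.R` (subcommands `simulate`, `extract`, `compare`,
`train-eval`, `screen`).

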