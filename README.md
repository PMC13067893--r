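# dxeval

Evaluation of a single diagnostic test against a binary reference (gold)
standard, for laboratory scientists, clinicians and biostatisticians who
need the standard accuracy indicators with honest uncertainty statements
and exportable, reproducible output — without proprietary software.

Given a dataset with one reference column (1 = diseased, 0 = non-diseased)
and one test column (binary 0/1 or a quantitative marker), plus a disease
prevalence for the target population, `dxeval` computes:

- **Sensitivity** Se = TP/(TP+FN), **specificity** Sp = TN/(TN+FP) and
  **accuracy** (TP+TN)/N, each with a 95% **Wilson score interval**
  (better small-sample and extreme-p behaviour than the Wald interval).
- **Predictive values** by Bayes' theorem at the *user-supplied*
  prevalence pr (the sample prevalence is deliberately not used):
  PPV = Se·pr / (Se·pr + (1−Sp)(1−pr)), NPV = Sp(1−pr) / (Sp(1−pr) + (1−Se)pr),
  with conservative bounds propagated from the four combinations of the
  Se/Sp interval limits.
- **Likelihood ratios** LR+ = Se/(1−Sp), LR− = (1−Se)/Sp with log-scale
  (Simel-type) 95% intervals.
- **Youden index** J = Se + Sp − 1 with a binomial-variance interval.
- For quantitative tests, the **ROC curve** over all thresholds, the
  **AUC with a DeLong interval** (placement values, midrank ties), the
  **optimal cutoff** minimizing the Euclidean distance
  √((1−Se)² + (1−Sp)²) to the top-left ROC corner, and a stratified
  **bootstrap sensitivity band** (5000 iterations by default).

All intervals use z = 1.96; displayed values are rounded half-up to three
decimals; any zero denominator yields `NA` rather than an error or an
infinity. Input is read from `.xlsx` with strict validation (exact,
documented error messages); results export to `.xlsx`, CSV and a
300-dpi ROC plot.

## Worked example

```r
library(dxeval)

d   <- dx_simulate(n = 113, seed = 7)      # Disease, Test1, Test2
fit <- dx_analyze(d$Test1, d$Disease, "quantitative",
                  prevalence = 0.1, n_boot = 5000, seed = 7)
print(fit)
```

```
Diagnostic test evaluation (quantitative test, direction: higher)

              Disease present Disease absent
Test positive              55               9
Test negative              20              29
n = 113 (75 diseased, 38 non-diseased)

optimal cutoff 1.967 (Se = 0.733, Sp = 0.763, distance 0.357)

 metric estimate lower upper
     Se    0.733 0.624 0.820
     Sp    0.763 0.608 0.870
    Acc    0.743 0.656 0.815
    PPV    0.256 0.150 0.412
    NPV    0.963 0.936 0.978
    LR+    3.096 1.722 5.568
    LR-    0.349 0.231 0.529
      J    0.496 0.328 0.665
    AUC    0.797 0.704 0.890
assumed prevalence: 0.1
```

Reading: at the selected cutoff (1.967, the threshold closest to the
perfect-classification corner) the marker detects 73% of diseased and
clears 76% of non-diseased subjects. Because the assumed population
prevalence is low (10%), a positive result still leaves only a 26%
disease probability (PPV), while a negative result is reassuring
(NPV 0.96). LR+ ≈ 3 is a modest rise in disease odds; the AUC of 0.797
(95% CI 0.704–0.890) indicates moderate discrimination. `dx_plot_roc(fit$curve,
fit$auc, band = fit$band, cutoff = fit$cutoff, path = "roc.png")` draws
the annotated ROC curve with its bootstrap band.

The same workflow runs from a shell:

```sh
exec/dxeval simulate --out data.xlsx --n 113 --seed 7
exec/dxeval run --input data.xlsx --test-col Test1 --ref-col Disease \
    --test-type quantitative --prevalence 0.1 --outdir results/ --seed 7
```

which writes `confusion_matrix.xlsx`, `metrics.xlsx`, `roc_points.csv`
and `roc.png`.

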