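# ehgelm

Classification of uterine electrohysterogram (EHG) recordings — labour vs
pregnancy contraction windows — using Hilbert-Huang features and an extreme
learning machine, in base R.

The EHG is a noninvasive abdominal recording of uterine electrical activity
(typically a 4-by-4 electrode grid: 16 channels at 200 Hz). Distinguishing
labour from pregnancy contractions automatically is a building block for
preterm-birth monitoring. The pipeline implemented here is:

1. **Band-pass** each channel to the 0.1–3 Hz EHG band with a 6th-order
   Butterworth filter (zero-phase, second-order sections) — `apply_filter()`.
2. **Empirical mode decomposition**: each channel is sifted into intrinsic
   mode functions `x(t) = Σ cᵢ(t) + r(t)`, fastest mode first — `emd()`.
3. **Feature**: the maximum instantaneous amplitude
   `max_t √(c² + H(c)²)` of a chosen IMF (IMF1 by default), one value per
   channel, giving a 16-dimensional feature vector per sample —
   `extract_features()`.
4. **Classifier**: an extreme learning machine — a single hidden layer of 20
   random sigmoid neurons whose output weights are the minimum-norm
   least-squares solution `β̂ = H⁺y` — `elm()`, with `predict()`, `coef()`,
   `summary()` methods.
5. **Evaluation**: confusion matrix (labour = positive), sensitivity /
   specificity / accuracy in percent, and ROC/AUC — `confusion()`,
   `classification_metrics()`, `roc_curve()`.

A synthetic contraction-burst generator (`generate_dataset()`) emulates the
band-limited bursty structure of real EHG, with class separation carried by
burst amplitude, so the entire pipeline is testable with no data download.
`run_experiment()` reproduces the full protocol (stratified split, seeded ELM,
held-out metrics) in one call.

## Worked example

```r
library(ehgelm)

cfg <- synth_config(n_per_class = 30, seed = 101)        # 16 ch x 4096 pts @ 200 Hz
ds  <- generate_dataset(cfg, validate_imfs = TRUE)

exp <- run_experiment(ds$samples,
                      experiment_config(n_train_per_class = 20,
                                        n_test_per_class = 10,
                                        n_hidden = 20,
                                        elm_seed = 10001, split_seed = 20001))
exp
```

```
<ehg_experiment> IMF1 features, ELM L=20, 20 train + 10 test per class
sensitivity 90.00%  specificity 100.00%  accuracy 95.00%  AUC 1.0000
```

Sensitivity is the fraction of labour windows correctly flagged, specificity
the fraction of pregnancy windows correctly passed, on the 10 + 10 held-out
samples of this split; the AUC summarises the score ranking across all
thresholds. Labour bursts are generated three times stronger than pregnancy
bursts on average, and the IMF1 amplitude feature recovers that separation
almost perfectly.

The classical worked example of the evaluation arithmetic — a 50 + 50 test
set in which 8 labour and 4 pregnancy samples are misjudged — gives:

```r
truth <- rep(c(2, 1), each = 50)                 # 2 = labour, 1 = pregnancy
pred  <- c(rep(1, 8), rep(2, 42), rep(2, 4), rep(1, 46))
classification_metrics(confusion(truth, pred))
#> sensitivity specificity    accuracy
#>          84          92          88
```

## Command-line use

A thin CLI wraps corpus generation and the experiment:

```sh
Rscript inst/cli/ehg.R synth --n 30 --seed 7 corpus/
Rscript inst/cli/ehg.R run --n-train 20 --n-test 10 corpus/ report.json
```

See `vignettes/ehg-classification.Rmd` for the model, the numerical choices
(filter conditioning, EMD stopping rules, edge handling) and the generator's
scope and limitations.
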