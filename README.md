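# lacto2dspec

Chemometric discrimination of raw-milk freshness from visible/near-infrared
(Vis/NIR) absorbance spectra, using synchronous two-dimensional correlation
spectroscopy against a fresh-milk reference.

Milk freshness is conventionally graded by titratable acidity: fresh **A**
(13–15 °T), sub-fresh **B** (15–18 °T), spoiled **C** (> 18 °T). Titration is
slow and destructive; Vis/NIR scanning (400–2500 nm, 2 nm steps) is fast but
milk's strong scattering and overlapping bands blur the 1D spectra. This
package builds, for every sample spectrum *y*, the dynamic spectrum
*ỹ = y − ȳ_fresh* against the mean fresh spectrum and the synchronous
correlation map

> Φ(ν₁, ν₂) = ỹ(ν₁) · ỹ(ν₂)  (per sample),  Φ = 1/(m−1) Σⱼ ỹⱼ(ν₁) ỹⱼ(ν₂)  (ensemble),

whose diagonal — the autocorrelation spectrum ỹ² — concentrates the
storage-driven intensity changes (water bands at 1450/1940 nm, lactose/lactic
acid at 1194 nm, fat at 1790 nm). On these features it fits and evaluates:

- a **peak-threshold rule**: fresh iff the synchronous peaks at (1450, 1450),
  (1940, 1940) and (1450, 1940) all stay below mean + 3 SD of the fresh
  calibration peaks;
- **trace-ratio LDA**: the projection *V* maximizing
  tr(VᵀS_B V)/tr(VᵀS_W V) with the between/within scatter matrices
  S_B = (1/N) Σᵢ Nᵢ(x̄ᵢ−x̄)(x̄ᵢ−x̄)ᵀ, S_W = (1/N) ΣᵢΣⱼ(xᵢⱼ−x̄ᵢ)(xᵢⱼ−x̄ᵢ)ᵀ,
  solved by the monotone trace-ratio iteration, with nearest-centroid
  assignment;
- **kernel SVMs** (linear, polynomial, RBF, sigmoid; one-vs-one) with [C, G]
  tuned by coarse grid search plus particle swarm optimization over
  cross-validated accuracy;
- accuracy bookkeeping (total and per class), coefficient of variation, and
  the acidity-to-class mapping.

Because the study's raw spectra are not publicly deposited, a first-class
synthetic generator (`generate_dataset()`) reproduces the study design — 130
samples over 6 days of refrigerated storage sampled every 12 h across 10 milk
types, acidity rising 14.1 → 21.0 °T, a 97/33 stratified
calibration/validation split — with documented band, growth and noise models
(see the methods vignette in `vignettes/`).

## Worked example

```r
library(lacto2dspec)

ds  <- generate_dataset(synth_config(seed = derive_seed(1, "synth")))
cal <- calibration(ds)
ref <- reference_spectrum(cal)              # mean fresh (class A) spectrum

## 2D autocorrelation features and an RBF SVM
feats <- autocorr_features(cal, ref)
cfg   <- svm_config("rbf", cost = 2^7, gamma = 2^-9, seed = 42)
cross_val_accuracy(feats, cfg)
#> [1] 0.9587629

model <- train_svm(feats, cfg)
model
#> Kernel SVM (rbf): C = 128, G = 0.001953, 13 support vectors

val <- validation(ds)
evaluate_predictions(val$label, predict(model, autocorr_features(val, ref))$.pred)
#> Freshness evaluation report
#>      estimate
#> truth A  B C
#>     A 8  0 0
#>     B 0 14 2
#>     C 0  0 9
#> Total accuracy: 93.9%
#> Per class: A 100.0%, B 87.5%, C 100.0%

## the threshold rule and the peak-vs-time regression
tm <- fit_thresholds(cal[cal$label == "A", ], ref)
tidy(tm)
#> # A tibble: 3 × 5
#>   peak              nu1   nu2 threshold  k_sd
#>   <chr>           <dbl> <dbl>     <dbl> <dbl>
#> 1 auto_1450        1450  1450  0.000984     3
#> 2 auto_1940        1940  1940  0.00121      3
#> 3 cross_1450_1940  1450  1940  0.00109      3

peak_time_regression(peak_series(cal, ref), intensity = "auto_1940")
#> # A tibble: 1 × 4
#>    slope intercept r_squared     n
#>    <dbl>     <dbl>     <dbl> <int>
#> 1 0.0236    -0.474     0.951    97
```

Reading the output: the five-fold cross-validated calibration accuracy of the
RBF SVM on autocorrelation features is 95.9%; on the 33 held-out samples it
classifies every fresh and spoiled sample correctly and mistakes two
sub-fresh samples for spoiled (93.9% total). The fresh-peak thresholds sit
near 10⁻³ absorbance² — three orders of magnitude under the day-6 peaks — and
the 1940 nm autocorrelation peak grows almost linearly with storage time
(R² = 0.95), which is what makes the simple threshold rule workable for
fresh/non-fresh screening.

One-call orchestration (simulate → preprocess → features → train → evaluate,
with calibration-only fitting and JSON/CSV artifacts):

```r
res <- run_pipeline(seed = 7, classifier = "svm", optimize = "grid",
                    out_dir = "run1")
glance(res)
```

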