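# eegrecon

Seizure-state detection from single-channel EEG via **one-class
autoencoder reconstruction features**.

Scalp EEG is the standard tool for diagnosing epilepsy, and automated
recognition of the three clinically relevant signal states — healthy,
interictal (between seizures) and ictal (during a seizure) — is the core
of any automatic monitoring system. Most pipelines extract spectral or
time–frequency features, which is computationally heavy. `eegrecon`
implements a lightweight time-domain alternative for researchers and
engineers working on EEG classification:

1. A 1-D convolutional autoencoder (three strided conv layers E1–E3, three
   mirrored transposed-conv layers D1–D3, ReLU activations, sigmoid
   output) is trained **only on interictal recordings**, minimizing
   reconstruction MSE with Adam (learning rate 0.001).
2. Every recording x with reconstruction x̂ (length n) is summarized by
   three reconstruction-fidelity indicators:
   - MSE = (1/n) Σᵢ (xᵢ − x̂ᵢ)²
   - ORSR = 10 log₁₀ (Σᵢ xᵢ² / Σᵢ x̂ᵢ²)  (original-to-reconstructed
     signal ratio, dB)
   - CS = Σᵢ xᵢx̂ᵢ / (√Σᵢxᵢ² · √Σᵢx̂ᵢ²)  (cosine similarity)

   Interictal records reconstruct well (MSE ≈ 0, ORSR ≈ 0 dB, CS ≈ 1);
   healthy and ictal records diverge.
3. The (MSE, ORSR, CS) table feeds three ensemble classifiers — random
   forest, AdaBoost (SAMME), gradient boosting — under a stratified 75/25
   split. A 10-component PCA on the raw normalized signals provides the
   baseline feature set for comparison.
4. Model interpretability: permutation importance and **exact**
   interventional Shapley values (full 2³-coalition enumeration, no
   sampling), summarized as mean |φ| per feature.

The package reads the University of Bonn EEG corpus format (one ASCII
sample per line, one directory per class; sets A/D/E = healthy/
interictal/ictal) and ships a three-class synthetic EEG generator so the
entire pipeline is testable with no download.

## Worked example

```r
library(eegrecon)

# 100 synthetic records per class, 4096 samples at 173.61 Hz
ds <- generate_eeg_dataset(synthetic_config(n_per_class = 100, seed = 1))

# one-class training on the interictal records
ae <- train_autoencoder(build_autoencoder(ae_config(seed = 2)),
                        dplyr::filter(ds, label == "interictal"))

# reconstruction features for all 300 records
features <- extract_features(ae, ds)
features |> dplyr::group_by(label) |>
  dplyr::summarise(dplyr::across(c(mse, orsr, cs), median))
#> # A tibble: 3 x 4
#>   label           mse     orsr    cs
#>   <fct>         <dbl>    <dbl> <dbl>
#> 1 healthy    0.00190  0.0655   0.997
#> 2 interictal 0.000535 0.000782 0.999
#> 3 ictal      0.00447  0.452    0.994
```

Interictal records sit an order of magnitude below the other classes in
median MSE and closest to (0 dB, 1) in ORSR/CS — the one-class
specificity the classifiers exploit.

```r
sp  <- split_table(features, 0.75, seed = 3)          # 225 train / 75 test
rf  <- train_classifier(sp$train, "random_forest", seed = 4)
ev  <- evaluate_classifier(rf, sp$test, train = sp$train)
ev
#> Evaluation of random_forest on 75 records
#>             predicted
#> truth        healthy interictal ictal
#>   healthy         25          0     0
#>   interictal       0         25     0
#>   ictal            0          0    25
#> test accuracy: 1 | training accuracy: 1

# interpretability on the held-out split
rep <- interpret_classifier(rf, sp$test, sp$train, seed = 5)
rep$ranking
#> [1] "cs"   "mse"  "orsr"
```

The whole protocol — data, one-class training, both feature sets, all
three classifiers, interpretability, artifact files — runs as one call:

```r
run <- run_pipeline(run_config(seed = 1), output_dir = "eegrecon_run")
tidy(run)   # train/test accuracy per (feature set, classifier)
```

or from the shell via the bundled CLI
(`inst/cli/eegrecon.R <simulate|train-ae|extract|pca|classify|interpret|run-all>`).

## Using the real Bonn corpus

Download sets A (Z), D (F) and E (S) from the Bonn epileptology archive,
unpack them as `bonn/A`, `bonn/D`, `bonn/E`, then:

```r
ds <- load_eeg_dataset("bonn", c(A = "healthy", D = "interictal", E = "ictal"))
run <- run_pipeline(run_config(
  seed = 1, data = list(source = "directory", root = "bonn",
                        class_map = list(A = "healthy", D = "interictal",
                                         E = "ictal"))),
  output_dir = "bonn_run")
```

On this corpus, expect test accuracy for the reconstruction features in
the 90–100% band with a large margin over the PCA baseline, CS the most
important feature and ORSR the least.

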