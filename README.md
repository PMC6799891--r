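# impedocyte

Label-free assessment of cell viability from multifrequency impedance
cytometry.

Staining-based viability instruments (trypan-blue exclusion) consume the
sample and preclude downstream molecular analysis. Impedance cytometry
avoids staining: each cell transiting a microchannel between electrodes
perturbs the AC impedance, and measuring that perturbation at several
excitation frequencies simultaneously (a low frequency near 500 kHz that
senses cell size, plus 20–30 MHz frequencies that probe the cell interior)
captures enough dielectric contrast to separate live from dead cells.
`impedocyte` implements the complete analysis pipeline for this
measurement, plus a physics-grounded simulator that generates labeled
benchmark data, for researchers developing or validating such devices.

## The method

The sensing channel is modelled as an equivalent circuit: a double-layer
capacitance `C_dl` at each electrode in series with the solution
resistance `R_s`, in parallel with the electrode-to-electrode coupling
capacitance `C_cell`:

```
Z(ω) = 2/(jωC_dl) + R_s · (1/(jωC_cell)) / (R_s + 1/(jωC_cell)),  ω = 2πf
```

A lock-in amplifier demodulates the channel current into in-phase (I) and
quadrature (Q) components per excitation frequency. For each detected
single-cell transit the pipeline extracts, at every frequency *f*:

- **amplitude change** ΔA = | |baseline| − |peak| | / |baseline| — the
  fractional dip in demodulated amplitude as the cell raises the channel
  impedance;
- **phase change** Δφ = arg(peak) − arg(baseline), wrapped to
  (−180°, 180°], computed from the real and imaginary components. Δφ is
  characteristically negative below 1 MHz and positive at 20–30 MHz.

Events are found on the 500 kHz amplitude trace after running-median
detrending and moving-average denoising, with a threshold of 5× the robust
(MAD-based) noise scale. Features (4 amplitude, 4 phase, or the combined
8-feature matrix) are min-max normalized on the training set and fed to a
Gaussian-kernel SVM (live = 1, dead = 0) whose hyperparameters `(C, γ)`
are chosen by stratified 5-fold cross-validation. Performance is reported
as a confusion matrix with accuracy = (TP + TN)/N, and the viability of a
mixed sample is the fraction of events predicted live, ×100.

## Worked example

```r
library(impedocyte)

# simulate a balanced training sample and a 90%-live test sample
train <- pipeline_features(n_cells = 500, live_fraction = 0.5, seed = 1)
model <- train_viability_svm(train$features, train$labels, seed = 1)
model
#> Gaussian-kernel live/dead SVM
#>   trained on 500 events, 8 features
#>   C = 0.1, gamma = 0.1 (CV accuracy 1.000)
#>   warning: small training set

mix <- pipeline_features(n_cells = 400, live_fraction = 0.9, seed = 2)
viability_percent(predict(model, mix$features))
#> viability: 89.5% (358 of 400 events predicted live)

confusion_matrix(predict(model, mix$features), mix$labels)
#>       predicted
#> truth  live dead
#>   live  358    0
#>   dead    2   40
#> accuracy: 0.995
```

The simulated sample contains 400 transits of which 90% are live; the
trained 8-feature classifier recovers a viability estimate of 89.5%,
within sampling error of the ground truth, with 99.5% per-event accuracy.
(The small-training-set warning is expected at 500 events; the standard
benchmark uses at least 1000.)

A command-line interface over the same functions lives at
`inst/cli/impedocyte.R`
(`Rscript impedocyte.R simulate|process|train|predict|evaluate ...`).

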