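# tastenet

Decoding sweetness concentration from taste-evoked EEG with a compact
multi-branch strip-convolution attention network.

## The problem

Gustatory stimulation evokes EEG responses whose intensity, spatial spread
and onset latency grow with stimulus concentration. `tastenet` classifies
single 1-s epochs of 21-channel EEG (10–20 montage, 256 Hz — a 21 × 256
matrix) into six concentration classes (0 = pure-water control, 1–5 =
increasing sucrose). It is aimed at researchers studying EEG-based sensory
evaluation who need a lightweight, fully inspectable decoding pipeline —
including a synthetic data generator, because no public recordings
accompany the acquisition protocol it targets.

## The model

The core is a shape-preserving feature-computation block. For input
X ∈ ℝ^{C×H×W} each of three branches (k = 3, 5, 7) computes

    X_i   = Conv(Conv(X, 1×k), k×1)                       strip convolutions
    X_i'  = σ(Conv1D(GAP(X_i), 3)) ⊗ X_i                  channel gate
    X_i'' = σ(Conv(mean_C(X_i'), 3×3)) ⊗ X_i'             spatial gate
    X_i'''= X ⊕ X_i''                                     residual
    Z_i   = softmax(Q_i K_iᵀ / √d_k) V_i                  self-attention over
                                                          C channel tokens,
                                                          Q,K,V = PW(X_i''')
    Y_i   = X_i''' ⊕ Z_i                                  residual

    X_o   = PW(Concat(Y_1, Y_2, Y_3))                     fusion back to C

with σ the logistic sigmoid, PW a point-wise (1 × 1) convolution and
d_k = H·W. The network wraps N such blocks between a point-wise expansion
(1 → 40 channels by default), a point-wise reduction, 1 × 2 temporal
pooling, and dense layers of 128 and 6 units. Training is cross-entropy /
Adam (learning rate 0.01) with stratified 8:2 splitting and stratified
k-fold cross-validation; metrics are one-vs-rest precision/recall per class
plus accuracy, reported per fold as mean ± sd. All forward and backward
passes run on compiled (Rcpp/Armadillo) kernels and are verified against
brute-force oracles and finite-difference gradients in the test suite.

## A worked example

```r
library(tastenet)

# 360 synthetic epochs: 4 subjects x 6 classes x 1 repetition x 15 epochs
ds <- generate_dataset(desk_synthetic_spec(rng_seed = 11))
ds
#> <taste_dataset: 360 epochs of 21 x 256, 6 class(es), 4 subject(s)>

sp  <- stratified_split(ds, ratio = 0.8, seed = 1)
fit <- train_model(build_model(desk_model_config(seed = 1)), sp$train,
                   desk_train_config(seed = 1))
m   <- evaluate(fit, sp$test)
m
#> <taste_metrics: n = 72, accuracy 0.9306, macro precision 0.9429, macro recall 0.9306>

glance(m)
#> # A tibble: 1 x 4
#>       n accuracy precision_macro recall_macro
#>   <int>    <dbl>           <dbl>        <dbl>
#> 1    72    0.931           0.943        0.931
autoplot(m)      # confusion-matrix heat map
autoplot(fit)    # training-loss curve
```

The held-out accuracy says the network separates the generator's
amplitude/spread/onset gradients almost perfectly at desk scale; class
confusions, when they occur, sit between adjacent concentrations.

Cross-validation, ablation grids and the command-line front end follow the
same pattern:

```r
cv <- kfold_cv(sp$train, desk_model_config(), desk_train_config())
glance(cv)                      # accuracy mean +/- sd across folds
best <- select_best_fold(cv)

tab <- run_ablation(ablation_grid("components", desk_model_config()),
                    sp$train, desk_train_config(epochs = 5))
autoplot(tab)
```

```sh
inst/cli/tastenet simulate --out data.rds --seed 1 --profile desk
inst/cli/tastenet train    --dataset data.rds --out run1 --seed 1
inst/cli/tastenet ablate   --dataset data.rds --grid directions --out run1
```

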