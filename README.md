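# ecgfsl — few-shot metric learning for 12-lead ECG classification

`ecgfsl` classifies 10-second, 500 Hz, 12-lead electrocardiograms from very
few labeled examples per class. It is aimed at researchers in biomedical
signal processing who want a complete, reproducible reference pipeline —
from raw multi-lead signal to evaluated classifier — with every stage
testable against synthetic ground truth.

The pipeline:

1. **Consensus R-peak labeling.** Six classical single-lead detectors
   (Hamilton, two-moving-average, stationary wavelet transform, Christov,
   Pan–Tompkins, Engzee) run on all 12 leads; the 72 candidate streams are
   reconciled by a deterministic 1-D k-means (k = rounded median of
   per-stream candidate counts, quantile initialization, majority support
   filter, refractory merge).
2. **QRS extraction.** Beats are cut at midpoints between consecutive
   consensus peaks; the two edge segments are dropped; each retained
   segment is resampled per lead to 100 samples, carrying
   `bpm = 60·fs/L` and `resample_ratio = L/100` metadata.
3. **Set encoding.** A compact 1-D conv net (channels 12→24→48→96→2,
   leaky-ReLU 0.01, kernel-2 max pools, final 1×1 reduction with 192
   weights) maps each 12×100 beat to a 24-D feature vector; exact
   max + average pooling over a record's beat set gives 48-D; a fully
   connected layer yields the 20-D record embedding
   `F = W [z_max, z_avg] + b`.
4. **Training.** Triplet margin loss
   `L(a,p,n) = max(d(a,p) − d(a,n) + m, 0)`, `m = 1`, Euclidean `d`,
   optimized with Adam over homogeneous-beat-count triplet batches;
   70/15/15 splits, best-on-validation checkpointing, early stopping.
   A softmax head trained with cross-entropy is the baseline.
5. **Evaluation.** The database/query protocol: held-out records split in
   half per class, per-class mean embeddings ("class centers") label each
   query by nearest Euclidean distance; metric panel with accuracy,
   precision, recall, F1, trapezoidal AUC, specificity, sensitivity;
   optional classifier heads (SVM ×4 kernels, random forest, decision
   tree, k-NN, XGBoost) on embeddings; 5-repetition cross-validation and
   a test-subset-size ablation.

A synthetic 12-lead generator (Gaussian PQRST bumps, class-dependent
morphology, known R-peak positions) makes every stage testable without any
external data. An adapter for filtering a PTB-XL-style diagnostic
statement table (100%-confidence, single-class, subclass-size rules) is
included for use with the real corpus.

## Worked example

```r
library(ecgfsl)

# two synthetic classes with distinct morphologies, 12 records each
specs <- demo_class_specs(2, noise_sd = 0)
recs  <- generate_dataset(specs, n_per_class = 12, seed = 11)

# consensus detection and QRS extraction
qrs <- lapply(recs, function(r)
  extract_qrs(r, consensus_rpeaks(detect_candidates(r))))

# few-shot training (70/15/15 split happens inside)
fit <- train_fsl(qrs, training_config(seed = 42, max_epochs = 200,
                                      patience = 10, batch_size = 16))
fit
#> <ecg_encoder_fit: fsl, 2 classes (MI, NORM)>
#>   epochs run: 11; best validation accuracy 1.000 at epoch 1

# prototype evaluation on freshly generated held-out records
eval_recs <- generate_dataset(specs, n_per_class = 8, seed = 909)
eval_qrs  <- lapply(eval_recs, function(r)
  extract_qrs(r, consensus_rpeaks(detect_candidates(r))))
fsl_evaluate(fit, eval_qrs, seed = 5)
#> <evaluation_report on 8 queries>
#>    accuracy   precision      recall          f1         auc specificity
#>           1           1           1           1           1           1
#> sensitivity
#>           1
```

The report reads: with class centers estimated from the database half of
the held-out records, every query record lands nearer its own class
center than the other class's — the two morphologies are perfectly
recovered. On real data these numbers drop to clinically plausible
ranges; the synthetic classes are deliberately well separated so that
anything below perfect recovery signals a pipeline defect.

The model object supports `print`, `summary`, `coef`, `predict`
(`type = "class"`, `"embedding"`, `"scores"`), `plot` (training curves)
and `residuals` (prototype margin per record). A command-line surface
(`run_cli()`, subcommands `simulate`, `detect`, `extract`, `train`,
`evaluate`, `ablate`) drives the same stages through on-disk artifacts.

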