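# smaddeconv

Sequence-based de-convolution of pooled Smad2/3 ChIP-seq peaks into
Smad2- and Smad3-bound sites.

## Why

TGF-β signaling acts through the receptor-regulated Smads. Smad2 and
Smad3 drive different — sometimes opposing — transcriptional programs,
but ChIP-seq almost always uses a pan-Smad2/3 antibody, so published
peak sets cannot say *which* R-Smad binds where. `smaddeconv`
classifies a 200-bp peak sequence as SMAD2- or SMAD3-bound using small
neural networks, exploiting indirect sequence signals: class-specific
co-factor motifs (E-box `CANNTG` for Smad2-associated bHLH factors;
P-box half-sites `AGAACA`/`AGGTCA` for Smad3-associated nuclear
receptors) and a slight GC-content offset between the classes.

## What is in the package

* **Peak preprocessing** — narrowPeak/BED input, promoter filtering
  against a TSS table (±3 kb), fixed-width resizing (midpoint or MACS2
  summit anchor), sequence extraction from FASTA, and a nearest-peak
  concordance diagnostic stratified by peak confidence.
* **Encoding** — N×200×5 one-hot arrays, channel order (A, T, C, G, N),
  with an exact decoder.
* **Models** — a CNN (kernel-5 then kernel-32 convolution stacks) and a
  CNN-LSTM (kernel-5 convolution into a 32-cell LSTM), both ending in
  batch norm → two ReLU dense layers sized by Huang's minimal-capacity
  rule, a 0.2 dropout, and a sigmoid output. Implemented natively in
  RcppArmadillo (no external deep-learning framework).
* **Training** — snapshot ensembles: one SGD run under a
  cosine-annealing-with-restarts schedule
  `a(t) = (a0/2)[cos(π((t−1) mod T/M)/(T/M)) + 1]`, with the weights
  harvested at the end of each of the M cycles and the member
  probabilities averaged.
* **Evaluation** — precision-recall curves and step-wise average
  precision (AUPR; SMAD3 positive), confusion matrices at the
  prevalence-matched 0.75 cutoff, an exhaustive ensemble-size
  ablation, and a Welch t-test on per-class GC content.
* **Synthetic data** — a generator that plants a shared Smad-binding
  element plus class-specific co-factor motifs into GC-controlled
  backgrounds at a 75/25 SMAD3:SMAD2 imbalance, with a ground-truth
  manifest, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(smaddeconv)

# synthetic study conditions: 2000 peaks, 75% SMAD3, planted motifs
ds    <- generate_dataset(synthetic_config(seed = 20))
labs  <- S4Vectors::mcols(ds$sequences)$label
split <- split_dataset(names(ds$sequences), labs, seed = 20)
train <- one_hot_encode(ds$sequences[split$train_idx])
test  <- one_hot_encode(ds$sequences[split$test_idx])

ens <- train_snapshot_ensemble(
  model_spec("cnn_lstm", conv1_filters = 16),
  train,
  schedule = schedule_params(a0 = 0.1, total_epochs = 50, n_cycles = 10),
  seed = 20)

evaluate_predictions(predict_ensemble(ens, test), test$labels)
```

```
<smad_eval> positive class SMAD3
 AUPR: 0.9464 
 confusion at threshold 0.75 (rows = true class):
       pred
true    SMAD2 SMAD3
  SMAD2   107    18
  SMAD3    43   332
 per-class recall: SMAD2 = 0.856 , SMAD3 = 0.885 
```

The ensemble separates the two classes (AUPR 0.95 against a 0.75
baseline prevalence) and, at the 0.75 cutoff, recovers 86% of SMAD2
and 89% of SMAD3 test peaks. `ablate_ensemble_size(ens, test)` shows
the snapshot-ensembling effect: mean AUPR rises and its
between-subset standard deviation shrinks as members are added.

A command-line wrapper with `simulate / extract / encode / train /
predict / evaluate / ablate / concordance` subcommands is installed at
`inst/cli/smaddeconv.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/smaddeconv.R", package="smaddeconv"))')" \
  simulate --n 2000 --seed 7 --out data/
```

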