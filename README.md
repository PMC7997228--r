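# m6aFuse

Sequence-based prediction of RNA N6-methyladenosine (m6A) sites.

N6-methyladenosine is the most abundant internal mRNA modification in
eukaryotes; mapping which adenosines carry it matters for RNA metabolism,
disease biology, and drug-target discovery, but transcriptome-wide wet-lab
assays are slow and expensive. `m6aFuse` is for computational biologists who
have fixed-length, adenine-centered RNA windows (the standard benchmark
convention: 41 nt with the candidate A at position 21) labeled
methylated/unmethylated and want a trainable, leakage-safe classifier plus
all the machinery around it.

## The method

1. **Multi-information feature fusion.** Eight encoders turn each window
   into numbers and are fused column-wise into one matrix (722 features at
   L = 41 with defaults):
   binary one-hot **BE** (4L = 164), K-spaced nucleotide pair frequencies
   **KSNPF** (16(K_max+1) = 96 at K_max = 5), sliding-window composition
   **ENAC** (4(L−4) = 148 at window 5), nucleotide chemical properties
   **NCP** (3L = 123), pseudo dinucleotide composition **PseDNC**
   (16+λ = 46 at λ = 30), trinucleotide composition **TNC** (64), and
   position-specific mono-/di-nucleotide propensities **PSNP**/**PSDP**
   (L = 41 / L−1 = 40), the last two being class-conditional frequency
   differences z⁺ᵢⱼ − z⁻ᵢⱼ fitted on training folds only.
2. **Elastic-net feature selection.** minimize
   `1/(2n)‖y − Xw‖² + αβ‖w‖₁ + α(1−β)/2‖w‖₂²` by coordinate descent;
   features with nonzero coefficients survive. An `α` sweep
   (`sweep_alpha()`, grid 0.01–0.1) picks the subset by cross-validated
   accuracy.
3. **Feed-forward DNN.** Two or three fully connected hidden layers, each
   followed by dropout, one sigmoid output unit, binary cross-entropy loss;
   seven activations, seven optimizers and seven weight initializers are
   implemented natively (no deep-learning framework required).
4. **TPE hyper-parameter search.** A native tree-structured Parzen
   estimator models the good- and bad-loss densities l(λ), g(λ) and
   suggests the candidate maximizing l/g (equivalent to expected
   improvement), over a mixed conditional space (the third hidden layer
   exists only when `layers = 3`).
5. **Evaluation.** Stratified 5-fold cross-validation with fold-safe
   refitting of every label-dependent component; Sn, Sp, ACC, MCC
   (four-factor square-root form), and rank-based AUC.

## Worked example

```r
library(m6aFuse)

# a synthetic benchmark: 500 windows/class, positives enriched (strength
# 0.6) for G at the eight positions flanking the central adenosine
sim <- generate_synthetic(synthetic_config(n_pos = 500, n_neg = 500,
                                           motif_strength = 0.6, seed = 42))
bundle <- m6a_train(sim, selection = list(alpha = 0.05, beta = 0.5),
                    config = dnn_config(epochs = 20), k = 5, seed = 42)
#> stage encode: 1000 sequences of length 41
#> stage fuse: initial dimension 722
#> stage select: alpha 0.05, beta 0.5 -> 20 features
#> stage cv: 5-fold fold-safe cross-validation
#> stage cv: mean ACC 0.8830 AUC 0.9605

bundle$cv$mean
#> m6aMetrics @ 0.50: ACC 0.8830  Sn 0.8800  Sp 0.8860  MCC 0.7667  AUC 0.9605
#>   (TP 440 TN 443 FP 57 FN 60)

m6a_predict(bundle, sim$sequences[1:3])
#>      id probability label
#> 1 seq_1   0.9933418     1
#> 2 seq_2   0.9969329     1
#> 3 seq_3   0.9442590     1
```

Reading the numbers: the fused 722-dimensional representation collapses to
20 informative features (the elastic net discards everything except the
planted position signals), and held-out accuracy/AUC of 0.88/0.96 reflect
the Bayes-limited separability of the 0.6-strength motif world — not
perfect, because the enrichment is probabilistic.

Real data enter through `read_sample_files("pos.fasta", "neg.fasta")`
(positives/negatives in two FASTA files; `T` is auto-mapped to `U`), and a
trained bundle persists as plain JSON via `save_bundle()` /
`load_bundle()`. Hyper-parameter tuning: pass
`tune = list(n_trials = 100)` to `m6a_train()`, or use `tpe_optimize()`
directly.

## Command line

```sh
Rscript inst/cli/m6afuse.R simulate --out sim --n-pos 500 --n-neg 500 --seed 1
Rscript inst/cli/m6afuse.R train --pos sim_pos.fasta --neg sim_neg.fasta --out bundle --seed 1
Rscript inst/cli/m6afuse.R predict --bundle bundle --fasta sim_pos.fasta --out scores.tsv --seed 1
Rscript inst/cli/m6afuse.R evaluate --bundle bundle --pos sim_pos.fasta --neg sim_neg.fasta --seed 1
```

Subcommands `sweep-params` (encoder-parameter grids) and `tune` (TPE) are
also available; see `?m6afuse_cli`.

## Documentation

The methods vignette (`vignettes/m6a-prediction-methods.Rmd`) describes the
model, its assumptions, the synthetic-data world, numerical choices and
limitations.
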