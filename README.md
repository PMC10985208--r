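# mircnn

Identification of plant miRNA precursors from small RNA-seq reads with
a convolutional neural network.

Plant miRNAs are 20–24 nt RNAs cut by Dicer-like enzymes from 100–200
nt hairpin precursors. Calling them from sequencing data is hard
because many siRNA precursors also fold into hairpins, so
structure-only rules produce abundant false positives. `mircnn`
implements the full calling pipeline — read collapsing and 20–24 nt
length filtering, exact-match mapping to both genome strands,
clustering, precursor-window excision and folding, a single-stem
hairpin screen, duplex-rule annotation — and classifies each candidate
with a small CNN trained on a joint representation of sequence,
structure and expression.

Each candidate precursor is encoded as a 7 × L matrix (L = 200): rows
1–4 one-hot A/U/C/G, rows 5–6 the pairing state (1 = paired,
0 = unpaired, 0.5 = gap/padding), row 7 the read coverage normalised
by the most abundant read. The network is

    conv 2×2 ×20 → ReLU → maxpool 2×2 → conv 2×2 ×60 → ReLU →
    maxpool 2×2 → FC 500 (identity) → FC 2 → softmax

trained with AdaDelta (ρ = 0.95, ε = 1e−6) on the negative log
likelihood, Xavier initialisation, dropout (retain 0.9) after each
hidden block, and minority-class oversampling to 1:1 inside each
training split of a stratified 5-fold cross-validation. Performance is
summarised by Accuracy = (TP+TN)/(TP+FP+FN+TN),
Precision = TP/(TP+FP), Recall = TP/(TP+FN) and
F1 = 2·TP/(2·TP+FP+FN), averaged over folds.

Candidate labelling follows the standard plant-miRNA annotation
criteria: a miRNA/miRNA\* duplex with at most five mismatched
positions of which at most three are nucleotides in asymmetric bulges,
no secondary stems or large loops, a 2-nt 3′ overhang star, and
precise processing (duplex reads ≥ 75 % of the locus read mass).
A seeded synthetic-data module generates toy genomes with planted
miRNA and siRNA-like loci so every stage is testable offline.

## Worked example

```r
library(mircnn)

# a toy study: 20 planted miRNA loci, 60 siRNA-like hairpin loci
spec <- simulation_spec(n_mirna_loci = 20, n_sirna_loci = 60, seed = 2)
ds   <- generate_dataset(spec, dir = "sim")

pipe <- mirna_pipeline(ds$genome, ds$paths$reads, format = "fastq")
#> reads: 654 unique sequences after length filter
#> mapping: 660 loci in 86 clusters
#> candidates: 768 windows, 85 hairpin candidates
#> labels: 25 miRNA / 60 other

score_recovery(pipe$candidates, ds$truth)[1:3]
#> $mirna_recovered
#> [1] 0.95
#> $mirna_labeled
#> [1] 0.95
#> $sirna_mislabeled
#> [1] 0.05
```

19 of the 20 planted miRNA loci are recovered as hairpin candidates
and labelled miRNA; 3 of 60 siRNA loci are mislabelled. (The 86
clusters exceed the 80 planted loci because perfectly complementary
duplexes also map on the opposite strand, creating a few mirrored
candidates.)
Training the classifier on a larger simulation:

```r
spec <- simulation_spec(n_mirna_loci = 400, n_sirna_loci = 1200, seed = 101)
ex   <- mirna_cv_experiment(spec, folds = 5, seed = 101)
ex$cv
#> 5-fold cross-validation (seed 101)
#> mean held-out metrics: accuracy 0.9493, precision 0.899, recall 0.9426, F1 0.9166
```

`predict(model, encoded, type = "prob")` returns per-candidate miRNA
probabilities for a fitted model; `summary()`, `plot()` (training
loss) and `print()` methods are available on fitted models and CV
results.

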