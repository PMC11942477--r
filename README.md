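# rnaduet

Dual-modality sequence + structure-vision modelling for RNA.

RNA function is driven by base pairing: which positions can pair, how
ambiguously, and in what nested arrangement.  Sequence-only language
models see none of this directly.  `rnaduet` computes, from the raw
sequence alone, a 24-channel L x L structural "image" — a Nussinov-style
maximum-matching map, pairing-ambiguity and A-U availability counts,
a Gaussian-decayed stacking-propensity matrix, positional/one-hot
distance maps, and Kronecker base-identity contact channels — and pairs
it with an overlapping k-mer token stream.  A BERT-style sequence
encoder and a hierarchical shifted-window (Swin-style) vision encoder
meet in self-/cross-attention fusion blocks, feeding either a sequence
classifier (ncRNA families, protein-RNA interaction) or a U-Net head
that predicts the L x L base-pair contact matrix.

The package is aimed at method developers who want the full feature
system, the architecture, base-pair evaluation metrics (PPV, SEN, F1,
MCC, ACC, AUROC, AUPRC), readers/writers for FASTA, dot-bracket, CT and
BPSEQ, and seeded synthetic benchmarks — all trainable and testable on
one CPU with no external downloads.  The neural network is a compact
reverse-mode implementation over base-R matrices with a C++ attention
kernel; it is meant for desk-scale experiments, not for pre-training.

## The core quantities

For a sequence of length L with pairing rules A-U, G-C, G-U and minimum
hairpin loop h = 3 (positions may pair when `j - i > h`):

* `LPSS[i,j]` — the maximum number of non-crossing admissible pairs
  inside fragment `[i..j]` (Nussinov maximum matching, all fragments).
* `SRS`/`BMS` — per base letter, how many positions in `[i..j]` have at
  least 2 admissible partners (ambiguity), or at least 1 A-U partner.
* `RCM[i,j]` — sum of `exp(-t^2/2) * w(pair)` along the potential helix
  through `(i,j)`, outward and inward to the first inadmissible offset
  (w = 2 / 3 / 0.8 for A-U / G-C / G-U).
* Distance maps and the 10 reduced base-identity contact channels.

Tokenization produces `L - k + 3` tokens (`[CLS]`, the L - k + 1
overlapping k-mers, `[SEP]`); with the default k = 3 and the default
L = 112, the fused classifier pools `C = L + L/16 = 119` positions.

## Worked example

```r
library(rnaduet)

s <- rna_sequence("GGGAGCAAAAGCUCCCAUAUAUAU")   # 24 bases
st <- build_feature_stack(s, normalize = FALSE)
st
#> <feature_stack> 24 channels of 24 x 24
st[1, 24, "LPSS"]
#> [1] 8
```

Eight non-crossing pairs fit in the full span: the 5-bp hairpin stem
(GGGAG..CUCCC) plus pairing the AU-rich tail onto the loop region.  The
stacking-propensity entry for the stem closing pair:

```r
round(st[4, 13, "RCM"], 4)
#> [1] 6.4845
```

(the G-C weight 3, plus decayed contributions from the admissible
neighbours along the helix).  Tokenize and inspect:

```r
tokenize_kmers(s, k = 3)
#> <token_sequence> 24 tokens (k = 3)   # 24 - 3 + 3
```

Score a predicted structure against truth (here truth vs itself):

```r
truth <- parse_dotbracket("(((((...)))))...........")
ppv_sen_f1(pair_confusion(truth, truth))
#> PPV SEN  F1
#>   1   1   1
```

Generate a seeded nested structure with a compatible sequence:

```r
random_structure(20, seed = 7)$dotbracket
#> [1] ".((.(....)..)(....))"
```

Train the toy dual-modality classifier on a seeded planted-motif task
(400 sequences of length 112, two motif classes, 5% motif noise):

```r
df  <- motif_dataset(synth_spec())
m   <- duet_model(toy_model_config(dropout = 0), "classify", n_classes = 2)
fit <- train_classifier(m, df, batch_size = 8, lr = 5e-4, adam_eps = 1e-4,
                        stop_acc = 0.9)
tail(fit$history, 1)   # stops once held-out accuracy reaches 0.9
```

A command-line interface covering `featurize`, `tokenize`, `synth`,
`train`, `predict` and `evaluate` is installed as `exec/rnaduet`:

```sh
rnaduet synth --config spec.yaml --output fixtures/
rnaduet featurize --input fixtures/classification.fasta --output features.rds
rnaduet train --task classify --input fixtures/classification.fasta \
        --labels fixtures/classification.tsv --output model.rds
rnaduet evaluate --task classify --input preds.tsv --truth truth.tsv \
        --output report.json
```

## Scope

Published benchmark-scale results require GPU pre-training on large
corpora and the original datasets; they are out of scope here.  The
pairing model is strictly nested (no pseudoknots).  See the methods
vignette (`vignettes/structure-vision-modelling.Rmd`) for the model
details, parameter defaults and design rationale.
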