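# chromint

Sequence-based prediction of plant chromatin interactions with a
CNN + transformer classifier, plus the interpretation toolkit that goes
with it: integrated-gradients attribution, continuous-run motif calling,
motif cooperation scanning, in-silico saturation mutagenesis, and
permutation-based interval enrichment.

## Who this is for

Plant regulatory genomicists who have (or want to emulate) chromatin
contact data — promoter–promoter pairs (PPI) or promoter–distal element
pairs (PDI, e.g. an ATAC peak and a candidate target promoter) — and want
to (i) train a classifier that predicts contacts from DNA sequence alone,
(ii) scan genomic regions into predicted interaction maps or ranked
target-gene lists, and (iii) ask *which bases* drive a predicted contact.

## The model

A pair of anchors is one-hot encoded (rows **A,T,G,C**; `N` → zero
column) and concatenated: 4×6000 for PPI (two 3 kb gene sequences: 1 kb
up + 0.5 kb down of the TSS, 0.5 kb up + 1 kb down of the TTS) or 4×3000
for PDI (1.5 kb distal element + 1.5 kb promoter). The network is

* convolution blocks `S_ij = Σ_u Σ_v W_uv X_{i−u+1, j−v+1}` with batch
  norm, ReLU and max pooling (first-layer filters are motif detectors),
* multi-head self-attention `softmax(QKᵀ/√d_k)V` over the pooled feature
  tokens (sinusoidal positional encoding, residual connection),
* a fully connected sigmoid head; a pair is called interacting when
  P(interaction) > 0.5.

Training is binary cross-entropy + Adam, written entirely in this
package (R over compiled Armadillo kernels), so exact input gradients
are available for attribution. Every backward pass is verified against
finite differences in the test suite.

## Worked example

Train on the built-in synthetic benchmark (a planted motif-pair AND
grammar: positives carry `TGACGTCATC` in anchor A *and* `CACGTGGCTA` in
anchor B; negatives are background or single-motif sequences), then
recover the planted motifs from the fitted model:

```r
library(chromint)

d   <- generate_pairs(synth_config(seed = 1))       # 2000 pairs, 500 bp anchors
cfg <- ctci_config(input_len = 1000, seed = 101)    # "simple" preset
fit <- ctci_fit(d$x[1:1600, , ], d$labels[1:1600], cfg, validation = 0.1)
fit
#> Sequence pair classifier (conv + self-attention)
#>   input width : 1000 bp
#>   trained on  : 1440 pairs, seed 101
#>   epochs run  : 60  (best: 39 )
#>   val AUC     : 0.965

ctci_evaluate(fit, d$x[1601:2000, , ], d$labels[1601:2000])$auc
#> [1] 0.9450125

pos <- which(d$manifest$label_true == 1)[1:30]
mine_motifs(fit, d$x[pos, , ], r = 0.2, N = 5, top_n = 3)[, c("motif", "score")]
#>       motif     score
#> 32 CACGTGGC 0.8024012
#> 43 CACGTGGC 0.7904261
#> 27 CACGTGGC 0.7730552
```

The held-out AUC says the classifier genuinely learned the cross-anchor
grammar (an OR detector cannot exceed ~0.75 here), and the top calls are
exact substrings of the planted motifs, read directly off the model's
input-gradient attributions (`TGACGTCA...` calls follow just below the
top three; `mine_motifs(..., top_n = 10)` shows both planted motifs).

Region scanning and target ranking follow the same pattern
(`predict_region_map()`, `rank_targets()`, `pdi_candidate_pairs()`), and
`saturation_mutation()` / `cooperation_scan()` / `motif_enrichment()`
interrogate a fitted model. A command-line wrapper is included:

```sh
Rscript inst/cli/chromint.R simulate --out sim --seed 1
Rscript inst/cli/chromint.R train --pairs sim/pairs.tsv --out model.rds
Rscript inst/cli/chromint.R motifs --model model.rds --pairs sim/pairs.tsv --top 10
```

See `vignettes/chromint-methods.Rmd` for the model, the benchmark
design, and every numerical choice.

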