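# modalign

Unsupervised integration of single-cell chromatin accessibility and gene
expression data into one joint 128-dimensional representation.

## The problem

scRNA-seq and scATAC-seq usually profile *different* cells: no pairing, no
shared cell counts, often separately annotated. Once accessibility peaks
are summarised into a cells-by-genes **gene activity** matrix, both
modalities share a gene vocabulary but are split by a large technical gap
— activity data is sparser, noisier and globally shifted. `modalign`
learns a joint latent space in which the two modalities mix while
cell-type structure survives, with no labels and no anchors, so that
labels, expression profiles and velocity inputs can be transferred across
modalities afterwards.

## The model

A single encoder `E` (fully connected → batch norm → ReLU → linear,
128-d latent) is trained with three cooperating objectives:

1. **Contrastive (NCE) loss** on two stochastically corrupted views of
   each batch, applied per modality through a 32-d linear head
   (τ = 0.15) and a 25-d softmax head (τ = 0.5):

   ℓᵢⱼ = −log [ exp(cos(zᵢ, zⱼ)/τ) / Σₖ≠ᵢ exp(cos(zᵢ, zₖ)/τ) ]

2. **Adversarial domain adaptation**: discriminator `D_rna` guesses the
   modality of each latent code; the encoder learns to defeat it,
   collapsing the modality difference.
3. **Cycle-consistent adversarial branch**: generator `G` maps RNA latent
   codes to activity-like data judged by `D_atac`, and the
   cycle-consistency loss ‖E(G(z)) − z‖² forces generated data to
   re-encode to its source code. The cycle is RNA-centred by design.

Training is plain SGD (lr 0.005, weight decay 0.0005, 100 epochs by
default), alternating one discriminator step with one
encoder/heads/generator step. Everything — networks, backpropagation,
optimiser — is implemented in base R on BLAS matrices, seeded and
single-threaded, so runs reproduce bitwise.

The package also ships the full benchmark framework (modality silhouette
1 − |S| and cell-type silhouette (1 + S)/2 on a common 2-D UMAP,
bidirectional linear-SVM label-transfer macro F1, the weighted aggregates
S_overall = 0.7·S_celltype + 0.3·S_modality, F1_overall and R_overall,
Wilcoxon-based method comparison) and a synthetic dual-modality generator
for offline testing.

## Worked example

```r
library(modalign)

data <- simulate_multiome(synthetic_spec(seed = 1))   # 4 types, 500+500 cells
pair <- preprocess_pair(data$rna, data$atac)          # log1p, HVG, harmonise
fit  <- train(pair,
              network_spec(input_dim = length(pair$features), init_seed = 1),
              train_config(epochs = 50, batch_size = 128, seed = 1))
emb  <- embed_all(fit, pair, data$labels_rna, data$labels_atac)
evaluate_integration(emb, subsample_frac = 1, seed = 1)
```

```
# A tibble: 1 x 8
  method   S_celltype S_modality f1_rna_to_atac f1_atac_to_rna S_overall F1_overall R_overall
  <chr>         <dbl>      <dbl>          <dbl>          <dbl>     <dbl>      <dbl>     <dbl>
1 modalign      0.839      0.902          0.918              1     0.858      0.959     0.909
```

Read: after 50 epochs the two modalities overlap almost perfectly in the
embedding (modality silhouette 0.90; 1 would be perfect mixing), the four
simulated cell types stay cleanly separated (cell-type silhouette 0.84),
and a linear SVM trained on one modality annotates the other nearly
perfectly in both directions (macro F1 0.92 RNA→ATAC, 1.00 ATAC→RNA).
`autoplot(emb)` draws the embedding coloured by modality and type;
`autoplot(fit)` shows the loss curves; `tidy(fit)` / `glance(fit)` give
the training history in broom style.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/modalign.R simulate  --outdir data --seed 1
Rscript inst/cli/modalign.R integrate --rna data/rna --atac data/atac \
    --labels_rna data/labels_rna.tsv --labels_atac data/labels_atac.tsv \
    --outdir run --epochs 50 --batch_size 128 --seed 1
Rscript inst/cli/modalign.R evaluate  --embedding run/embedding.tsv --outdir run
```

See `vignettes/integration-methods.Rmd` for the model, the synthetic
generator's assumptions, and every design decision.

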