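# crossddi

Cross-view contrastive learning for drug–drug interaction (DDI) prediction
in R.

Co-administered drugs can interact, changing each other's pharmacological
effect, and predicting which pairs interact from chemical structure alone is
a standard task in computational pharmacology. `crossddi` predicts a binary
interaction label for a drug pair from the two complementary representations
every drug already has:

- **graph view** — the molecule is decomposed into BRICS pharmacophore
  subgraphs; each subgraph's one-hot atom and bond features are projected to
  a common width *d*, stacked into a token matrix
  *X′ = [X′_V ‖ X′_E]*, encoded by multi-head self-attention
  (softmax(QKᵀ/√d_k)V per head, heads concatenated through W^O, with the
  usual residual/feed-forward/layer-norm sublayers), and pooled by a
  two-stage mean into the molecule embedding **z_mol**;
- **sequence view** — the SMILES string is tokenized at the atom level and
  encoded by a BERT-style transformer (token embedding + learned positional
  embedding, self-attention layers, mean pooling) into **h_mol**.

During training a cross-view contrastive loss pulls a drug's two view
embeddings together and pushes different drugs apart. For a pair of drugs A
and B with cosine similarity *s*:

```
L = −log [ (e^{s(z_A,h_A)/τ} + e^{s(z_B,h_B)/τ}) /
           (e^{s(z_A,z_B)/τ} + e^{s(z_A,h_B)/τ} + e^{s(h_A,z_B)/τ} + e^{s(h_A,h_B)/τ}) ]
```

(the denominator holds only the four cross-drug pairs; an NT-Xent-style
batch mode is available as a documented alternative). The two views are then
fused per drug by bidirectional cross-attention, and a sigmoid MLP scores
the concatenated pair `ŷ = σ(MLP([d_A ; d_B]))`.

The package also ships the full evaluation protocol — stratified warm-start
cross-validation, drug-disjoint cold-start splits with per-split negative
sampling, confusion metrics / AUROC / AUPRC, Kruskal–Wallis + Mann–Whitney +
Holm–Bonferroni model comparison, an ablation runner — and a synthetic
molecule/interaction generator with a plantable substructure-pair rule, so
the entire pipeline is testable without any external dataset. See the
methods vignette (`vignettes/crossview-ddi-methods.Rmd`) for the model
details and design decisions.

## Worked example

```r
library(crossddi)

# parse and decompose a molecule
mol <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O", drug_id = "aspirin")
dec <- brics_decompose(mol)
dec
#> <decomposed_molecule> aspirin: N = 4 pharmacophore(s), 3 cleaved bond(s)
```

Aspirin splits into four pharmacophores — the acetyl group (atoms 0–2), the
ester oxygen (atom 3), the benzene ring (atoms 4–9) and the carboxyl group
(atoms 10–12) — exactly the cleavages a BRICS reference implementation
produces.

```r
# a self-contained benchmark: 80 synthetic drugs, 600 labelled pairs,
# positives driven by a planted fragment-pair rule with 10% label noise
ds <- synth_dataset(n_drugs = 80, n_pairs = 600, noise = 0.1, seed = 42)
split <- make_warm_split(ds$triplets, k = 5, seed = 1)

cfg <- ddi_config(d = 32, graph = list(heads = 4, layers = 2),
                  seq = list(heads = 4, layers = 2),
                  fusion = list(d_f = 64), predict = list(hidden = 64),
                  train = list(epochs = 45, epochs_cl = 5, batch_size = 64),
                  seed = 1)
fit <- train_model(ds$drugs, split, cfg)
fit
#> <ddi_fit> variant=full | best val AUROC 0.7930 | test:
#> <metrics_report> n=121 @0.50 | TP=36 FN=14 FP=7 TN=64 | ACC=0.8264
#>   AUROC=0.8239 AUPRC=0.8429 F1=0.7742 P=0.8372 R=0.7200
```

The fit reports the confusion counts at threshold 0.5 on the held-out fold
together with accuracy, AUROC, AUPRC, F1, precision and recall. With 10%
label noise the best achievable AUROC against the noisy labels is about
0.90 (see the vignette), so 0.82 on this small 80-drug instance means most
of the planted signal is recovered; at the full benchmark scale (300 drugs,
3000 pairs) the model reaches ≈ 0.86–0.89.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/crossddi.R synth --n-drugs 300 --n-pairs 3000 --noise 0.1 --seed 7 --out-dir data/
Rscript inst/cli/crossddi.R split --ddis data/ddis.tsv --mode warm --k 5 --seed 1 --out split.json
Rscript inst/cli/crossddi.R train --drugs data/drugs.tsv --split split.json \
    --d 32 --epochs 45 --epochs-cl 5 --batch-size 64 --seed 1 --out report.json
```

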