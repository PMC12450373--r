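# protlora

Parameter-efficient fine-tuning (LoRA) of per-residue protein sequence
encoders, and a benchmark suite for judging whether fine-tuning improved
the resulting embeddings.

Protein language models embed each residue of a sequence as a vector;
averaging the residue vectors gives a pooled, sequence-level embedding.
Models pre-trained on general protein databases represent viral proteins
poorly: pooled embeddings of unrelated viral proteins look almost as
similar as embeddings of true orthologs. Low-rank adaptation (LoRA)
counters this cheaply: the pre-trained weights `W` are frozen and each
adapted projection learns a rank-r update

```
h = W x + (alpha / r) * B A x
```

with only the factors `A` (r x d) and `B` (d x r) trainable — here with
rank r = 8 on the query/key/value attention projections. `protlora`
implements this scheme on a compact, deterministic reference transformer
(forward pass, explicit backpropagation and Adam in native R), three
fine-tuning objectives, and the evaluation protocol:

* **Objectives** — masked-token prediction (15% of positions selected,
  masking probability 0.8, loss `-sum log P(true token | context)`);
  orthologous-group classification (affine head on the pooled embedding,
  cross-entropy); contrastive triplet learning (anchor / same-group
  positive / other-group negative) with a hybrid cosine-MSE pair loss
  driving anchor-positive cosine toward 1 and anchor-negative toward 0.
* **Benchmarks** — pooled within-group pairwise cosine similarity;
  conserved-column detection in MSAs (< 5% unknowns, <= 4 residue
  types, >= 70% majority) with conserved-site versus well-separated
  random-site residue similarity (`|p_i - p_j| > 20`); bootstrap
  density-based clustering (HDBSCAN*, implemented natively) scored by
  silhouette `S(i) = (b(i) - a(i)) / max(a(i), b(i))` with a best-case
  maximum across iterations; embedding-driven pairwise soft alignments
  scored by the longest homologous residue path (mutual nearest
  neighbors + longest increasing subsequence; filter: path > 18,
  sequences < 1,024 residues); and MSA quality via mean mutual
  information (bits) and column occupancy.
* **Synthetic ortholog families** — a seeded generator emulating
  orthologous groups with conserved motif blocks, point substitutions at
  a configurable rate (default 0.5), optional indels, and ground-truth
  alignments and conserved columns, so everything runs end-to-end with
  no external database.

## Worked example

```r
library(protlora)

gen <- generate_families(synthetic_family_config(seed = 0))  # 30 x 12
sp  <- stratified_split(gen$data, 0.1, seed = 0)
enc <- build_reference_encoder(encoder_config(seed = 0))     # d = 32, 2 layers
ad  <- inject_lora(enc, lora_config(init_seed = 0))          # r = 8 on q/k/v
ad
#> <plm_adapted> d=32, 2 layers, r=8 on {query,key,value}, 3072 trainable LoRA params

fit <- train(ad, subset_groups(gen$data, sp$train_ids),
             train_config("CON", learning_rate = 1e-3,
                          epochs = 10, max_steps = 200, seed = 0))
fit$history$train_loss
#> [1] 0.6200870 0.5518430 0.5383398

trip <- heldout_triplets(gen$data, sp$test_ids, 200, seed = 123)
emb0 <- embed_dataset(ad, gen$data, residues = FALSE)$pooled
emb1 <- embed_dataset(fit$encoder, gen$data, residues = FALSE)$pooled
triplet_cosine_gap(emb0, trip)$gap   # untrained encoder
#> [1] 0.01925382
triplet_cosine_gap(emb1, trip)$gap   # after 200 contrastive steps
#> [1] 0.2464271
```

The training loss falls over the 200 optimizer steps (per-epoch values
evaluated on a fixed held-back batch), and the gap between
anchor-positive and anchor-negative cosine similarity on held-out
anchors grows from ~0.02 to ~0.25: the fine-tuned encoder separates
ortholog families that the untrained encoder conflates. Only the 3,072
LoRA parameters moved; the base weights are bitwise unchanged
(`identical(fit$encoder$base, ad$base)` is `TRUE`).

A command-line front end over the same functions is installed at
`inst/cli/protlora.R` (`simulate`, `finetune`, `embed`,
`bench-pairwise`, `bench-cluster`, `bench-align`, `report`); every
command writes its artifacts plus a `manifest.json` echoing the resolved
configuration and seeds.

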