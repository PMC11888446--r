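# curriculab

Curriculum learning for antibody language models (AbLMs), at desk scale.

## The problem

Antibody language models are increasingly pre-trained on a mixture of
*unpaired* chains (heavy or light alone, available in the hundreds of
millions) and *natively paired* heavy/light sequences (available in the low
millions). Paired sequences teach cross-chain features that unpaired data
cannot, but naively switching from unpaired pre-training to paired
finetuning invites catastrophic forgetting of the unpaired domain.
Curriculum training replaces the hard switch with a gradual one: at
training step `s` (with `t = s / total_steps`), each example in the batch
is drawn from the unpaired pool with probability

```
P(t) = B − A / (1 + exp(−k · (t − shift)))
```

a sigmoid decay from near `B` down to near `B − A` with slope `k`. The
midpoint `shift` is not free: it is **calibrated** (by bisection, the mean
being strictly increasing in `shift`) so that the discrete mean of `P(t)`
over all steps equals the prescribed total unpaired data budget — 62.5%
for the optimized configuration, whose range is 0.7 to 0.3 (`B = 0.7`,
`A = 0.4`) with `k = 15`.

The package implements the full experimental apparatus around that idea,
runnable on one CPU with no external data:

* **Synthetic repertoires** — seeded V(D)J-style assembly of heavy
  (115-130 aa) and light (105-115 aa) chains with FR1-FR4/CDR1-3 region
  annotations, naive/memory mutation states, native pairing, and optional
  specificity class labels with learnable CDR3-motif signal.
* **Tokenization** — the 33-token ESM-2-style vocabulary with a
  configurable chain separator (`<sep>`, reused `<cls>`, or none),
  fixed 320-token padding, greedy identity clustering for deduplication,
  and 96/2/2 train/eval/test splitting.
* **Schedules** — the curriculum curve plus the four reference strategies
  (constant mixing, unpaired-then-paired finetuning, unpaired-only,
  paired-only), all matched on the same data budget; linear, WSD and SGDR
  learning-rate schedules.
* **Sampling & collation** — binomial per-step batch composition,
  epoch-wise shuffling without replacement, and the 15% / 80-10-10 masked
  language-model collator.
* **Encoder** — a small bidirectional transformer (tied embeddings,
  pre-layer-norm, selectable rotary or absolute positional embeddings)
  with a hand-derived backward pass and AdamW, plus a seeded training
  loop that logs paired and unpaired evaluation losses separately.
* **Evaluation & tasks** — cross-entropy/accuracy excluding structural
  tokens, per-region CE and CDRH3 accuracy via single-position masking,
  native-vs-random pair classification with mutation subsets, balanced
  specificity classification, and a cross-validated metric battery
  (accuracy, F1, AUC, AUPR, MCC, each mean ± SE over stratified folds).

## Worked example

Calibrate the optimized schedule, pre-train a tiny rotary encoder on a
synthetic repertoire, and finetune a specificity classifier:

```r
library(curriculab)

cfg <- curriculum_config(B = 0.7, A = 0.4, k = 15, total_steps = 100000,
                         target_unpaired_fraction = 0.625)
cfg
#> <curriculum_config> P(t) = 0.7 - 0.4 / (1 + exp(-15 (t - 0.816624)))
#>   100000 steps, target unpaired fraction 0.625 (mean P = 0.625)
```

The solver places the sigmoid midpoint at 81.7% of training so that the
curve — which starts near 0.7 and decays toward 0.3 — averages exactly
0.625 over all steps.

```r
rep <- generate_repertoire(n_paired = 160, n_unpaired_heavy = 200,
                           n_unpaired_light = 80, seed = 7)
vocab <- build_vocabulary("unique_sep")
tok_p <- lapply(rep$paired,   tokenize_record, vocab = vocab)
tok_u <- lapply(rep$unpaired, tokenize_record, vocab = vocab)
sp <- split_train_eval_test(tok_p, 0.9, seed = 1)
su <- split_train_eval_test(tok_u, 0.9, seed = 2)

model <- build_encoder(encoder_config(), seed = 1)   # 2 layers, hidden 64, RoPE
sched <- make_schedule("curriculum", target_unpaired_fraction = 0.625,
                       total_steps = 400)
run <- train(model,
             list(unpaired = su$train, paired = sp$train,
                  eval_unpaired = su$eval, eval_paired = sp$eval),
             train_run_config(400L, 8L, schedule = sched, seed = 3), vocab)
run
#> <ablm_train_run> 400 steps, batch 8 (curriculum schedule)
#>   realized unpaired fraction: 0.6219 (schedule target 0.6250)
#>   eval CE unpaired: 3.4786 -> 2.0000 | paired: 3.4909 -> 1.9496
```

The untrained model scores at the uniform baseline `ln 33 ≈ 3.50` per
masked position; 400 steps on germline-structured synthetic chains pull
held-out CE down to ~2.0 on both data types, and the realized unpaired
sampling fraction tracks the calibrated budget.

```r
pools <- list(
  HD  = generate_repertoire(0, 80, 0, seed = 21, specificity = "HD")$unpaired,
  Flu = generate_repertoire(0, 80, 0, seed = 22, specificity = "Flu")$unpaired,
  CoV = generate_repertoire(0, 80, 0, seed = 23, specificity = "CoV")$unpaired)
task <- build_specificity_dataset(pools, identity_threshold = 0.99, seed = 5)
res <- finetune_classifier(build_encoder(encoder_config(), seed = 1), task,
                           vocab, epochs = 25, batch_size = 16,
                           peak_lr = 5e-3, seed = 6)
res$metrics
#> <classifier_metrics> mean +/- SE over 5 folds
#>   accuracy  0.6839 +/- 0.0124
#>   f1        0.6833 +/- 0.0134
#>   auc       0.8250 +/- 0.0058
#>   aupr      0.7202 +/- 0.0118
#>   mcc       0.5286 +/- 0.0195
```

The generator plants class-specific CDR3 motifs and V-gene usage bias, so
a correct pipeline must classify well above the 1/3 chance level — here
68% accuracy from mean-pooled representations of an *untrained* encoder,
confirming the task construction carries signal.

A complete seeded experiment (generate → tokenize → schedule → train →
evaluate, with a reproducibility manifest) is driven by one YAML file:

```r
run_experiment(system.file("extdata", "tiny_curriculum.yaml",
                           package = "curriculab"), "out/")
```

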