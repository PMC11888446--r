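---
title: "Curriculum pre-training for antibody language models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curriculum pre-training for antibody language models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curriculab)
```

## The model

Antibody variable domains arise from somatic recombination of germline V
and J segments, a largely non-templated CDR3 junction, and somatic
hypermutation. Language models of antibodies are pre-trained with a
masked-token objective on either *unpaired* single chains (abundant) or
*natively paired* heavy/light sequences (scarce but richer: only they can
teach cross-chain structure). Mixing the two is attractive, but training
first on one and then the other risks catastrophic forgetting.

The curriculum approach treats the mixture as a per-step sampling
probability. At step `s` of `N`, with `t = s/N`, an example is drawn from
the unpaired pool with probability

$$P(t) = B - \frac{A}{1 + e^{-k\,(t-\mathrm{shift})}}$$

and from the paired pool otherwise. `B` is the upper asymptote, `A` the
height of the decay (so the curve runs from near `B` down to near
`B - A`), `k` the slope, and `shift` the midpoint as a fraction of
training. A stated range such as "0.7 to 0.3" refers to the asymptotic
bounds (`B = 0.7`, `A = 0.4`); at `t = 0, 1` the curve is near but not
exactly at the endpoints for moderate `k` — that is a property of the
sigmoid, not an approximation made here.

### Calibration

`shift` is determined, not chosen: `solve_shift()` finds the value for
which the *discrete* mean of `P` over steps `0..N-1` equals the total
unpaired data budget (0.625 in the optimized configuration: with `B = 0.7`,
`A = 0.4`, `k = 15`, `N = 100{,}000` the solver places the midpoint at
`shift ≈ 0.817`). Two numerical choices matter:

* **Discrete vs continuous mean.** The budget is interpreted as the mean
  of `P` over actual training steps (`t = s/N`), equivalently the expected
  fraction of all training examples that are unpaired. The continuous
  integral differs by `O(1/N)`; at pre-training scale the distinction is
  invisible, but the discrete form is the one the sampler realizes.
* **Bisection.** The mean is strictly increasing in `shift` (delaying the
  decay keeps `P` near `B` longer), so bisection is exact. We search
  `shift ∈ [-1, 2]` — wider than `[0, 1]` so that extreme slopes with
  saturated curves remain solvable — to a tolerance of `1e-9` on the mean,
  capped at 200 iterations. Targets outside `[B - A, B]` are rejected up
  front with the attainable interval in the error message.

### Schedule variants

`make_schedule()` expresses the five training strategies under a common
interface, all matched on the same data budget: the calibrated
`curriculum`; `constant` (`P ≡` budget); `finetuned` (`P = 1` for the
first `round(budget · N)` steps, then 0 — the classic pre-train/finetune
switch); and the `unpaired_only` / `paired_only` controls. Matching the
discrete means (within `1/(2N)`, the rounding granularity of the switch
step) is what makes the strategies comparable: they see the same total
amount of each data type, differing only in its arrangement over time.

### Learning-rate schedules

Three schedules are provided: linear warmup/decay (default: the
pre-training recipe is peak 4e-4 with 6,000 warmup steps), warmup-stable-
decay (WSD), and cosine annealing with warm restarts (SGDR). The WSD decay
fraction (default 0.2 of total steps) and SGDR cycle count (default 3) are
exposed configuration values; the literature on these schedules does not
pin a single canonical setting, so the defaults are deliberate and visible
rather than hidden constants.

## Data representation

The vocabulary is the 33-token ESM-2 set. With the `unique_sep` policy,
the base vocabulary's unused `<null_1>` placeholder is replaced by
`<sep>`, keeping the size at 33 and every other token id stable; with
`reuse_cls`, `<cls>` doubles as the separator; `none` omits separators.
Separator placement encodes chain identity: between the chains of a
paired input, at the *end* of an unpaired heavy chain, at the *beginning*
of an unpaired light chain — mirroring where each chain sits in a paired
input. Inputs are framed by `<cls>`/`<eos>` and padded to 320 tokens, the
length that accommodates the longest paired sequence. Whether an `<eos>`
token is used at all is a representational free choice; this
implementation includes one, and the invertibility of the layout is
enforced by tests.

Region annotations travel with every sequence as 0-based half-open
intervals that tile the chain, in both residue and token coordinates
(prefixed `H-`/`L-` after tokenization).

### Deduplication stand-in

`filter_and_dedup()` removes records containing the literal substring
`"nan"` (a tabular-export artifact) or non-alphabet characters, then
performs greedy centroid clustering in input order with identity defined
as position-wise matches over the shorter length divided by the longer
length — no alignment. This is a deliberate desk-scale simplification:
it supports the *semantics* tests need (exact and near duplicates
collapse; retained centroids are mutually below threshold) but is not a
replacement for profile-based clustering of real repertoires.

### Splitting

`split_train_eval_test()` shuffles (seeded) and takes the training
fraction (0.96 by default); the holdout is divided half-and-half between
evaluation and test, the evaluation set receiving the odd item. The
50/50 division of the holdout is a choice this package makes explicit.

## The synthetic repertoire generator

The generator defines the data conditions everything else is tested
under. Each chain is assembled from a built-in library (4 V and 2 J
segments per chain type, human-germline-like but synthetic) plus a
uniform-random CDR3 junction, then mutated. Defaults, chosen once as
plausible desk-scale settings:

| parameter | default | rationale |
|---|---|---|
| heavy chain length | 115-130 aa (V 99 + CDR3 5-20 + J 11) | typical VH span |
| light chain length | 105-115 aa (V 90 + CDR3 5-15 + J 10) | typical VL span; light CDR3s are shorter than heavy ones |
| `naive_fraction` | 0.5 | repertoires mix naive and memory B cells; both chains of a pair share the state |
| `mutation_rate` | 6 per memory chain | amino-acid-level SHM load of a memory sequence |
| mutation count law | Poisson(`mutation_rate`) truncated to ≥ 1 | simple, seedable, mean-parameterized |
| CDR3 junction | uniform length, uniform residues | emulates non-templated diversity without biological claims |

Specificity labels (`HD`, `Flu`, `CoV`) optionally add learnable signal:
non-HD classes carry a class 3-mer motif in the heavy CDR3 (probability
0.8) and a biased V-segment choice (probability 0.6 for a preferred
segment). Without planted signal a specificity classifier has nothing to
learn and its pipeline cannot be validated.

What the generator does **not** emulate: nucleotide-level V(D)J junctional
biology, allele usage, SHM hotspot targeting, clonal lineage structure,
or the length/composition statistics of any real repertoire. Passing
tests therefore demonstrate that the *machinery* (sampling, collation,
optimization, evaluation, task construction) is correct and calibrated —
not that any particular accuracy would transfer to real antibody data.

## Sampling and MLM collation

Batch composition is binomial: `n_unpaired ~ Binomial(batch_size, P(t))`.
Per-example Bernoulli draws are unbiased for any probability, whereas
deterministic rounding would distort small batches. Each pool serves
indices without replacement within an epoch; epoch permutations are
seeded from `(base seed, pool name, epoch number)` so runs are exactly
reproducible regardless of how the two pools interleave.

The collator selects each *eligible* position independently with
probability 0.15; of the selected, 80% become `<mask>`, 10% a random
token, 10% stay unchanged. Two interpretations are fixed here:

* **Eligibility excludes structural tokens** (`<cls>`, separator,
  `<eos>`, padding). Evaluation excludes separators from all metrics, so
  training predictions on them would create a train/eval mismatch.
* **Random replacement draws a canonical residue different from the
  original** (mirroring how point mutation is defined). A "random"
  action therefore always changes the token, which makes the 80/10/10
  split directly measurable from token-id changes.

## The encoder harness

A pre-layer-norm bidirectional transformer with tied input/output
embeddings over the 33-token vocabulary. The desk-scale default (2
layers, 4 heads, hidden 64, intermediate 256 — ~100k parameters) trains
in minutes on one CPU; the 55M pilot configuration (5/20/960/3840) is
expressible through `encoder_config()` but is not exercised by the tests.

Positional information is either a learned absolute embedding table or
rotary embeddings (RoPE): query/key vectors are split into pairs and pair
`i` is rotated by `position · base^{-2i/d}` with base 10,000 (the
canonical convention). Rotation makes the attention dot product a
function of relative offset only, which is why a rotary model transfers
between single-chain inputs (~135 tokens) and paired inputs (~240
tokens) far better than an absolute-PE model; the package asserts the
relative-distance property numerically and the transfer asymmetry
behaviorally (shift-invariance under a prepended masked pad).

Implementation choices:

* Gradients are derived by hand and checked against central finite
  differences for every parameter tensor in both PE modes.
* The attention inner loops (softmax over key positions per batch
  element and head, forward and backward) are Rcpp/Armadillo kernels;
  everything else is R matrix algebra on BLAS.
* GELU uses the sigmoid form `x·σ(1.702x)`.
* Optimizer: AdamW (β₁ = 0.9, β₂ = 0.98, ε = 1e-8, weight decay 0.01 on
  weight matrices and embeddings, never on biases or layer-norm
  parameters). These are explicit config values, standard for this
  architecture family.
* Initialization N(0, 0.02²) from a seed; two builds with one seed are
  parameter-identical.
* Each training step processes the unpaired and paired examples of a
  batch as separate sub-batches truncated to their own maximum length,
  accumulating gradients into a single AdamW update — unpaired chains
  are about half the length of paired inputs, and padding them to the
  paired length would roughly double the attention cost for no change
  in the computed gradient.

Training logs the two data types separately: held-out paired and
unpaired sets are masked once with a fixed seed and re-evaluated at
intervals, so evaluation CE is comparable across checkpoints.

## Evaluation conventions

Cross-entropy and accuracy average over *labeled* positions only;
structural tokens are never labeled, so perturbing a model's output at
those positions cannot change a metric (tested directly). An untrained
model scores at the uniform baseline `ln 33 ≈ 3.50`.

Per-region CE and CDRH3 accuracy use single-position masking: one
position is hidden at a time with the rest of the sequence visible.
CDRH3 accuracy is micro-averaged (all (sequence, position) pairs pooled);
a per-sequence macro average is available via `average = "macro"`. Micro
is the default because region lengths vary and the pooled form weights
every prediction equally.

## Downstream tasks

**Pair classification.** Natives are labeled 1; negatives are built by a
derangement of the light chains (no light chain keeps its native
partner), giving an exact 50/50 balance and guaranteeing no accidental
native pair re-forms. Each example carries its mutation subset — both
chains mutated, both unmutated, or one of each (a chain is "mutated" iff
its count is ≥ 1, i.e. naive ⇔ unmutated) — since mixed-mutation
negatives are detectably easier and should be reported separately.

**Specificity classification.** Per class: greedy clustering at the
task's identity threshold (0.99 for the three-class task, 0.95 for the
two-class task), then seeded downsampling of every class to the smallest
clustered class so classes are exactly balanced, then stratified 5-fold
assignment (per-class counts across folds differ by at most one). The
unpaired variant keeps only heavy chains.

**Metrics.** Accuracy, F1 (binary, or macro one-vs-rest for C > 2), ROC
AUC (via pROC), area under the precision-recall curve (average
precision), and the Matthews correlation coefficient (the generalized
multi-class form, which reduces to the familiar binary formula), each
reported as mean ± standard error (sample SD across folds / √k). Folds
where AUC/AUPR is undefined (single-class fold) are excluded from that
metric's mean with a warning. Implementations are tested against
exhaustive small confusion-matrix oracles, a rank-statistic AUC oracle,
and a hand-worked average-precision case.

**Finetuning.** A two-layer (dense-tanh-dense) head on mean-pooled final
hidden states, trained per fold with AdamW under warmup/linear-decay.
Defaults mirror the specificity recipe (warmup ratio 0.1, peak 5e-5);
the pair-task recipe is peak 1e-5 for 50 epochs. The encoder itself
stays frozen here: at desk scale the representations are small and
head-only training keeps the cross-validation loop in seconds while
exercising the identical task, fold, and metric machinery.

## Problem sizes and limitations

The test suite runs everything at deliberately small sizes: repertoires
of a few hundred sequences, encoders of 10⁴-10⁵ parameters, training
runs of 10²-2×10³ steps (the end-to-end demonstration trains the default
2-layer/hidden-64 rotary encoder for 2,000 steps at batch 4, enough for
held-out CE to fall well below the uniform baseline while the realized
unpaired fraction stays within its binomial tolerance of the calibrated
budget). Calibration, conservation, and metric properties are exact at
any scale and are asserted at tolerances 1e-6 or tighter; absolute loss
values, by contrast, depend on model capacity and data realism and are
only checked directionally. Nothing here attempts to reproduce
full-scale pre-training results on real repertoire databases — that is
precisely the part that requires GPU-scale compute and real data, and it
is out of scope by design.
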