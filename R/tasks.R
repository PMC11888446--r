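#' Mutation-status subset of a pair
#'
#' Pairs are split by the somatic-mutation status of their chains: both
#' chains mutated (`mutated`), both unmutated (`unmutated`), or one
#' mutated and the other not (`different`). A chain counts as mutated when
#' its `mutation_count >= 1`, i.e. naive equals unmutated.
#'
#' @param pair A [paired_record()].
#' @return One of `"mutated"`, `"unmutated"`, `"different"`.
#' @export
assign_mutation_subset <- function(pair) {
  stopifnot(inherits(pair, "paired_record"))
  h <- pair$heavy$mutation_count > 0L
  l <- pair$light$mutation_count > 0L
  if (h && l) "mutated" else if (!h && !l) "unmutated" else "different"
}

# Sample a derangement (permutation without fixed points) by rejection;
# for n >= 2 the success probability tends to 1/e, so this terminates fast.
sample_derangement <- function(n) {
  if (n < 2L) stop_config("cannot derange fewer than 2 elements")
  repeat {
    perm <- sample.int(n)
    if (!any(perm == seq_len(n))) return(perm)
  }
}

#' Build the native-vs-random pair classification task
#'
#' Every native pair enters with label 1; an equal number of label-0
#' examples is built by re-pairing each heavy chain with the light chain
#' of another record via a derangement of the light chains, so no light
#' chain keeps its native partner and class balance is exactly 50/50.
#' Each example is annotated with its mutation subset
#' ([assign_mutation_subset()]).
#'
#' @param pairs List of native [paired_record()]s (at least 2).
#' @param seed Integer seed for the derangement.
#' @return An object of class `ab_task`: `records` (list of
#'   [paired_record()]), `label` (1 native / 0 random), `subset`, and
#'   (after [stratified_kfold()]) `fold`.
#' @export
build_pair_classification <- function(pairs, seed = 42L) {
  n <- length(pairs)
  if (n < 2L) stop_config("need at least 2 native pairs to build negatives")
  stopifnot(all(vapply(pairs, inherits, logical(1), "paired_record")))
  perm <- with_seed(derive_seed(seed, "pair-derangement"), sample_derangement(n))
  negatives <- lapply(seq_len(n), function(i) {
    paired_record(pairs[[i]]$heavy, pairs[[perm[i]]]$light,
                  pair_id = sprintf("%s x %s", pairs[[i]]$pair_id,
                                    pairs[[perm[i]]]$pair_id),
                  is_native = FALSE)
  })
  records <- c(pairs, negatives)
  structure(list(
    records = records,
    label = rep(c(1L, 0L), each = n),
    subset = vapply(records, assign_mutation_subset, character(1)),
    fold = NULL
  ), class = "ab_task")
}

#' @export
print.ab_task <- function(x, ...) {
  cat(sprintf("<ab_task> %d examples, %d classes%s\n", length(x$records),
              length(unique(x$label)),
              if (is.null(x$fold)) "" else sprintf(", %d folds", max(x$fold))))
  print(table(label = x$label))
  invisible(x)
}

#' Build a balanced specificity classification dataset
#'
#' Per class: cluster/deduplicate with [filter_and_dedup()] at
#' `identity_threshold` (0.99 for the three-class HD/Flu/CoV task, 0.95
#' for the two-class HD/CoV task), then downsample every class to the size
#' of the smallest clustered class so classes are exactly balanced, and
#' assign stratified folds. For the unpaired task variant set
#' `heavy_only = TRUE` to keep only the heavy chain of paired records.
#'
#' @param class_pools Named list mapping class name to a list of
#'   [paired_record()] or [antibody_sequence()] objects.
#' @param identity_threshold Clustering identity threshold.
#' @param seed Integer seed (downsampling and fold assignment).
#' @param k Number of stratified cross-validation folds.
#' @param heavy_only Keep only heavy chains of paired records.
#' @return An `ab_task` with integer labels 0..C-1 following the order of
#'   `names(class_pools)`, and fold assignments.
#' @export
build_specificity_dataset <- function(class_pools, identity_threshold = 0.99,
                                      seed = 42L, k = 5L, heavy_only = FALSE) {
  if (length(class_pools) < 2L) stop_config("need at least 2 classes")
  if (is.null(names(class_pools))) stop_config("class_pools must be named")
  clustered <- lapply(names(class_pools), function(cls) {
    kept <- filter_and_dedup(class_pools[[cls]], identity_threshold)
    if (length(kept) == 0L) {
      stop_config(sprintf("class '%s' is empty after clustering", cls))
    }
    kept
  })
  names(clustered) <- names(class_pools)
  n_min <- min(lengths(clustered))
  records <- list(); labels <- integer(0)
  with_seed(derive_seed(seed, "specificity-balance"), {
    for (ci in seq_along(clustered)) {
      keep <- sort(sample(length(clustered[[ci]]), n_min))
      sel <- clustered[[ci]][keep]
      if (heavy_only) {
        sel <- lapply(sel, function(x) if (inherits(x, "paired_record")) x$heavy else x)
      }
      records <- c(records, sel)
      labels <- c(labels, rep(ci - 1L, n_min))
    }
  })
  task <- structure(list(records = records, label = labels, subset = NULL,
                         fold = NULL), class = "ab_task")
  task$fold <- stratified_kfold(labels, k = k, seed = seed)
  task
}

#' Stratified k-fold assignment
#'
#' Partitions examples into `k` folds such that per-class counts across
#' folds differ by at most one: within each class, indices are shuffled
#' (seeded) and dealt round-robin.
#'
#' @param labels Vector of class labels (or an `ab_task`).
#' @param k Number of folds (>= 2); every class must have >= k members.
#' @param seed Integer seed.
#' @return Integer fold ids in 1..k (R convention), one per example.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 42L) {
  if (inherits(labels, "ab_task")) labels <- labels$label
  stopifnot(is_count(k), k >= 2)
  tab <- table(labels)
  if (any(tab < k)) {
    small <- names(tab)[tab < k][1L]
    stop_config(sprintf("class '%s' has %d member(s), fewer than k = %d folds",
                        small, tab[[small]], k))
  }
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, "stratified-kfold"), {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# ---- classifier metric battery ------------------------------------------

# Binary AUC of the ROC curve via pROC; scores are P(class 1).
binary_auc <- function(truth, score) {
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = truth, predictor = score,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

# Area under the precision-recall curve as average precision:
# AP = sum_i (R_i - R_{i-1}) P_i over descending score thresholds.
binary_aupr <- function(truth, score) {
  n_pos <- sum(truth == 1)
  if (n_pos == 0L || n_pos == length(truth)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  tp <- cumsum(truth == 1)
  fp <- cumsum(truth == 0)
  # collapse tied scores to one operating point (the last index of a tie)
  keep <- c(score[-length(score)] != score[-1L], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

# Generalized (multi-class) Matthews correlation coefficient from the
# confusion matrix; reduces to the familiar binary formula for C = 2.
mcc_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)   # true counts per class
  p_k <- colSums(cm)   # predicted counts per class
  num <- c_ * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

f1_binary <- function(truth, pred) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

# Per-fold metric computation for labels 0..C-1 and a score matrix with C
# columns (or a vector of P(class 1) for binary).
fold_metrics <- function(truth, scores) {
  if (is.vector(scores)) scores <- cbind(1 - scores, scores)
  C <- ncol(scores)
  pred <- max.col(scores, ties.method = "first") - 1L
  classes <- 0:(C - 1L)
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  acc <- mean(pred == truth)
  if (C == 2L) {
    f1 <- f1_binary(truth, pred)
    auc <- binary_auc(truth, scores[, 2L])
    aupr <- binary_aupr(truth, scores[, 2L])
  } else {
    f1 <- mean(vapply(classes, function(cl) {
      f1_binary(as.integer(truth == cl), as.integer(pred == cl))
    }, numeric(1)))
    auc <- mean(vapply(classes, function(cl) {
      binary_auc(as.integer(truth == cl), scores[, cl + 1L])
    }, numeric(1)))
    aupr <- mean(vapply(classes, function(cl) {
      binary_aupr(as.integer(truth == cl), scores[, cl + 1L])
    }, numeric(1)))
  }
  c(accuracy = acc, f1 = f1, auc = auc, aupr = aupr,
    mcc = mcc_from_confusion(cm))
}

#' Cross-validated classifier metric battery
#'
#' Computes accuracy, F1 (binary, or macro one-vs-rest for more than two
#' classes), ROC AUC, area under the precision-recall curve, and the
#' Matthews correlation coefficient per fold, and reports the mean with a
#' standard error (sample standard deviation across folds divided by the
#' square root of the number of folds). Folds in which a metric is
#' undefined (a single class present) are flagged and excluded from that
#' metric's mean.
#'
#' @param true_labels Integer labels 0..C-1.
#' @param predicted_scores Matrix of per-class scores (n x C), or a vector
#'   of P(class 1) for binary tasks.
#' @param per_fold Integer fold assignment (1..k) per example.
#' @return An object of class `classifier_metrics`: a `summary` data frame
#'   (metric, mean, se, n_folds) and the `per_fold` matrix.
#' @export
classification_metrics <- function(true_labels, predicted_scores, per_fold) {
  true_labels <- as.integer(true_labels)
  k <- length(unique(per_fold))
  per <- t(vapply(sort(unique(per_fold)), function(f) {
    sel <- per_fold == f
    sc <- if (is.vector(predicted_scores)) predicted_scores[sel]
          else predicted_scores[sel, , drop = FALSE]
    fold_metrics(true_labels[sel], sc)
  }, numeric(5)))
  rownames(per) <- paste0("fold", sort(unique(per_fold)))
  if (anyNA(per)) {
    warning("AUC/AUPR undefined in fold(s) with a single class; excluded from the mean")
  }
  summ <- data.frame(
    metric = colnames(per),
    mean = apply(per, 2, mean, na.rm = TRUE),
    se = apply(per, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
    }),
    n_folds = apply(per, 2, function(x) sum(!is.na(x))),
    row.names = NULL)
  structure(list(summary = summ, per_fold = per, k = k),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("<classifier_metrics> mean +/- SE over %d folds\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.*f +/- %.*f\n", s$metric[i], digits, s$mean[i],
                digits, s$se[i]))
  }
  invisible(x)
}

# ---- finetuning ----------------------------------------------------------

# Mean-pooled final hidden state over real, non-structural positions.
pooled_features <- function(model, task, vocab, chunk = 16L) {
  examples <- lapply(task$records, tokenize_record, vocab = vocab)
  ds <- tokenized_dataset(examples)
  n <- nrow(ds$ids)
  H <- model$cfg$hidden_size
  feats <- matrix(0, n, H)
  special <- c(vocab$cls_id, vocab$pad_id, vocab$eos_id, vocab$mask_id,
               if (!is.na(vocab$sep_id)) vocab$sep_id)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(n, start + chunk - 1L)
    bd <- batch_slice(ds, sel)
    hid <- enc_forward(model, bd$ids, bd$mask, cache = FALSE)$hidden
    Tn <- ncol(bd$ids)
    for (j in seq_along(sel)) {
      rows <- ((j - 1L) * Tn + 1L):(j * Tn)
      keep <- bd$mask[j, ] == 1L & !(bd$ids[j, ] %in% special)
      feats[sel[j], ] <- colMeans(hid[rows, , drop = FALSE][keep, , drop = FALSE])
    }
  }
  feats
}

# Two-layer classification head (dense + tanh + dense), trained with Adam
# and warmup/linear-decay, mirroring the ESM-2-style sequence head.
train_head <- function(X, y, n_class, epochs, batch_size, peak_lr,
                       warmup_ratio, seed, hidden = ncol(X)) {
  n <- nrow(X); H <- ncol(X)
  with_seed(seed, {
    p <- list(W1 = matrix(stats::rnorm(H * hidden, sd = 0.02), H, hidden),
              b1 = numeric(hidden),
              W2 = matrix(stats::rnorm(hidden * n_class, sd = 0.02), hidden, n_class),
              b2 = numeric(n_class))
    st <- adamw_state(p)
    steps_per_epoch <- max(1L, ceiling(n / batch_size))
    total <- max(2L, epochs * steps_per_epoch)
    lr_cfg <- lr_schedule_config("linear", peak_lr = peak_lr,
                                 warmup_steps = max(1L, round(warmup_ratio * total)),
                                 total_steps = total)
    step <- 0L
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        perm <- sample.int(n)
        for (start in seq(1L, n, by = batch_size)) {
          sel <- perm[start:min(n, start + batch_size - 1L)]
          Xb <- X[sel, , drop = FALSE]; yb <- y[sel]
          A1 <- addrow(Xb %*% p$W1, p$b1)
          Z1 <- tanh(A1)
          logits <- addrow(Z1 %*% p$W2, p$b2)
          r <- ce_and_grad(logits, yb)
          dZ1 <- tcrossprod(r$dlogits, p$W2)
          dA1 <- dZ1 * (1 - Z1^2)
          grads <- list(W1 = crossprod(Xb, dA1), b1 = colSums(dA1),
                        W2 = crossprod(Z1, r$dlogits), b2 = colSums(r$dlogits))
          lr <- lr_at(lr_cfg, min(step, total - 1L))
          p <- adamw_step(p, grads, st, lr, weight_decay = 0.01)
          step <- step + 1L
        }
      }
    }
    p
  })
}

head_predict <- function(p, X) {
  logits <- addrow(tanh(addrow(X %*% p$W1, p$b1)) %*% p$W2, p$b2)
  E <- exp(logits - rowmax(logits))
  E / rowSums(E)
}

#' Finetune a classifier on a task and score it across folds
#'
#' Attaches a two-layer (dense-tanh-dense) sequence classification head to
#' mean-pooled encoder representations and trains it per cross-validation
#' fold on the other folds, evaluating on the held-out fold. The encoder
#' itself stays frozen (desk-scale head finetuning); defaults mirror the
#' specificity-task recipe (warmup ratio 0.1, peak learning rate 5e-5,
#' linear decay) — pass `peak_lr = 1e-5, epochs = 50` for the pair-task
#' recipe. Deterministic given the seeds.
#'
#' @param model An [build_encoder()] model.
#' @param task An `ab_task` with fold assignments (see
#'   [stratified_kfold()]).
#' @param vocab The [build_vocabulary()] to tokenize task records with.
#' @param epochs,batch_size,peak_lr,warmup_ratio Head-training
#'   hyperparameters.
#' @param seed Integer seed.
#' @return A list: `metrics` (a [classification_metrics()] object),
#'   `scores` (per-example class-probability matrix, each example scored
#'   by the head that held out its fold), and `fold`.
#' @export
finetune_classifier <- function(model, task, vocab, epochs = 5L,
                                batch_size = 8L, peak_lr = 5e-5,
                                warmup_ratio = 0.1, seed = 42L) {
  stopifnot(inherits(task, "ab_task"))
  if (is.null(task$fold)) stop_config("task has no fold assignments; run stratified_kfold() first")
  y <- as.integer(task$label)
  n_class <- length(unique(y))
  X <- pooled_features(model, task, vocab)
  folds <- sort(unique(task$fold))
  scores <- matrix(NA_real_, nrow(X), n_class)
  for (f in folds) {
    tr <- task$fold != f
    p <- train_head(X[tr, , drop = FALSE], y[tr], n_class, epochs, batch_size,
                    peak_lr, warmup_ratio, seed = derive_seed(seed, "head", f))
    scores[!tr, ] <- head_predict(p, X[!tr, , drop = FALSE])
  }
  list(metrics = classification_metrics(y, scores, task$fold),
       scores = scores, fold = task$fold)
}
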