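#' Pack tokenized examples into batch matrices
#'
#' @param examples List of `tokenized_example`s.
#' @return List with integer matrices `ids`, `mask`, `labels`
#'   (n x 320) and the per-example `origin`s.
#' @export
tokenized_dataset <- function(examples) {
  stopifnot(length(examples) > 0)
  n <- length(examples)
  ids <- t(vapply(examples, function(e) e$ids, integer(MAX_TOKENS)))
  mask <- t(vapply(examples, function(e) e$attention_mask, integer(MAX_TOKENS)))
  labels <- t(vapply(examples, function(e) e$labels, integer(MAX_TOKENS)))
  list(ids = ids, mask = mask, labels = labels,
       origin = vapply(examples, function(e) e$origin, character(1)),
       token_regions = lapply(examples, function(e) e$token_regions))
}

# Cross-entropy and softmax gradient at labeled positions.
# logits: (B*T) x V; labels_flat aligned with rows; returns mean CE,
# accuracy and the dlogits matrix (zero at unlabeled rows).
ce_and_grad <- function(logits, labels_flat, want_grad = TRUE, norm = NULL) {
  rows <- which(labels_flat != IGNORE_INDEX)
  if (length(rows) == 0L) stop_config("no labeled positions to score")
  norm <- norm %||% length(rows)
  L <- logits[rows, , drop = FALSE]
  L <- L - rowmax(L)
  P <- exp(L)
  P <- P / rowSums(P)
  idx <- cbind(seq_along(rows), labels_flat[rows] + 1L)
  ce <- -sum(log(pmax(P[idx], 1e-300))) / norm
  acc <- sum(max.col(L, ties.method = "first") == labels_flat[rows] + 1L) / norm
  out <- list(ce = ce, accuracy = acc, n = length(rows))
  if (want_grad) {
    dlogits <- matrix(0, nrow(logits), ncol(logits))
    P[idx] <- P[idx] - 1
    dlogits[rows, ] <- P / norm
    out$dlogits <- dlogits
  }
  out
}

# Elementwise sum of two named gradient lists.
add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (nm in names(g2)) {
    g1[[nm]] <- if (is.null(g1[[nm]])) g2[[nm]] else g1[[nm]] + g2[[nm]]
  }
  g1
}

#' Training-run configuration
#'
#' @param total_steps Number of optimizer steps.
#' @param batch_size Examples per step (desk-scale default 8; the paper-
#'   scale runs use 512).
#' @param lr_schedule An [lr_schedule_config()].
#' @param mlm An [mlm_config()].
#' @param schedule A [make_schedule()] plan with the same `total_steps`.
#' @param seed Base seed for batch composition, masking and evaluation.
#' @param eval_interval Steps between held-out evaluations (default: ten
#'   evaluations per run).
#' @param eval_mlm_seed_tag Tag deriving the fixed evaluation masking seed.
#' @param betas,eps,weight_decay AdamW hyperparameters.
#' @return An object of class `train_run_config`.
#' @export
train_run_config <- function(total_steps, batch_size = 8L,
                             lr_schedule = NULL, mlm = mlm_config(),
                             schedule = NULL, seed = 1L,
                             eval_interval = NULL,
                             eval_mlm_seed_tag = "eval-mlm",
                             betas = c(0.9, 0.98), eps = 1e-8,
                             weight_decay = 0.01) {
  stopifnot(is_count(total_steps), is_count(batch_size), batch_size >= 1)
  if (is.null(schedule)) {
    schedule <- make_schedule("curriculum", total_steps = max(1L, total_steps))
  }
  if (is.null(lr_schedule)) {
    lr_schedule <- lr_schedule_config("linear", peak_lr = 1e-3,
                                      warmup_steps = max(1L, round(0.06 * total_steps)),
                                      total_steps = max(2L, total_steps))
  }
  structure(list(total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size),
                 lr_schedule = lr_schedule, mlm = mlm, schedule = schedule,
                 seed = as.integer(seed),
                 eval_interval = eval_interval %||% max(1L, total_steps %/% 10L),
                 eval_mlm_seed_tag = eval_mlm_seed_tag,
                 betas = betas, eps = eps, weight_decay = weight_decay),
            class = "train_run_config")
}

# Apply fixed MLM masking to an evaluation set once, so eval CE across
# checkpoints is comparable (same masked positions every time).
prepare_eval_set <- function(examples, mlm, vocab, seed) {
  with_seed(seed, {
    tokenized_dataset(lapply(examples, apply_mlm, cfg = mlm, vocab = vocab))
  })
}

# Slice a dataset to selected examples and truncate to the longest real
# length in the batch (padding beyond it carries no information).
batch_slice <- function(ds, sel) {
  ids <- ds$ids[sel, , drop = FALSE]
  mask <- ds$mask[sel, , drop = FALSE]
  labels <- ds$labels[sel, , drop = FALSE]
  tmax <- max(rowSums(mask))
  list(ids = ids[, seq_len(tmax), drop = FALSE],
       mask = mask[, seq_len(tmax), drop = FALSE],
       labels = labels[, seq_len(tmax), drop = FALSE])
}

#' Pre-train an encoder with the masked-language-model objective
#'
#' Runs the full loop: per step, plan the batch composition from the
#' schedule ([plan_batch()]), draw examples from the unpaired and paired
#' pools, collate with [apply_mlm()], forward, cross-entropy on labeled
#' positions, backprop and an AdamW update at the scheduled learning rate.
#' Held-out paired and unpaired sets are evaluated separately (the two
#' data types are logged apart) at a fixed masking, before the first step,
#' every `eval_interval` steps, and after the last step. The whole run is
#' reproducible from `run_cfg$seed`.
#'
#' @param model An [build_encoder()] model.
#' @param pools List with elements `unpaired`, `paired` (lists of
#'   unlabeled `tokenized_example`s) and `eval_unpaired`, `eval_paired`
#'   (held-out examples, disjoint from the training pools).
#' @param run_cfg A [train_run_config()].
#' @param vocab The [build_vocabulary()] used for tokenization.
#' @return An object of class `ablm_train_run`: the trained `model`, a
#'   per-step `log` data frame (step, lr, unpaired probability, realized
#'   unpaired count, train CE), an `evals` data frame (step, CE and
#'   accuracy per data type) and the realized overall unpaired fraction.
#' @export
train <- function(model, pools, run_cfg, vocab) {
  stopifnot(inherits(model, "ablm_encoder"), inherits(run_cfg, "train_run_config"))
  for (nm in c("unpaired", "paired", "eval_unpaired", "eval_paired")) {
    if (is.null(pools[[nm]])) stop_config(sprintf("pools$%s is missing", nm))
  }
  up_ds <- tokenized_dataset(pools$unpaired)
  pp_ds <- tokenized_dataset(pools$paired)
  eval_seed <- derive_seed(run_cfg$seed, run_cfg$eval_mlm_seed_tag)
  ev_up <- prepare_eval_set(pools$eval_unpaired, run_cfg$mlm, vocab, eval_seed)
  ev_pp <- prepare_eval_set(pools$eval_paired, run_cfg$mlm, vocab,
                            derive_seed(eval_seed, "paired"))
  up_pool <- sampler_pool(nrow(up_ds$ids), "unpaired", run_cfg$seed)
  pp_pool <- sampler_pool(nrow(pp_ds$ids), "paired", run_cfg$seed)
  state <- adamw_state(model$params)
  steps <- run_cfg$total_steps
  log <- data.frame(step = integer(0), lr = numeric(0), p_unpaired = numeric(0),
                    n_unpaired = integer(0), train_ce = numeric(0))
  evals <- list()
  eval_now <- function(step) {
    r_up <- masked_eval(model, ev_up)
    r_pp <- masked_eval(model, ev_pp)
    data.frame(step = step,
               ce_unpaired = r_up$ce_loss, acc_unpaired = r_up$accuracy,
               ce_paired = r_pp$ce_loss, acc_paired = r_pp$accuracy)
  }
  evals[[1L]] <- eval_now(0L)
  if (steps > 0L) {
    with_seed(derive_seed(run_cfg$seed, "train-loop"), {
      for (step in 0:(steps - 1L)) {
        plan <- plan_batch(run_cfg$schedule, step, run_cfg$batch_size,
                           up_pool, pp_pool)
        # unpaired chains are roughly half the length of paired inputs, so
        # the two origins are processed as separate sub-batches (each
        # truncated to its own length) and their gradients accumulated
        # into one optimizer step
        groups <- Filter(length, list(
          lapply(pools$unpaired[plan$unpaired_idx], apply_mlm,
                 cfg = run_cfg$mlm, vocab = vocab),
          lapply(pools$paired[plan$paired_idx], apply_mlm,
                 cfg = run_cfg$mlm, vocab = vocab)))
        bds <- lapply(groups, function(g) batch_slice(tokenized_dataset(g),
                                                      seq_along(g)))
        n_labeled <- sum(vapply(bds, function(bd) sum(bd$labels != IGNORE_INDEX),
                                numeric(1)))
        if (n_labeled == 0) {  # no position selected; nothing to learn from
          log[nrow(log) + 1L, ] <- list(step, NA_real_, plan$p_unpaired,
                                        plan$n_unpaired, NA_real_)
          next
        }
        step_ce <- 0; grads <- NULL
        for (bd in bds) {
          fwd <- enc_forward(model, bd$ids, bd$mask, cache = TRUE)
          cg <- ce_and_grad(fwd$logits, as.vector(t(bd$labels)), norm = n_labeled)
          step_ce <- step_ce + cg$ce
          grads <- add_grads(grads, enc_backward(model, bd$ids, bd$mask, fwd,
                                                 cg$dlogits))
        }
        if (!is.finite(step_ce)) {
          stop_config(sprintf("training diverged at step %d (non-finite loss)", step))
        }
        cg <- list(ce = step_ce)
        lr <- lr_at(run_cfg$lr_schedule, min(step, run_cfg$lr_schedule$total_steps - 1L))
        model$params <- adamw_step(model$params, grads, state, lr,
                                   run_cfg$betas, run_cfg$eps, run_cfg$weight_decay)
        log[nrow(log) + 1L, ] <- list(step, lr, plan$p_unpaired,
                                      plan$n_unpaired, cg$ce)
        if ((step + 1L) %% run_cfg$eval_interval == 0L && step + 1L < steps) {
          evals[[length(evals) + 1L]] <- eval_now(step + 1L)
        }
      }
    })
    evals[[length(evals) + 1L]] <- eval_now(steps)
  }
  structure(list(model = model, log = log, evals = do.call(rbind, evals),
                 realized_unpaired_fraction =
                   if (nrow(log)) sum(log$n_unpaired) / (nrow(log) * run_cfg$batch_size)
                   else NA_real_,
                 run_cfg = run_cfg),
            class = "ablm_train_run")
}

#' @export
print.ablm_train_run <- function(x, ...) {
  ev <- x$evals
  cat(sprintf("<ablm_train_run> %d steps, batch %d (%s schedule)\n",
              x$run_cfg$total_steps, x$run_cfg$batch_size, x$run_cfg$schedule$kind))
  if (!is.na(x$realized_unpaired_fraction)) {
    cat(sprintf("  realized unpaired fraction: %.4f (schedule target %.4f)\n",
                x$realized_unpaired_fraction,
                x$run_cfg$schedule$target_unpaired_fraction))
  }
  cat(sprintf("  eval CE unpaired: %.4f -> %.4f | paired: %.4f -> %.4f\n",
              ev$ce_unpaired[1], ev$ce_unpaired[nrow(ev)],
              ev$ce_paired[1], ev$ce_paired[nrow(ev)]))
  invisible(x)
}
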