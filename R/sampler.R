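#' Create a cycling example pool
#'
#' A pool serves example indices without replacement within an epoch,
#' reshuffling when exhausted. The permutation of epoch `e` is seeded
#' deterministically from `(base_seed, name, e)`, so a training run is
#' reproducible from its base seed regardless of how batches interleave
#' pool draws. The pool is a mutable environment: drawing advances its
#' cursor.
#'
#' @param n Number of examples in the pool.
#' @param name Pool name (enters the epoch seed derivation).
#' @param seed Base seed.
#' @return An environment of class `sampler_pool`.
#' @export
sampler_pool <- function(n, name, seed) {
  stopifnot(is_count(n))
  pool <- new.env(parent = emptyenv())
  pool$n <- as.integer(n)
  pool$name <- name
  pool$seed <- as.integer(seed)
  pool$epoch <- 0L
  pool$pos <- 0L
  pool$perm <- if (n > 0) with_seed(derive_seed(seed, name, 0L), sample.int(n)) else integer(0)
  class(pool) <- c("sampler_pool", "environment")
  pool
}

# Draw k indices from the pool, crossing epoch boundaries as needed.
pool_draw <- function(pool, k) {
  if (k == 0L) return(integer(0))
  if (pool$n == 0L) {
    stop_config(sprintf("pool '%s' is empty but %d example(s) were requested",
                        pool$name, k))
  }
  out <- integer(0)
  while (length(out) < k) {
    take <- min(k - length(out), pool$n - pool$pos)
    out <- c(out, pool$perm[pool$pos + seq_len(take)])
    pool$pos <- pool$pos + take
    if (pool$pos == pool$n) {
      pool$epoch <- pool$epoch + 1L
      pool$perm <- with_seed(derive_seed(pool$seed, pool$name, pool$epoch),
                             sample.int(pool$n))
      pool$pos <- 0L
    }
  }
  out
}

#' Plan the composition of one training batch
#'
#' The number of unpaired examples is a binomial draw with probability
#' `schedule$probability_fn(step)` and size `batch_size` (per-example
#' Bernoulli sampling — unbiased for any probability); the remainder of the
#' batch is paired. Indices are then taken without replacement from each
#' pool's current epoch permutation.
#'
#' @param schedule A [make_schedule()] plan.
#' @param step 0-based training step.
#' @param batch_size Number of examples in the batch.
#' @param unpaired_pool,paired_pool [sampler_pool()] objects (mutated).
#' @return An object of class `batch_plan`: `step`, `p_unpaired`,
#'   `n_unpaired`, `n_paired`, `unpaired_idx`, `paired_idx`.
#' @export
plan_batch <- function(schedule, step, batch_size, unpaired_pool, paired_pool) {
  stopifnot(inherits(schedule, "schedule_plan"))
  if (!is_count(step) || step >= schedule$total_steps) {
    stop_config("step must lie in [0, total_steps)")
  }
  if (!is_count(batch_size) || batch_size < 1) stop_config("batch_size must be >= 1")
  batch_size <- as.integer(batch_size)
  p <- schedule$probability_fn(step)
  n_unpaired <- stats::rbinom(1L, batch_size, p)
  n_paired <- batch_size - n_unpaired
  structure(list(
    step = as.integer(step), p_unpaired = p,
    n_unpaired = n_unpaired, n_paired = n_paired,
    unpaired_idx = pool_draw(unpaired_pool, n_unpaired),
    paired_idx = pool_draw(paired_pool, n_paired)
  ), class = "batch_plan")
}

#' Masked-language-model collation configuration
#'
#' Of the eligible residue positions, `select_rate` are chosen for
#' prediction; of the chosen, `mask_rate` are replaced by `<mask>`,
#' `random_rate` by a random canonical residue different from the original,
#' and `keep_rate` are left unchanged. Defaults are the standard
#' 15% / 80% / 10% / 10% recipe.
#'
#' @param select_rate Proportion of eligible positions selected.
#' @param mask_rate,random_rate,keep_rate Proportions of selected
#'   positions; must sum to 1.
#' @return An object of class `mlm_config`.
#' @export
mlm_config <- function(select_rate = 0.15, mask_rate = 0.8,
                       random_rate = 0.1, keep_rate = 0.1) {
  check_proportion(select_rate, "select_rate")
  if (select_rate <= 0 || select_rate >= 1) {
    stop_config("select_rate must lie strictly inside (0, 1)")
  }
  if (abs(mask_rate + random_rate + keep_rate - 1) > 1e-12) {
    stop_config("mask_rate + random_rate + keep_rate must equal 1")
  }
  structure(list(select_rate = select_rate, mask_rate = mask_rate,
                 random_rate = random_rate, keep_rate = keep_rate),
            class = "mlm_config")
}

#' Apply MLM masking to a tokenized example
#'
#' Eligible positions are residue tokens only: `<cls>`, separator, `<eos>`
#' and padding are never selected, matching the evaluation convention of
#' excluding separator tokens from metrics. Each eligible position is
#' independently selected with probability `cfg$select_rate`; selected
#' positions receive their original id as the prediction label and are
#' then masked / randomized / kept per `cfg`. Random replacements draw
#' a canonical residue different from the original, so a "random" action
#' always changes the token. Non-selected labels remain the ignore
#' sentinel. Uses the current RNG state.
#'
#' @param example A `tokenized_example` with all labels at the ignore
#'   sentinel.
#' @param cfg An [mlm_config()].
#' @param vocab The [build_vocabulary()] used to tokenize.
#' @return The example with `ids` perturbed and `labels` filled in.
#' @export
apply_mlm <- function(example, cfg = mlm_config(), vocab) {
  stopifnot(inherits(example, "tokenized_example"), inherits(cfg, "mlm_config"))
  if (any(example$labels != IGNORE_INDEX)) {
    stop_config("example already carries MLM labels")
  }
  ids <- example$ids
  eligible <- which(ids %in% vocab$eligible_ids & example$attention_mask == 1L)
  if (length(eligible) == 0L) return(example)
  sel <- eligible[stats::runif(length(eligible)) < cfg$select_rate]
  if (length(sel) == 0L) return(example)
  example$labels[sel] <- ids[sel]
  u <- stats::runif(length(sel))
  to_mask <- sel[u < cfg$mask_rate]
  to_rand <- sel[u >= cfg$mask_rate & u < cfg$mask_rate + cfg$random_rate]
  ids[to_mask] <- vocab$mask_id
  for (p in to_rand) {
    ids[p] <- sample(setdiff(vocab$residue_ids, ids[p]), 1L)
  }
  example$ids <- ids
  example
}
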