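# Normalize a dataset argument: either a list of tokenized_examples or the
# matrix form produced by tokenized_dataset().
as_tokenized_dataset <- function(dataset) {
  if (is.list(dataset) && !is.null(dataset$ids) && is.matrix(dataset$ids)) {
    return(dataset)
  }
  tokenized_dataset(dataset)
}

# Dispatch a forward pass: `model` is either an ablm_encoder or a plain
# function(ids, mask) returning a ((B*T) x V) logits matrix (rows ordered
# by example then position). The function form admits reference models
# (uniform, oracle) in tests and analyses.
model_logits_flat <- function(model, ids, mask) {
  if (inherits(model, "ablm_encoder")) {
    enc_forward(model, ids, mask, cache = FALSE)$logits
  } else if (is.function(model)) {
    model(ids, mask)
  } else {
    stop_config("model must be an ablm_encoder or a function(ids, mask)")
  }
}

#' Evaluate masked-token predictions
#'
#' Mean cross-entropy and argmax accuracy over labeled positions only.
#' Structural tokens (`<cls>`, separator, `<eos>`, padding) are never
#' labeled by the collator, so they are excluded from the metrics by
#' construction; perturbing a model's predictions at those positions
#' cannot change the report.
#'
#' @param model An [build_encoder()] model or a `function(ids, mask)`
#'   returning a flat logits matrix.
#' @param dataset A list of MLM-labeled `tokenized_example`s or the matrix
#'   form from [tokenized_dataset()].
#' @param chunk Examples per forward pass.
#' @return An object of class `eval_report`: `ce_loss`, `accuracy`,
#'   `n_positions`.
#' @export
masked_eval <- function(model, dataset, chunk = 16L) {
  ds <- as_tokenized_dataset(dataset)
  n <- nrow(ds$ids)
  if (all(ds$labels == IGNORE_INDEX)) {
    stop_config("dataset has no labeled positions; apply MLM masking first")
  }
  tot_ce <- 0; tot_acc <- 0; tot_n <- 0L
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(n, start + chunk - 1L)
    bd <- batch_slice(ds, sel)
    if (all(bd$labels == IGNORE_INDEX)) next
    logits <- model_logits_flat(model, bd$ids, bd$mask)
    r <- ce_and_grad(logits, as.vector(t(bd$labels)), want_grad = FALSE)
    tot_ce <- tot_ce + r$ce * r$n
    tot_acc <- tot_acc + r$accuracy * r$n
    tot_n <- tot_n + r$n
  }
  structure(list(ce_loss = tot_ce / tot_n, accuracy = tot_acc / tot_n,
                 n_positions = tot_n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> CE %.4f, accuracy %.4f over %d positions\n",
              x$ce_loss, x$accuracy, x$n_positions))
  invisible(x)
}

# Mask-one-position-at-a-time predictions. For each example and each
# token position inside the requested regions, a variant input is built
# with only that position replaced by <mask> (the rest of the sequence
# fully visible), and the model predicts it. Returns one row per scored
# position.
single_mask_scores <- function(model, dataset, vocab, regions = NULL,
                               chunk = 32L) {
  ds <- as_tokenized_dataset(dataset)
  out <- list()
  for (i in seq_len(nrow(ds$ids))) {
    tr <- ds$token_regions[[i]]
    if (is.null(tr)) next
    use <- if (is.null(regions)) names(tr) else intersect(names(tr), regions)
    if (length(use) == 0L) next
    tlen <- sum(ds$mask[i, ])
    base_ids <- ds$ids[i, seq_len(tlen)]
    base_mask <- ds$mask[i, seq_len(tlen)]
    pos_tab <- do.call(rbind, lapply(use, function(nm) {
      iv <- tr[[nm]]
      data.frame(region = nm, position = seq(iv[[1]], iv[[2]] - 1L))
    }))
    pos_tab <- pos_tab[pos_tab$position < tlen, , drop = FALSE]
    if (nrow(pos_tab) == 0L) next
    for (start in seq(1L, nrow(pos_tab), by = chunk)) {
      sub <- pos_tab[start:min(nrow(pos_tab), start + chunk - 1L), , drop = FALSE]
      nb <- nrow(sub)
      ids <- matrix(base_ids, nb, tlen, byrow = TRUE)
      msk <- matrix(base_mask, nb, tlen, byrow = TRUE)
      tcol <- sub$position + 1L                     # 0-based -> column
      true_id <- ids[cbind(seq_len(nb), tcol)]
      ids[cbind(seq_len(nb), tcol)] <- vocab$mask_id
      logits <- model_logits_flat(model, ids, msk)
      rows <- (seq_len(nb) - 1L) * tlen + tcol
      L <- logits[rows, , drop = FALSE]
      L <- L - rowmax(L)
      P <- exp(L); P <- P / rowSums(P)
      ce <- -log(pmax(P[cbind(seq_len(nb), true_id + 1L)], 1e-300))
      pred <- max.col(L, ties.method = "first") - 1L
      out[[length(out) + 1L]] <- data.frame(
        example = i, region = sub$region, position = sub$position,
        true_id = true_id, pred_id = pred, ce = ce)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Per-region cross-entropy by single-position masking
#'
#' For every annotated region, each position is masked and predicted one
#' at a time with the rest of the sequence visible; cross-entropies are
#' averaged per region across the dataset (positions pooled). Regions
#' absent from every example are omitted with a warning.
#'
#' @inheritParams masked_eval
#' @param vocab The [build_vocabulary()] used to tokenize.
#' @param regions Optional subset of region names (e.g. `"H-CDR3"`).
#' @return Named numeric vector of mean CE per region.
#' @export
per_region_loss <- function(model, dataset, vocab, regions = NULL) {
  scores <- single_mask_scores(model, dataset, vocab, regions)
  if (is.null(scores)) stop_config("no annotated regions found in the dataset")
  if (!is.null(regions)) {
    missing <- setdiff(regions, unique(scores$region))
    if (length(missing)) {
      warning("region(s) absent from all examples: ", paste(missing, collapse = ", "))
    }
  }
  means <- tapply(scores$ce, scores$region, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' CDRH3 accuracy by individual masking
#'
#' Masks and predicts each heavy-chain CDR3 position individually, then
#' averages prediction correctness. The default micro-average pools all
#' (sequence, position) pairs; `average = "macro"` averages per-sequence
#' accuracies instead.
#'
#' @inheritParams per_region_loss
#' @param average `"micro"` (pooled positions, default) or `"macro"`.
#' @return Accuracy in \[0, 1\].
#' @export
cdrh3_accuracy <- function(model, dataset, vocab, average = c("micro", "macro")) {
  average <- match.arg(average)
  scores <- single_mask_scores(model, dataset, vocab, regions = "H-CDR3")
  if (is.null(scores)) stop_config("dataset carries no H-CDR3 annotations")
  hit <- scores$pred_id == scores$true_id
  if (average == "micro") {
    mean(hit)
  } else {
    mean(tapply(hit, scores$example, mean))
  }
}
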