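test_that("mutation subsets partition all pairs", {
  rep <- fixture_repertoire(n_paired = 30)
  mk <- function(h_mut, l_mut) {
    p <- rep$paired[[1]]
    p$heavy$mutation_count <- h_mut; p$light$mutation_count <- l_mut
    p
  }
  expect_identical(assign_mutation_subset(mk(3L, 2L)), "mutated")
  expect_identical(assign_mutation_subset(mk(0L, 0L)), "unmutated")
  expect_identical(assign_mutation_subset(mk(3L, 0L)), "different")
  expect_identical(assign_mutation_subset(mk(0L, 1L)), "different")
  subsets <- vapply(rep$paired, assign_mutation_subset, character(1))
  expect_true(all(subsets %in% c("mutated", "unmutated", "different")))
})

test_that("pair classification is balanced, deranged and reproducible", {
  rep <- fixture_repertoire(n_paired = 100)
  task <- build_pair_classification(rep$paired, seed = 7)
  expect_length(task$records, 200)
  expect_identical(sum(task$label == 1L), 100L)
  expect_identical(sum(task$label == 0L), 100L)
  natives <- task$records[task$label == 1L]
  negatives <- task$records[task$label == 0L]
  for (i in seq_along(negatives)) {
    expect_false(negatives[[i]]$is_native)
    # the i-th negative reuses the i-th native heavy but never its light
    expect_identical(negatives[[i]]$heavy, natives[[i]]$heavy)
    expect_false(identical(negatives[[i]]$light, natives[[i]]$light))
  }
  expect_identical(build_pair_classification(rep$paired, seed = 7), task)
  expect_false(identical(build_pair_classification(rep$paired, seed = 8)$records,
                         task$records))
  expect_error(build_pair_classification(rep$paired[1], seed = 1), "at least 2")
})

test_that("specificity datasets are clustered, balanced and stratified", {
  pools <- list(
    HD = generate_repertoire(0, 60, 0, seed = 1, specificity = "HD")$unpaired,
    Flu = generate_repertoire(0, 45, 0, seed = 2, specificity = "Flu")$unpaired,
    CoV = generate_repertoire(0, 52, 0, seed = 3, specificity = "CoV")$unpaired)
  task <- build_specificity_dataset(pools, identity_threshold = 0.99, seed = 5)
  sizes <- table(task$label)
  expect_length(unique(as.integer(sizes)), 1L)   # exactly balanced
  expect_lte(as.integer(sizes[1]), 45L)
  expect_identical(sort(unique(task$label)), 0:2)
  # stratified: per-class fold counts differ by at most 1
  for (cls in 0:2) {
    counts <- table(task$fold[task$label == cls])
    expect_lte(max(counts) - min(counts), 1)
  }
  # identity threshold 1.0 with no duplicates keeps class sizes (before balancing)
  kept <- filter_and_dedup(pools$Flu, 1.0)
  expect_length(kept, 45L)
})

test_that("stratified folds are exact partitions with near-equal class counts", {
  labels <- rep(c(0L, 1L), c(103, 97))
  fold <- stratified_kfold(labels, k = 5, seed = 9)
  expect_length(fold, 200)
  expect_setequal(unique(fold), 1:5)
  c0 <- table(fold[labels == 0L]); c1 <- table(fold[labels == 1L])
  expect_true(all(c0 %in% c(20, 21)))
  expect_true(all(c1 %in% c(19, 20)))
  expect_identical(sum(c0), 103L)
  expect_identical(sum(c1), 97L)
  expect_identical(stratified_kfold(labels, 5, 9), fold)
  expect_error(stratified_kfold(rep(0:1, c(3, 50)), k = 5), "fewer than")
})

test_that("metrics match closed-form oracles on exhaustive small confusion matrices", {
  for (tp in 0:4) for (fp in 0:4) for (fn in 0:4) for (tn in 0:4) {
    if (tp + fn == 0 || fp + tn == 0) next  # need both classes present
    truth <- rep(c(1L, 1L, 0L, 0L), c(tp, fn, fp, tn))
    pred <- rep(c(1L, 0L, 1L, 0L), c(tp, fn, fp, tn))
    scores <- ifelse(pred == 1L, 0.9, 0.1)
    m <- suppressWarnings(
      classification_metrics(truth, scores, rep(1L, length(truth))))
    s <- m$summary
    get <- function(nm) s$mean[s$metric == nm]
    n <- tp + fp + fn + tn
    expect_equal(get("accuracy"), (tp + tn) / n)
    expect_equal(get("f1"),
                 if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(get("mcc"),
                 if (den == 0) 0 else (tp * tn - fp * fn) / den)
  }
})

test_that("the hand-built 8-example fold reproduces accuracy 0.75 and MCC 0.5", {
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 0, 0, 0)   # TP=3 FP=1 FN=1 TN=3
  m <- classification_metrics(truth, ifelse(pred == 1, 0.8, 0.2),
                              rep(1L, 8))
  s <- m$summary
  expect_equal(s$mean[s$metric == "accuracy"], 0.75)
  expect_equal(s$mean[s$metric == "mcc"], 0.5)
})

test_that("AUC agrees with the rank-based Mann-Whitney oracle", {
  set.seed(12)
  for (i in 1:10) {
    truth <- rbinom(40, 1, 0.5)
    if (length(unique(truth)) < 2) next
    score <- rnorm(40)
    m <- classification_metrics(truth, plogis(score), rep(1L, 40))
    r <- rank(score)
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    u <- sum(r[truth == 1]) - n1 * (n1 + 1) / 2
    expect_equal(m$summary$mean[m$summary$metric == "auc"], u / (n1 * n0),
                 tolerance = 1e-10)
  }
})

test_that("AUPR equals the frozen average-precision of a hand-worked case", {
  truth <- c(1, 0, 1, 1, 0)
  score <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  m <- classification_metrics(truth, score, rep(1L, 5))
  # ranked: 1,0,1,1,0 -> AP = 1/3*1 + 1/3*(2/3) + 1/3*(3/4) = 29/36
  expect_equal(m$summary$mean[m$summary$metric == "aupr"], 29 / 36,
               tolerance = 1e-12)
})

test_that("perfect and degenerate classifiers hit the analytic extremes", {
  truth <- rep(c(0L, 1L), 20)
  fold <- rep(1:4, each = 10)
  perfect <- classification_metrics(truth, ifelse(truth == 1, 0.99, 0.01), fold)
  expect_true(all(abs(perfect$summary$mean - 1) < 1e-12))
  expect_true(all(perfect$summary$se == 0))
  # constant single-class predictor on a balanced task
  degen <- suppressWarnings(classification_metrics(truth, rep(0.9, 40), fold))
  s <- degen$summary
  expect_equal(s$mean[s$metric == "accuracy"], 0.5)
  expect_equal(s$mean[s$metric == "mcc"], 0)
})

test_that("single-class folds are excluded from AUC with a warning", {
  truth <- c(rep(1L, 10), rep(c(0L, 1L), 5))
  fold <- rep(1:2, each = 10)
  expect_warning(
    m <- classification_metrics(truth, runif(20), fold),
    "single class")
  expect_identical(m$summary$n_folds[m$summary$metric == "auc"], 1L)
  expect_identical(m$summary$n_folds[m$summary$metric == "accuracy"], 2L)
})

test_that("head finetuning on motif-labeled data beats chance", {
  pools <- list(
    HD = generate_repertoire(0, 40, 0, seed = 21, specificity = "HD")$unpaired,
    Flu = generate_repertoire(0, 40, 0, seed = 22, specificity = "Flu")$unpaired,
    CoV = generate_repertoire(0, 40, 0, seed = 23, specificity = "CoV")$unpaired)
  task <- build_specificity_dataset(pools, identity_threshold = 1.0, seed = 5)
  v <- build_vocabulary()
  m <- tiny_encoder(seed = 31, hidden_size = 32, intermediate_size = 64)
  res <- finetune_classifier(m, task, v, epochs = 25, batch_size = 16,
                             peak_lr = 5e-3, seed = 6)
  acc <- res$metrics$summary$mean[res$metrics$summary$metric == "accuracy"]
  expect_gt(acc, 1 / 3)
  # determinism
  res2 <- finetune_classifier(m, task, v, epochs = 25, batch_size = 16,
                              peak_lr = 5e-3, seed = 6)
  expect_identical(res$scores, res2$scores)
  # untrained head scores near chance on balanced data
  res0 <- suppressWarnings(finetune_classifier(m, task, v, epochs = 0, seed = 6))
  acc0 <- res0$metrics$summary$mean[res0$metrics$summary$metric == "accuracy"]
  expect_lt(abs(acc0 - 1 / 3), 0.25)
})
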