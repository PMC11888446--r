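#' Validate an experiment configuration
#'
#' Checks the hierarchical configuration (see the bundled
#' `tiny_curriculum.yaml` for the schema) before any compute, reporting
#' violations with their field paths. In particular the schedule's target
#' unpaired fraction must be attainable, i.e. inside `[B - A, B]`.
#'
#' @param config A named list (typically from [yaml::read_yaml()]).
#' @return The config, invisibly, with defaults filled in.
#' @export
validate_experiment_config <- function(config) {
  fail <- function(path, msg) stop_config(sprintf("config field `%s`: %s", path, msg))
  req <- function(path, default = NULL) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
    val <- config
    for (p_ in parts) val <- val[[p_]]
    if (is.null(val)) {
      if (is.null(default)) fail(path, "is required") else default
    } else val
  }
  config$seed <- req("seed", 1L)
  config$repertoire <- utils::modifyList(
    list(n_paired = 200L, n_unpaired_heavy = 300L, n_unpaired_light = 100L,
         mutation_rate = 6, naive_fraction = 0.5),
    config$repertoire %||% list())
  for (nm in c("n_paired", "n_unpaired_heavy", "n_unpaired_light")) {
    if (!is_count(config$repertoire[[nm]])) fail(paste0("repertoire.", nm), "must be a non-negative integer")
  }
  config$prep <- utils::modifyList(
    list(separator_mode = "unique_sep", train_fraction = 0.96),
    config$prep %||% list())
  if (!config$prep$separator_mode %in% c("unique_sep", "reuse_cls", "none")) {
    fail("prep.separator_mode", "must be one of unique_sep, reuse_cls, none")
  }
  if (config$prep$train_fraction <= 0 || config$prep$train_fraction >= 1) {
    fail("prep.train_fraction", "must lie in (0, 1)")
  }
  config$schedule <- utils::modifyList(
    list(kind = "curriculum", B = 0.7, A = 0.4, k = 15,
         target_unpaired_fraction = 0.625),
    config$schedule %||% list())
  sch <- config$schedule
  if (sch$kind == "curriculum") {
    if (sch$target_unpaired_fraction < sch$B - sch$A ||
        sch$target_unpaired_fraction > sch$B) {
      fail("schedule.target_unpaired_fraction",
           sprintf("must lie in the attainable interval [%.4g, %.4g]",
                   sch$B - sch$A, sch$B))
    }
  }
  config$train <- utils::modifyList(
    list(total_steps = 200L, batch_size = 8L, peak_lr = 1e-3,
         warmup_ratio = 0.06, lr_kind = "linear", eval_size = 24L),
    config$train %||% list())
  if (!is_count(config$train$total_steps) || config$train$total_steps < 1) {
    fail("train.total_steps", "must be a positive integer")
  }
  invisible(config)
}

#' Run a seeded end-to-end experiment
#'
#' Executes generate -> prep -> schedule -> train -> evaluate as declared
#' in the configuration, writing per-stage outputs (schedule table,
#' training log, evaluation report) and a run manifest (config snapshot,
#' derived per-stage seeds, package version, output checksums) to
#' `out_dir`. All stages are deterministic given the config, so re-running
#' from the same config reproduces identical outputs.
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NA_character_
  }
  config <- validate_experiment_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  seeds <- list(repertoire = derive_seed(seed, "repertoire"),
                split = derive_seed(seed, "split"),
                train = derive_seed(seed, "train"),
                tasks = derive_seed(seed, "tasks"))

  rep_cfg <- config$repertoire
  rep <- generate_repertoire(rep_cfg$n_paired, rep_cfg$n_unpaired_heavy,
                             rep_cfg$n_unpaired_light,
                             mutation_rate = rep_cfg$mutation_rate,
                             naive_fraction = rep_cfg$naive_fraction,
                             seed = seeds$repertoire)
  vocab <- build_vocabulary(config$prep$separator_mode)
  tok_paired <- lapply(rep$paired, tokenize_record, vocab = vocab)
  tok_unpaired <- lapply(rep$unpaired, tokenize_record, vocab = vocab)
  sp_p <- split_train_eval_test(tok_paired, config$prep$train_fraction, seeds$split)
  sp_u <- split_train_eval_test(tok_unpaired, config$prep$train_fraction,
                                derive_seed(seeds$split, "unpaired"))

  tr <- config$train
  schedule <- make_schedule(config$schedule$kind,
                            target_unpaired_fraction = config$schedule$target_unpaired_fraction,
                            total_steps = tr$total_steps,
                            B = config$schedule$B, A = config$schedule$A,
                            k = config$schedule$k)
  lr_cfg <- lr_schedule_config(tr$lr_kind, peak_lr = tr$peak_lr,
                               warmup_steps = max(1L, round(tr$warmup_ratio * tr$total_steps)),
                               total_steps = tr$total_steps)
  steps <- 0:(tr$total_steps - 1L)
  schedule_table <- data.frame(step = steps,
                               unpaired_probability = schedule$probability_fn(steps),
                               lr = lr_at(lr_cfg, steps))
  utils::write.csv(schedule_table, file.path(out_dir, "schedule.csv"),
                   row.names = FALSE)

  enc_cfg <- encoder_config(
    n_layers = config$encoder$n_layers %||% 2L,
    n_heads = config$encoder$n_heads %||% 4L,
    hidden_size = config$encoder$hidden_size %||% 64L,
    intermediate_size = config$encoder$intermediate_size %||% 256L,
    pe_type = config$encoder$pe_type %||% "rope")
  model <- build_encoder(enc_cfg, seed = derive_seed(seed, "encoder"))
  cap <- function(x, n) x[seq_len(min(length(x), n))]
  pools <- list(unpaired = sp_u$train, paired = sp_p$train,
                eval_unpaired = cap(sp_u$eval, tr$eval_size),
                eval_paired = cap(sp_p$eval, tr$eval_size))
  run_cfg <- train_run_config(tr$total_steps, tr$batch_size,
                              lr_schedule = lr_cfg, schedule = schedule,
                              seed = seeds$train)
  run <- train(model, pools, run_cfg, vocab)
  utils::write.csv(run$log, file.path(out_dir, "train_log.csv"), row.names = FALSE)
  utils::write.csv(run$evals, file.path(out_dir, "evals.csv"), row.names = FALSE)

  test_report <- list(
    unpaired = unclass(masked_eval(run$model, prepare_eval_set(
      cap(sp_u$test, tr$eval_size), run_cfg$mlm, vocab,
      derive_seed(seed, "test-mlm-unpaired")))),
    paired = unclass(masked_eval(run$model, prepare_eval_set(
      cap(sp_p$test, tr$eval_size), run_cfg$mlm, vocab,
      derive_seed(seed, "test-mlm-paired")))),
    realized_unpaired_fraction = run$realized_unpaired_fraction,
    schedule_mean = mean(schedule_table$unpaired_probability))
  jsonlite::write_json(test_report, file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)

  outputs <- c("schedule.csv", "train_log.csv", "evals.csv", "eval_report.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("curriculab")),
    config_path = config_path,
    config = config,
    seeds = seeds,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, outputs)))), outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
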