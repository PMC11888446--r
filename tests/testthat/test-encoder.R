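test_that("rope_rotate is an orthogonal map matching the 2-D rotation oracle", {
  set.seed(1)
  x <- rnorm(16)
  expect_equal(rope_rotate(x, 0), x)
  for (pos in c(1, 7, 123)) {
    expect_equal(sqrt(sum(rope_rotate(x, pos)^2)), sqrt(sum(x^2)), tolerance = 1e-12)
  }
  expect_error(rope_rotate(rnorm(5), 1), "even")
  # d = 2: pair 0 rotates by exactly `position` radians; explicit
  # rotation-matrix oracle
  theta <- pi / 2
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(rope_rotate(c(1, 0), theta), as.vector(R %*% c(1, 0)), tolerance = 1e-12)
  expect_equal(rope_rotate(c(0.3, -2), theta), as.vector(R %*% c(0.3, -2)), tolerance = 1e-12)
})

test_that("rotary attention dot products depend only on relative distance", {
  set.seed(2)
  for (d in c(8, 16)) {
    q <- rnorm(d); k <- rnorm(d)
    offsets <- c(0, 1, 5, 17)
    for (delta in c(0, 1, 4, 9)) {
      dots <- vapply(offsets, function(m) {
        sum(rope_rotate(q, m + delta) * rope_rotate(k, m))
      }, numeric(1))
      expect_lt(max(dots) - min(dots), 1e-6)
    }
    # and genuinely varies with the relative distance itself
    d0 <- sum(rope_rotate(q, 3) * rope_rotate(k, 3))
    d5 <- sum(rope_rotate(q, 8) * rope_rotate(k, 3))
    expect_gt(abs(d0 - d5), 1e-8)
  }
})

test_that("encoder builds are deterministic and shaped correctly", {
  m1 <- tiny_encoder(seed = 4)
  m2 <- tiny_encoder(seed = 4)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_encoder(seed = 5)
  expect_false(identical(m1$params, m3$params))
  expect_error(encoder_config(n_heads = 3, hidden_size = 64), "divisible")
  expect_error(encoder_config(pe_type = "absolute", max_positions = 100), "max_positions")

  v <- build_vocabulary()
  ds <- tokenized_dataset(fixture_tokenized(n = 3))
  logits <- encoder_forward(m1, ds$ids, ds$mask)
  expect_identical(dim(logits), c(3L, 320L, 33L))
  expect_true(all(is.finite(logits)))
})

test_that("rotary logits are invariant to the amount of trailing padding", {
  m <- tiny_encoder(seed = 6)
  ids <- matrix(c(0L, sample(4:23, 10, TRUE), 2L), 1)
  n <- ncol(ids)
  mask <- matrix(1L, 1, n)
  base <- encoder_forward(m, ids, mask)
  padded <- encoder_forward(m, cbind(ids, matrix(1L, 1, 7)),
                            cbind(mask, matrix(0L, 1, 7)))
  expect_equal(base[1, 1:n, ], padded[1, 1:n, ], tolerance = 1e-10)
})

test_that("shifting content breaks absolute-PE logits but not rotary ones", {
  set.seed(8)
  ids <- matrix(c(0L, sample(4:23, 12, TRUE), 2L), 1)
  n <- ncol(ids)
  mask <- matrix(1L, 1, n)
  # shift right by one, with a masked pad prepended
  ids_s <- cbind(matrix(1L, 1, 1), ids)
  mask_s <- cbind(matrix(0L, 1, 1), mask)
  m_rope <- tiny_encoder(seed = 9, pe_type = "rope")
  a <- encoder_forward(m_rope, ids, mask)[1, , ]
  b <- encoder_forward(m_rope, ids_s, mask_s)[1, -1, ]
  expect_equal(a, b, tolerance = 1e-8)
  m_abs <- tiny_encoder(seed = 9, pe_type = "absolute")
  a2 <- encoder_forward(m_abs, ids, mask)[1, , ]
  b2 <- encoder_forward(m_abs, ids_s, mask_s)[1, -1, ]
  expect_gt(max(abs(a2 - b2)), 1e-4)
})

test_that("analytic gradients match central finite differences", {
  for (pe in c("rope", "absolute")) {
    m <- build_encoder(encoder_config(n_layers = 2, n_heads = 2, hidden_size = 8,
                                      intermediate_size = 16, pe_type = pe), seed = 3)
    set.seed(10)
    ids <- matrix(sample(4:23, 2 * 11, TRUE), 2, 11)
    ids[, 1] <- 0L; ids[, 11] <- 2L
    mask <- matrix(1L, 2, 11); mask[2, 9:11] <- 0L
    labels <- matrix(-100L, 2, 11)
    labels[1, c(3, 6)] <- ids[1, c(3, 6)]; labels[2, c(2, 5)] <- ids[2, c(2, 5)]
    fwd <- curriculab:::enc_forward(m, ids, mask, cache = TRUE)
    cg <- curriculab:::ce_and_grad(fwd$logits, as.vector(t(labels)))
    gr <- curriculab:::enc_backward(m, ids, mask, fwd, cg$dlogits)
    loss_at <- function(mm) {
      f <- curriculab:::enc_forward(mm, ids, mask)
      curriculab:::ce_and_grad(f$logits, as.vector(t(labels)), want_grad = FALSE)$ce
    }
    eps <- 1e-5
    for (nm in names(m$params)) {
      for (trial in 1:2) {
        i <- sample(length(m$params[[nm]]), 1)
        m2 <- m
        m2$params[[nm]][i] <- m$params[[nm]][i] + eps
        up <- loss_at(m2)
        m2$params[[nm]][i] <- m$params[[nm]][i] - eps
        dn <- loss_at(m2)
        num <- (up - dn) / (2 * eps)
        expect_lt(abs(num - gr[[nm]][i]), 1e-3 * max(1, abs(num)))
      }
    }
  }
})

test_that("an untrained encoder scores near the uniform cross-entropy", {
  v <- build_vocabulary()
  exs <- fixture_tokenized(n = 12, seed = 41)
  set.seed(2)
  labeled <- lapply(exs, apply_mlm, cfg = mlm_config(), vocab = v)
  m <- build_encoder(encoder_config(), seed = 20)  # desk-scale default
  r <- masked_eval(m, labeled)
  expect_lt(abs(r$ce_loss - log(33)), 0.1)
})

test_that("a short training run reduces held-out cross-entropy", {
  v <- build_vocabulary()
  rep <- generate_repertoire(40, 60, 20, seed = 51)
  tp <- lapply(rep$paired, tokenize_record, vocab = v)
  tu <- lapply(rep$unpaired, tokenize_record, vocab = v)
  sp <- split_train_eval_test(tp, 0.8, 1)
  su <- split_train_eval_test(tu, 0.8, 2)
  pools <- list(unpaired = su$train, paired = sp$train,
                eval_unpaired = su$eval, eval_paired = sp$eval)
  m <- build_encoder(encoder_config(n_layers = 1, n_heads = 2, hidden_size = 32,
                                    intermediate_size = 64), seed = 1)
  sched <- make_schedule("curriculum", total_steps = 120L)
  run <- train(m, pools, train_run_config(120L, 4L, schedule = sched, seed = 5), v)
  ev <- run$evals
  expect_equal(ev$step[1], 0)
  expect_lt(ev$ce_unpaired[nrow(ev)], ev$ce_unpaired[1])
  expect_lt(ev$ce_paired[nrow(ev)], ev$ce_paired[1])
  expect_identical(nrow(run$log), 120L)
  # a zero-step run returns only the initial evaluation
  run0 <- train(m, pools, train_run_config(0L, 4L, schedule = sched, seed = 5), v)
  expect_identical(nrow(run0$evals), 1L)
  expect_identical(nrow(run0$log), 0L)
  expect_identical(run0$model$params, m$params)
})

test_that("training runs are reproducible from the seed", {
  v <- build_vocabulary()
  rep <- generate_repertoire(15, 20, 8, seed = 61)
  tp <- lapply(rep$paired, tokenize_record, vocab = v)
  tu <- lapply(rep$unpaired, tokenize_record, vocab = v)
  sp <- split_train_eval_test(tp, 0.7, 1)
  su <- split_train_eval_test(tu, 0.7, 2)
  pools <- list(unpaired = su$train, paired = sp$train,
                eval_unpaired = su$eval, eval_paired = sp$eval)
  one <- function() {
    m <- tiny_encoder(seed = 2)
    sched <- make_schedule("constant", total_steps = 10L)
    train(m, pools, train_run_config(10L, 4L, schedule = sched, seed = 77), v)
  }
  r1 <- one(); r2 <- one()
  expect_identical(r1$log, r2$log)
  expect_identical(r1$model$params, r2$model$params)
})
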