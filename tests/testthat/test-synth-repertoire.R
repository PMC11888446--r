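test_that("empty and degenerate generation requests are honored", {
  rep <- generate_repertoire(0, 0, 0, seed = 1)
  expect_identical(rep$paired, list())
  expect_identical(rep$unpaired, list())

  rep <- generate_repertoire(20, 10, 10, naive_fraction = 1, seed = 2)
  muts <- c(
    vapply(rep$paired, function(p) p$heavy$mutation_count + p$light$mutation_count, integer(1)),
    vapply(rep$unpaired, function(s) s$mutation_count, integer(1)))
  expect_true(all(muts == 0L))
})

test_that("requested counts and chain types are exact", {
  rep <- fixture_repertoire(n_paired = 7, n_uh = 5, n_ul = 3)
  expect_length(rep$paired, 7)
  expect_length(rep$unpaired, 8)
  chains <- vapply(rep$unpaired, function(s) s$chain, character(1))
  expect_identical(sum(chains == "heavy"), 5L)
  expect_identical(sum(chains == "light"), 3L)
})

test_that("naive fraction lands inside a 3-standard-deviation binomial interval", {
  n <- 1000
  rep <- generate_repertoire(n, 0, 0, naive_fraction = 0.5, seed = 7)
  naive <- vapply(rep$paired, function(p) {
    p$heavy$mutation_count == 0L && p$light$mutation_count == 0L
  }, logical(1))
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(naive) - 0.5), 3 * se)
  # both chains of a native pair share the naive/memory state
  states <- vapply(rep$paired, function(p) {
    (p$heavy$mutation_count > 0L) == (p$light$mutation_count > 0L)
  }, logical(1))
  expect_true(all(states))
})

test_that("mutate_chain changes exactly the requested number of positions", {
  rep <- fixture_repertoire(n_paired = 1, n_uh = 0, n_ul = 0)
  seq0 <- rep$paired[[1]]$heavy
  expect_identical(mutate_chain(seq0, 0), seq0)

  hamming <- function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }
  set.seed(33)
  m3 <- mutate_chain(seq0, 3)
  expect_identical(hamming(m3$sequence, seq0$sequence), 3L)
  expect_identical(m3$mutation_count, seq0$mutation_count + 3L)
  expect_identical(m3$regions, seq0$regions)

  n <- nchar(seq0$sequence)
  all_mut <- mutate_chain(seq0, n)
  expect_identical(hamming(all_mut$sequence, seq0$sequence), n)
  expect_error(mutate_chain(seq0, n + 1), "n_mutations")
})

test_that("region annotations tile every generated sequence", {
  rep <- fixture_repertoire(n_paired = 15, n_uh = 15, n_ul = 15)
  seqs <- c(lapply(rep$paired, `[[`, "heavy"),
            lapply(rep$paired, `[[`, "light"), rep$unpaired)
  for (s in seqs) {
    ivs <- do.call(rbind, s$regions)
    ord <- order(ivs[, 1])
    ivs <- ivs[ord, ]
    expect_identical(ivs[1, 1], 0L)
    expect_identical(ivs[nrow(ivs), 2], nchar(s$sequence))
    expect_true(all(ivs[-1, 1] == ivs[-nrow(ivs), 2]))
    expect_identical(rownames(ivs), c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"))
  }
})

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_repertoire(10, 10, 5, seed = 99)
  b <- generate_repertoire(10, 10, 5, seed = 99)
  expect_identical(a, b)
  c <- generate_repertoire(10, 10, 5, seed = 100)
  expect_false(identical(a, c))
})

test_that("heavy chains are longer than light chains on average and in range", {
  rep <- fixture_repertoire(n_paired = 100, n_uh = 0, n_ul = 0)
  hl <- vapply(rep$paired, function(p) nchar(p$heavy$sequence), integer(1))
  ll <- vapply(rep$paired, function(p) nchar(p$light$sequence), integer(1))
  expect_gt(mean(hl), mean(ll))
  expect_true(all(hl >= 115 & hl <= 130))
  expect_true(all(ll >= 105 & ll <= 115))
})

test_that("paired token streams are roughly twice unpaired length", {
  v <- build_vocabulary()
  rep <- fixture_repertoire(n_paired = 40, n_uh = 40, n_ul = 40)
  ptok <- vapply(rep$paired, function(p) length(format_tokens(p)), integer(1))
  utok <- vapply(rep$unpaired, function(s) length(format_tokens(s)), integer(1))
  ratio <- mean(ptok) / mean(utok)
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("specificity labels carry learnable CDR3 motif signal", {
  rep <- generate_repertoire(0, 300, 0, seed = 5,
                             specificity = c("HD", "Flu", "CoV"))
  cls <- vapply(rep$unpaired, function(s) s$specificity, character(1))
  expect_true(all(cls %in% c("HD", "Flu", "CoV")))
  cdr3 <- function(s) {
    iv <- s$regions$CDR3
    substr(s$sequence, iv[[1]] + 1L, iv[[2]])
  }
  has_motif <- function(s, m) grepl(m, cdr3(s), fixed = TRUE)
  flu_rate <- mean(vapply(rep$unpaired[cls == "Flu"], has_motif, logical(1), m = "EDY"))
  hd_rate <- mean(vapply(rep$unpaired[cls == "HD"], has_motif, logical(1), m = "EDY"))
  expect_gt(flu_rate, 0.5)
  expect_lt(hd_rate, 0.2)
})

test_that("FASTA and CSV writers round-trip", {
  rep <- fixture_repertoire(n_paired = 4, n_uh = 3, n_ul = 2)
  fa <- tempfile(fileext = ".fasta")
  write_repertoire_fasta(rep$paired, rep$unpaired, fa)
  aa <- Biostrings::readAAStringSet(fa)
  expect_length(aa, 4 * 2 + 5)
  expect_identical(as.character(aa[["P000001/H"]]), rep$paired[[1]]$heavy$sequence)

  csv <- tempfile(fileext = ".csv")
  write_repertoire_csv(rep$paired, rep$unpaired, csv)
  back <- read_repertoire_csv(csv)
  expect_length(back$paired, 4)
  expect_length(back$unpaired, 5)
  expect_identical(back$paired[[1]]$heavy$sequence, rep$paired[[1]]$heavy$sequence)
  expect_identical(back$paired[[2]]$light$regions, rep$paired[[2]]$light$regions)
  expect_identical(back$unpaired[[3]]$mutation_count, rep$unpaired[[3]]$mutation_count)
})
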