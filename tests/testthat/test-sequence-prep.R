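test_that("the vocabulary always has exactly 33 tokens", {
  for (mode in c("unique_sep", "reuse_cls", "none")) {
    v <- build_vocabulary(mode)
    expect_length(v$tokens, 33)
    expect_true(all(c("L", "A", "G", "V", "S", "E", "R", "T", "I", "D", "P",
                      "K", "Q", "N", "F", "Y", "M", "H", "W", "C") %in% v$tokens))
  }
  expect_true("<sep>" %in% build_vocabulary("unique_sep")$tokens)
  expect_false("<sep>" %in% build_vocabulary("reuse_cls")$tokens)
  # the replacement preserves every other token id
  vs <- build_vocabulary("unique_sep"); vn <- build_vocabulary("none")
  expect_identical(vs$tokens[-32L], vn$tokens[-32L])
})

test_that("encode/decode round-trips all 33 ids", {
  for (mode in c("unique_sep", "reuse_cls")) {
    v <- build_vocabulary(mode)
    ids <- 0:32
    expect_identical(encode_tokens(v, decode_ids(v, ids)), ids)
  }
  expect_error(encode_tokens(build_vocabulary(), c("Q", "J")), "'J' at position 2")
})

make_pair <- function(h = "QVQ", l = "DIQ") {
  hs <- antibody_sequence("heavy", h, list(CDR3 = c(0, nchar(h))))
  ls <- antibody_sequence("light", l, list(CDR3 = c(0, nchar(l))))
  paired_record(hs, ls, "p1")
}

test_that("separator placement follows the chain rules", {
  pr <- make_pair()
  expect_identical(format_tokens(pr, "unique_sep"),
                   c("<cls>", "Q", "V", "Q", "<sep>", "D", "I", "Q", "<eos>"))
  expect_identical(format_tokens(pr, "reuse_cls"),
                   c("<cls>", "Q", "V", "Q", "<cls>", "D", "I", "Q", "<eos>"))
  expect_identical(format_tokens(pr, "none"),
                   c("<cls>", "Q", "V", "Q", "D", "I", "Q", "<eos>"))
  h <- antibody_sequence("heavy", "QVQ", list(CDR3 = c(0, 3)))
  expect_identical(format_tokens(h, "unique_sep"),
                   c("<cls>", "Q", "V", "Q", "<sep>", "<eos>"))
  l <- antibody_sequence("light", "DIQ", list(CDR3 = c(0, 3)))
  expect_identical(format_tokens(l, "unique_sep"),
                   c("<cls>", "<sep>", "D", "I", "Q", "<eos>"))
  expect_identical(format_tokens(l, "none"), c("<cls>", "D", "I", "Q", "<eos>"))
})

test_that("format_tokens is invertible", {
  rep <- fixture_repertoire(n_paired = 10, n_uh = 5, n_ul = 5)
  for (p in rep$paired) {
    toks <- format_tokens(p, "unique_sep")
    sep_at <- which(toks == "<sep>")
    expect_identical(paste(toks[2:(sep_at - 1)], collapse = ""), p$heavy$sequence)
    expect_identical(paste(toks[(sep_at + 1):(length(toks) - 1)], collapse = ""),
                     p$light$sequence)
  }
  for (u in rep$unpaired) {
    toks <- format_tokens(u, "unique_sep")
    expect_identical(
      paste(toks[!toks %in% c("<cls>", "<sep>", "<eos>")], collapse = ""),
      u$sequence)
  }
})

test_that("tokenize_and_pad produces fixed 320-length examples", {
  v <- build_vocabulary()
  pr <- make_pair()
  ex <- tokenize_and_pad(format_tokens(pr, "unique_sep"), v, "paired")
  expect_length(ex$ids, 320)
  expect_length(ex$attention_mask, 320)
  expect_length(ex$labels, 320)
  expect_identical(sum(ex$attention_mask), 9L)
  expect_true(all(ex$ids[10:320] == v$pad_id))
  expect_true(all(ex$attention_mask[10:320] == 0L))
  expect_true(all(ex$labels == -100L))
  expect_error(tokenize_and_pad(rep("Q", 321), v), "exceeds the 320-token limit")
  expect_error(tokenize_and_pad(character(0), v), "at least")
})

test_that("token-coordinate regions reflect the cls and separator offsets", {
  v <- build_vocabulary()
  rep <- fixture_repertoire(n_paired = 5, n_uh = 2, n_ul = 2)
  for (p in rep$paired) {
    ex <- tokenize_record(p, v)
    hlen <- nchar(p$heavy$sequence)
    # independent recomputation by direct index arithmetic on the token list
    expected_start <- 1L + hlen + 1L + p$light$regions$CDR3[[1]]
    expect_identical(ex$token_regions[["L-CDR3"]][["start"]], expected_start)
    expect_identical(ex$token_regions[["H-FR1"]][["start"]], 1L)
    # the tokens under H-CDR3 decode back to the heavy CDR3 residues
    iv <- ex$token_regions[["H-CDR3"]]
    decoded <- paste(decode_ids(v, ex$ids[(iv[["start"]] + 1):iv[["end"]]]), collapse = "")
    cdr3 <- substr(p$heavy$sequence, p$heavy$regions$CDR3[[1]] + 1L,
                   p$heavy$regions$CDR3[[2]])
    expect_identical(decoded, cdr3)
  }
  u <- rep$unpaired[[3]]  # a light chain: cls + sep precede the residues
  ex <- tokenize_record(u, v)
  expect_identical(ex$token_regions[["L-FR1"]][["start"]], 2L)
})

test_that("filter_and_dedup removes artifacts and exact duplicates", {
  seqs <- c("QVQLVQ", "QVnanQ", "QVQLVQ", "DIQMTQ", "QVQXZ9")
  out <- filter_and_dedup(seqs, identity_threshold = 1.0)
  expect_identical(out, c("QVQLVQ", "DIQMTQ"))
})

test_that("greedy clustering matches a brute-force identity matrix", {
  # hand-built 10-mers: s2 differs from s1 at 1/10 positions (90% identity),
  # s4 likewise from s3; s5 is unrelated
  s <- c("QVQLVQSGAE", "QVQLVQSGAY", "DIQMTQSPSS", "DIQMTQSPSL", "WGQGTLVTVS")
  ident <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- min(length(av), length(bv))
    sum(av[1:n] == bv[1:n]) / max(length(av), length(bv))
  }
  M <- outer(s, s, Vectorize(ident))
  expect_identical(sum(M[upper.tri(M)] >= 0.9), 2L)  # exactly the two pairs
  out <- filter_and_dedup(s, identity_threshold = 0.9)
  expect_identical(out, s[c(1, 3, 5)])
  # no two retained centroids reach the threshold (brute-force check)
  Mo <- outer(out, out, Vectorize(ident))
  expect_true(all(Mo[upper.tri(Mo)] < 0.9))
})

test_that("dedup centroid property holds on generated repertoires", {
  rep <- generate_repertoire(0, 60, 0, seed = 12, mutation_rate = 2)
  out <- filter_and_dedup(rep$unpaired, identity_threshold = 0.95)
  strings <- vapply(out, `[[`, character(1), "sequence")
  ident <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    sum(utf8ToInt(substr(a, 1, n)) == utf8ToInt(substr(b, 1, n))) /
      max(nchar(a), nchar(b))
  }
  for (i in seq_along(strings)) {
    for (j in seq_len(i - 1L)) {
      expect_lt(ident(strings[i], strings[j]), 0.95)
    }
  }
})

test_that("train/eval/test split is an exact seeded partition", {
  items <- seq_len(10000)
  sp <- split_train_eval_test(items, 0.96, seed = 3)
  expect_length(sp$train, 9600)
  expect_length(sp$eval, 200)
  expect_length(sp$test, 200)
  expect_setequal(c(sp$train, sp$eval, sp$test), items)
  expect_length(intersect(sp$train, c(sp$eval, sp$test)), 0)
  sp2 <- split_train_eval_test(items, 0.96, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_train_eval_test(1:2, 0.5, 1), "at least 3")
})
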