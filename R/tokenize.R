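MAX_TOKENS <- 320L

#' Lay out a record as a token string list
#'
#' Applies the separator placement rules: paired sequences carry the
#' separator between the heavy and light chains, unpaired heavy chains at
#' their end, and unpaired light chains at their beginning — so the model
#' can infer chain identity and position from the separator alone. Every
#' input is framed by `<cls>` ... `<eos>`. With policy `none` the separator
#' is omitted everywhere; with `reuse_cls` the separator token is `<cls>`
#' itself.
#'
#' @param record A [paired_record()] or an [antibody_sequence()].
#' @param policy Separator policy: `"unique_sep"`, `"reuse_cls"` or `"none"`.
#' @return Character vector of unpadded token strings.
#' @export
format_tokens <- function(record, policy = c("unique_sep", "reuse_cls", "none")) {
  policy <- match.arg(policy)
  sep_tok <- switch(policy, unique_sep = "<sep>", reuse_cls = "<cls>", none = NULL)
  split_checked <- function(s, what) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% CANONICAL_AA)
    if (length(bad)) {
      stop_config(sprintf("unknown residue '%s' at position %d of %s chain",
                          chars[bad[1L]], bad[1L], what))
    }
    chars
  }
  if (inherits(record, "paired_record")) {
    c("<cls>", split_checked(record$heavy$sequence, "heavy"), sep_tok,
      split_checked(record$light$sequence, "light"), "<eos>")
  } else if (inherits(record, "antibody_sequence")) {
    if (record$chain == "heavy") {
      c("<cls>", split_checked(record$sequence, "heavy"), sep_tok, "<eos>")
    } else {
      c("<cls>", sep_tok, split_checked(record$sequence, "light"), "<eos>")
    }
  } else {
    stop_config("record must be a paired_record or antibody_sequence")
  }
}

#' Tokenize a formatted token list to a fixed-length example
#'
#' Converts token strings to ids and pads to exactly 320 positions — sized
#' to the longest paired input — with the attention mask 1 over real tokens
#' and 0 over padding. MLM labels are initialized to the ignore sentinel
#' (-100); masking happens later in [apply_mlm()].
#'
#' @param tokens Character vector from [format_tokens()]; at most 320 long.
#' @param vocab An [build_vocabulary()] object.
#' @param origin One of `"paired"`, `"unpaired_heavy"`, `"unpaired_light"`.
#' @param token_regions Optional named list of token-coordinate intervals
#'   (0-based half-open), as produced by [tokenize_record()].
#' @return An object of class `tokenized_example` with fields `ids`,
#'   `attention_mask`, `labels` (each length 320), `origin`, `token_regions`.
#' @export
tokenize_and_pad <- function(tokens, vocab,
                             origin = c("paired", "unpaired_heavy", "unpaired_light"),
                             token_regions = NULL) {
  origin <- match.arg(origin)
  n <- length(tokens)
  if (n < 2L) stop_config("token list must contain at least <cls> and <eos>")
  if (n > MAX_TOKENS) {
    stop_config(sprintf("input of %d tokens exceeds the %d-token limit", n, MAX_TOKENS))
  }
  ids <- c(encode_tokens(vocab, tokens), rep(vocab$pad_id, MAX_TOKENS - n))
  structure(list(
    ids = as.integer(ids),
    attention_mask = c(rep(1L, n), rep(0L, MAX_TOKENS - n)),
    labels = rep(IGNORE_INDEX, MAX_TOKENS),
    origin = origin,
    token_regions = token_regions
  ), class = "tokenized_example")
}

#' @export
print.tokenized_example <- function(x, ...) {
  n <- sum(x$attention_mask)
  cat(sprintf("<tokenized_example> %s, %d real tokens (+%d pad)\n",
              x$origin, n, length(x$ids) - n))
  invisible(x)
}

#' Tokenize a record with region bookkeeping
#'
#' Convenience wrapper: [format_tokens()] then [tokenize_and_pad()], also
#' translating the record's residue-coordinate region annotations into
#' token coordinates. Heavy-chain regions are prefixed `H-` and shifted by
#' the leading `<cls>`; light-chain regions are prefixed `L-` and, for
#' paired inputs, additionally shifted by the heavy length plus the
#' separator (if any).
#'
#' @inheritParams format_tokens
#' @param vocab An [build_vocabulary()] object; its separator mode is used
#'   as the policy unless `policy` is given.
#' @param policy Optional explicit separator policy.
#' @return A `tokenized_example` with `token_regions` populated.
#' @export
tokenize_record <- function(record, vocab, policy = NULL) {
  policy <- policy %||% vocab$separator_mode
  tokens <- format_tokens(record, policy)
  sep_len <- if (policy == "none") 0L else 1L
  shift_regions <- function(regions, prefix, offset) {
    out <- lapply(regions, function(r) c(start = r[[1]] + offset, end = r[[2]] + offset))
    names(out) <- paste0(prefix, names(regions))
    out
  }
  if (inherits(record, "paired_record")) {
    hlen <- nchar(record$heavy$sequence)
    token_regions <- c(
      shift_regions(record$heavy$regions, "H-", 1L),
      shift_regions(record$light$regions, "L-", 1L + hlen + sep_len)
    )
    origin <- "paired"
  } else if (record$chain == "heavy") {
    token_regions <- shift_regions(record$regions, "H-", 1L)
    origin <- "unpaired_heavy"
  } else {
    token_regions <- shift_regions(record$regions, "L-", 1L + sep_len)
    origin <- "unpaired_light"
  }
  tokenize_and_pad(tokens, vocab, origin, token_regions)
}

#' Filter and deduplicate sequences by greedy identity clustering
#'
#' A desk-scale stand-in for AntiRef-style clustering. First removes
#' sequences containing the literal substring `"nan"` (case-insensitive, an
#' artifact of tabular exports) or characters outside the canonical residue
#' alphabet. Then clusters greedily in input order: a sequence joins the
#' first existing centroid with identity >= `identity_threshold`, otherwise
#' becomes a new centroid; only centroids are returned. Identity is the
#' number of position-wise matches over the leading `min(len)` positions,
#' divided by `max(len)` (no alignment).
#'
#' @param sequences Character vector, or a list of [antibody_sequence()] /
#'   [paired_record()] objects (paired records are compared on the
#'   concatenated heavy+light string).
#' @param identity_threshold Clustering threshold in (0, 1].
#' @return The retained elements of `sequences`, first-occurrence order.
#' @export
filter_and_dedup <- function(sequences, identity_threshold = 0.9) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 || identity_threshold > 1) {
    stop_config("identity_threshold must be in (0, 1]")
  }
  strings <- sequence_strings(sequences)
  ok <- !grepl("nan", strings, ignore.case = TRUE) &
    grepl(sprintf("^[%s]+$", paste(CANONICAL_AA, collapse = "")), strings)
  keep_idx <- which(ok)
  centroids <- character(0)
  centroid_idx <- integer(0)
  for (i in keep_idx) {
    s <- strings[i]
    joined <- FALSE
    for (c_s in centroids) {
      if (pairwise_identity(s, c_s) >= identity_threshold) { joined <- TRUE; break }
    }
    if (!joined) {
      centroids <- c(centroids, s)
      centroid_idx <- c(centroid_idx, i)
    }
  }
  if (is.list(sequences)) sequences[centroid_idx] else sequences[centroid_idx]
}

sequence_strings <- function(sequences) {
  if (is.character(sequences)) return(sequences)
  vapply(sequences, function(x) {
    if (inherits(x, "paired_record")) paste0(x$heavy$sequence, x$light$sequence)
    else if (inherits(x, "antibody_sequence")) x$sequence
    else as.character(x)
  }, character(1))
}

# Position-wise identity over the shorter length, normalized by the longer.
pairwise_identity <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L) return(0)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  sum(av == bv) / max(na, nb)
}

#' Split items into train / eval / test sets
#'
#' Seeded shuffle, then an exact partition: `round(train_fraction * n)`
#' items for training and the holdout split half-and-half between the
#' evaluation and test sets (evaluation receives the extra item when the
#' holdout is odd).
#'
#' @param items A list or vector.
#' @param train_fraction Training proportion in (0, 1); the pre-training
#'   datasets use 0.96.
#' @param seed Integer seed.
#' @return A list with elements `train`, `eval`, `test`.
#' @export
split_train_eval_test <- function(items, train_fraction = 0.96, seed = 42L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_config("train_fraction must be in (0, 1)")
  }
  n <- length(items)
  if (n < 3L) stop_config("need at least 3 items to form train/eval/test sets")
  with_seed(derive_seed(seed, "split"), {
    perm <- sample.int(n)
    n_train <- round(train_fraction * n)
    n_train <- max(1L, min(n - 2L, n_train))
    holdout <- perm[-seq_len(n_train)]
    n_eval <- ceiling(length(holdout) / 2)
    list(train = items[perm[seq_len(n_train)]],
         eval = items[holdout[seq_len(n_eval)]],
         test = items[holdout[-seq_len(n_eval)]])
  })
}
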