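#' Build the 33-token model vocabulary
#'
#' The vocabulary is the ESM-2 token set (4 leading specials, 20 canonical
#' residues, ambiguity codes, gap characters, a placeholder, and the mask
#' token) with an optional chain-separator token. Three separator policies
#' are supported:
#' \describe{
#'   \item{`unique_sep`}{the base vocabulary's unused `<null_1>` placeholder
#'     is replaced by a dedicated `<sep>` token, so the size stays 33 and
#'     every other token keeps its id;}
#'   \item{`reuse_cls`}{no `<sep>` token exists; the `<cls>` token doubles
#'     as the chain separator;}
#'   \item{`none`}{no separator is placed anywhere (the vocabulary is the
#'     unmodified base set).}
#' }
#'
#' @param separator_mode One of `"unique_sep"`, `"reuse_cls"`, `"none"`.
#' @return An object of class `ab_vocab`: the ordered token list, a
#'   token-to-id map (ids are 0-based, following the ESM-2 convention), and
#'   the ids of the structural tokens (`cls`, `pad`, `eos`, `unk`, `mask`,
#'   and `sep` where defined).
#' @export
build_vocabulary <- function(separator_mode = c("unique_sep", "reuse_cls", "none")) {
  separator_mode <- match.arg(separator_mode)
  tokens <- c("<cls>", "<pad>", "<eos>", "<unk>", CANONICAL_AA,
              "X", "B", "U", "Z", "O", ".", "-", "<null_1>", "<mask>")
  stopifnot(length(tokens) == 33L)
  if (separator_mode == "unique_sep") {
    tokens[tokens == "<null_1>"] <- "<sep>"
  }
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  sep_id <- switch(separator_mode,
                   unique_sep = index[["<sep>"]],
                   reuse_cls = index[["<cls>"]],
                   none = NA_integer_)
  structure(list(
    tokens = tokens,
    index = index,
    separator_mode = separator_mode,
    cls_id = index[["<cls>"]], pad_id = index[["<pad>"]],
    eos_id = index[["<eos>"]], unk_id = index[["<unk>"]],
    mask_id = index[["<mask>"]], sep_id = sep_id,
    # ids eligible for MLM selection: residue-letter tokens (canonical +
    # ambiguity codes), never structural or gap tokens
    residue_ids = unname(index[CANONICAL_AA]),
    eligible_ids = unname(index[c(CANONICAL_AA, "X", "B", "U", "Z", "O")])
  ), class = "ab_vocab")
}

#' @export
print.ab_vocab <- function(x, ...) {
  cat(sprintf("<ab_vocab> %d tokens, separator mode '%s'\n",
              length(x$tokens), x$separator_mode))
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Encode tokens to ids / decode ids to tokens
#'
#' @param vocab An [build_vocabulary()] object.
#' @param tokens Character vector of token strings.
#' @param ids Integer vector of 0-based token ids.
#' @return `encode_tokens()` returns 0-based integer ids; `decode_ids()`
#'   returns token strings.
#' @export
encode_tokens <- function(vocab, tokens) {
  ids <- vocab$index[tokens]
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1L]
    stop_config(sprintf("unknown token '%s' at position %d", tokens[bad], bad))
  }
  unname(ids)
}

#' @rdname encode_tokens
#' @export
decode_ids <- function(vocab, ids) {
  if (any(ids < 0L | ids >= length(vocab$tokens))) {
    stop_config("token id out of range")
  }
  vocab$tokens[ids + 1L]
}
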