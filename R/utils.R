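# Internal helpers shared across modules.

# The 20 canonical amino acids, in ESM-2 vocabulary order.
CANONICAL_AA <- c("L", "A", "G", "V", "S", "E", "R", "T", "I", "D",
                  "P", "K", "Q", "N", "F", "Y", "M", "H", "W", "C")

# Sentinel for positions that carry no MLM prediction label.
IGNORE_INDEX <- -100L

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so seeded package functions never perturb the user's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically derive a child seed < 2^31 from a base seed and a
# string tag (pool name, stage name, epoch number ...). Cheap polynomial
# rolling hash; collisions across tags are irrelevant as long as the map
# is deterministic.
derive_seed <- function(seed, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(tag)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

stop_config <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config(sprintf("`%s` must be a single value in [0, 1], got %s",
                        name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}
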