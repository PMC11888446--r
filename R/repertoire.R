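#' Antibody sequence and paired-record containers
#'
#' `antibody_sequence()` holds one chain (heavy or light): its amino-acid
#' string, region annotations (0-based half-open intervals that tile the
#' sequence), a somatic mutation count (0 for naive B-cell sequences, >= 1
#' for memory), the germline segment identifier it was assembled from, and
#' an optional specificity class label. `paired_record()` holds a natively
#' associated heavy/light pair.
#'
#' @param chain `"heavy"` or `"light"`.
#' @param sequence Amino-acid string over the 20 canonical residues.
#' @param regions Named list of `c(start, end)` 0-based half-open intervals
#'   (`FR1`, `CDR1`, `FR2`, `CDR2`, `FR3`, `CDR3`, `FR4`) tiling the sequence.
#' @param mutation_count Non-negative integer, at most `nchar(sequence)`.
#' @param germline_id Identifier of the originating V/J segments.
#' @param specificity Optional class label (e.g. `"HD"`, `"Flu"`, `"CoV"`).
#' @return An object of class `antibody_sequence`.
#' @export
antibody_sequence <- function(chain, sequence, regions, mutation_count = 0L,
                              germline_id = NA_character_, specificity = NULL) {
  chain <- match.arg(chain, c("heavy", "light"))
  if (!grepl(sprintf("^[%s]+$", paste(CANONICAL_AA, collapse = "")), sequence)) {
    stop_config("sequence must be a non-empty string over the 20 canonical amino acids")
  }
  n <- nchar(sequence)
  if (!is_count(mutation_count) || mutation_count > n) {
    stop_config("mutation_count must be a non-negative integer <= sequence length")
  }
  validate_region_tiling(regions, n)
  structure(list(chain = chain, sequence = sequence, regions = regions,
                 mutation_count = as.integer(mutation_count),
                 germline_id = germline_id, specificity = specificity),
            class = "antibody_sequence")
}

validate_region_tiling <- function(regions, n) {
  if (is.null(names(regions)) || any(names(regions) == "")) {
    stop_config("regions must be a named list of intervals")
  }
  ivs <- do.call(rbind, lapply(regions, function(r) as.integer(r[1:2])))
  ord <- order(ivs[, 1])
  ivs <- ivs[ord, , drop = FALSE]
  if (ivs[1, 1] != 0L || ivs[nrow(ivs), 2] != n ||
      any(ivs[, 2] <= ivs[, 1]) ||
      (nrow(ivs) > 1 && any(ivs[-1, 1] != ivs[-nrow(ivs), 2]))) {
    stop_config("region intervals must tile [0, sequence length) without gaps or overlaps")
  }
  invisible(regions)
}

#' @rdname antibody_sequence
#' @param heavy,light `antibody_sequence` objects with matching `chain`.
#' @param pair_id Identifier shared by the two chains (lineage/droplet id).
#' @param is_native `TRUE` for natively paired records, `FALSE` for
#'   artificial (shuffled) pairings such as pair-classification negatives.
#' @export
paired_record <- function(heavy, light, pair_id, is_native = TRUE) {
  if (!inherits(heavy, "antibody_sequence") || heavy$chain != "heavy") {
    stop_config("`heavy` must be an antibody_sequence with chain = 'heavy'")
  }
  if (!inherits(light, "antibody_sequence") || light$chain != "light") {
    stop_config("`light` must be an antibody_sequence with chain = 'light'")
  }
  structure(list(heavy = heavy, light = light, pair_id = as.character(pair_id),
                 is_native = isTRUE(is_native)),
            class = "paired_record")
}

#' @export
print.antibody_sequence <- function(x, ...) {
  cat(sprintf("<%s chain> %d aa, %d mutation(s)%s\n  %s\n", x$chain,
              nchar(x$sequence), x$mutation_count,
              if (!is.null(x$specificity)) paste0(", ", x$specificity) else "",
              x$sequence))
  invisible(x)
}

#' @export
print.paired_record <- function(x, ...) {
  cat(sprintf("<paired record %s>%s\n", x$pair_id,
              if (x$is_native) "" else " (non-native)"))
  cat(sprintf("  H (%3d aa, %d mut): %s\n", nchar(x$heavy$sequence),
              x$heavy$mutation_count, x$heavy$sequence))
  cat(sprintf("  L (%3d aa, %d mut): %s\n", nchar(x$light$sequence),
              x$light$mutation_count, x$light$sequence))
  invisible(x)
}

# CDR3 motifs used to give specificity classes learnable sequence signal.
# "HD" (healthy donor, nonspecific) carries no motif by design.
SPECIFICITY_MOTIFS <- list(HD = NULL, Flu = "EDY", CoV = "RGW")

#' Generate a synthetic antibody repertoire
#'
#' Assembles seeded synthetic paired and unpaired repertoires with the
#' structure the rest of the framework assumes: each chain is built by
#' choosing germline V and J segments, inserting a randomized CDR3 junction,
#' and applying somatic mutations. A fraction `naive_fraction` of records is
#' naive (zero mutations on every chain); the remainder are memory, with
#' per-chain mutation counts drawn from a Poisson distribution with mean
#' `mutation_rate` truncated to >= 1. Both chains of a native pair share the
#' naive/memory state, as they derive from one B cell.
#'
#' @param n_paired,n_unpaired_heavy,n_unpaired_light Numbers of records.
#' @param mutation_rate Mean mutations per memory chain (Poisson mean).
#' @param naive_fraction Probability that a record is naive (unmutated).
#' @param seed Integer seed; output is byte-identical across calls with
#'   identical arguments.
#' @param library A [germline_library()]; defaults to the built-in library.
#' @param specificity Optional character vector of class names (see
#'   [SPECIFICITY_MOTIFS] for the built-in classes); when given, every
#'   record is assigned a class, and non-HD classes receive a class motif in
#'   the heavy CDR3 (probability `motif_prob`) plus a biased V-segment
#'   choice so that classifiers have learnable signal.
#' @param motif_prob Probability that a non-HD record carries its class
#'   CDR3 motif.
#' @return A list with elements `paired` (list of [paired_record()]) and
#'   `unpaired` (list of [antibody_sequence()], heavy chains first).
#' @export
generate_repertoire <- function(n_paired, n_unpaired_heavy, n_unpaired_light,
                                mutation_rate = 6, naive_fraction = 0.5,
                                seed = 42L, library = germline_library(),
                                specificity = NULL, motif_prob = 0.8) {
  stopifnot(is_count(n_paired), is_count(n_unpaired_heavy), is_count(n_unpaired_light))
  check_proportion(naive_fraction, "naive_fraction")
  if (mutation_rate < 0) stop_config("mutation_rate must be >= 0")
  if (!inherits(library, "germline_library")) {
    stop_config("`library` must be a germline_library object")
  }
  with_seed(seed, {
    paired <- vector("list", n_paired)
    if (n_paired > 0) {
      for (i in seq_len(n_paired)) {
        naive <- stats::runif(1) < naive_fraction
        cls <- draw_class(specificity)
        h <- assemble_chain("heavy", library, naive, mutation_rate, cls, motif_prob)
        l <- assemble_chain("light", library, naive, mutation_rate, cls, motif_prob)
        paired[[i]] <- paired_record(h, l, pair_id = sprintf("P%06d", i))
      }
    }
    unpaired <- vector("list", n_unpaired_heavy + n_unpaired_light)
    chains <- rep(c("heavy", "light"), c(n_unpaired_heavy, n_unpaired_light))
    for (i in seq_along(chains)) {
      naive <- stats::runif(1) < naive_fraction
      cls <- draw_class(specificity)
      unpaired[[i]] <- assemble_chain(chains[i], library, naive, mutation_rate,
                                      cls, motif_prob)
    }
    list(paired = paired, unpaired = unpaired)
  })
}

draw_class <- function(specificity) {
  if (is.null(specificity)) NULL else sample(specificity, 1L)
}

# Build one chain: V + random CDR3 junction + J, then mutate. Uses the
# current RNG state; callers are responsible for seeding.
assemble_chain <- function(chain, library, naive, mutation_rate,
                           specificity = NULL, motif_prob = 0.8) {
  vs <- if (chain == "heavy") library$heavy_v else library$light_v
  js <- if (chain == "heavy") library$heavy_j else library$light_j
  jr <- if (chain == "heavy") library$heavy_junction else library$light_junction
  template <- if (chain == "heavy") library$heavy_template else library$light_template

  vi <- pick_v_segment(length(vs), specificity)
  ji <- sample(length(js), 1L)
  v_regions <- vs[[vi]]
  v_seq <- paste(v_regions[V_REGIONS], collapse = "")

  jl <- sample(seq(jr[1], jr[2]), 1L)
  junction <- paste(sample(CANONICAL_AA, jl, replace = TRUE), collapse = "")
  if (chain == "heavy" && !is.null(specificity)) {
    motif <- SPECIFICITY_MOTIFS[[specificity]] %||% NULL
    if (!is.null(motif) && nchar(motif) < jl && stats::runif(1) < motif_prob) {
      substr(junction, 2L, 1L + nchar(motif)) <- motif
    }
  }
  j_seq <- js[[ji]]

  lv <- nchar(v_seq)
  regions <- c(template, list(
    CDR3 = c(start = lv, end = lv + jl),
    FR4 = c(start = lv + jl, end = lv + jl + nchar(j_seq))
  ))
  seq <- antibody_sequence(
    chain = chain,
    sequence = paste0(v_seq, junction, j_seq),
    regions = regions,
    mutation_count = 0L,
    germline_id = paste(names(vs)[vi], names(js)[ji], sep = "/"),
    specificity = specificity
  )
  if (!naive) {
    n_mut <- 0L
    while (n_mut == 0L) n_mut <- stats::rpois(1L, mutation_rate)
    n_mut <- min(n_mut, nchar(seq$sequence))
    seq <- mutate_chain(seq, n_mut)
  }
  seq
}

# Specificity classes softly prefer one V segment each, adding germline
# usage bias on top of the CDR3 motif.
pick_v_segment <- function(n_v, specificity) {
  if (is.null(specificity)) return(sample(n_v, 1L))
  cls_idx <- match(specificity, names(SPECIFICITY_MOTIFS))
  preferred <- if (is.na(cls_idx)) 1L else ((cls_idx - 1L) %% n_v) + 1L
  if (stats::runif(1) < 0.6) preferred else sample(n_v, 1L)
}

#' Apply somatic point mutations to a chain
#'
#' Substitutes exactly `n_mutations` distinct positions of the chain, each
#' to a residue drawn uniformly from the 19 alternatives, emulating the
#' amino-acid effect of somatic hypermutation. Region annotations are
#' unchanged (substitutions preserve length); `mutation_count` is
#' incremented by `n_mutations`. Draws from the current RNG state; seed
#' before calling for reproducibility.
#'
#' @param seq An [antibody_sequence()].
#' @param n_mutations Number of positions to substitute; at most the chain
#'   length.
#' @return The mutated `antibody_sequence`.
#' @export
mutate_chain <- function(seq, n_mutations) {
  stopifnot(inherits(seq, "antibody_sequence"))
  n <- nchar(seq$sequence)
  if (!is_count(n_mutations) || n_mutations > n) {
    stop_config(sprintf("n_mutations (%s) must be an integer in [0, %d]",
                        format(n_mutations), n))
  }
  if (n_mutations == 0L) return(seq)
  chars <- strsplit(seq$sequence, "", fixed = TRUE)[[1L]]
  pos <- sample(n, n_mutations)
  for (p in pos) {
    chars[p] <- sample(setdiff(CANONICAL_AA, chars[p]), 1L)
  }
  seq$sequence <- paste(chars, collapse = "")
  seq$mutation_count <- seq$mutation_count + as.integer(n_mutations)
  seq
}

#' Write a repertoire to FASTA or CSV
#'
#' FASTA records are one per chain; the two chains of a pair share the pair
#' id with `/H` and `/L` suffixes. The CSV dialect carries one row per
#' chain with columns `pair_id`, `chain`, `sequence`, `regions` (encoded as
#' `NAME:start-end;...`), `mutation_count`, `germline_id`, `specificity`,
#' and is read back by [read_repertoire_csv()].
#'
#' @param paired List of [paired_record()].
#' @param unpaired List of [antibody_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repertoire_fasta <- function(paired, unpaired, path) {
  seqs <- character(0)
  for (p in paired) {
    seqs[paste0(p$pair_id, "/H")] <- p$heavy$sequence
    seqs[paste0(p$pair_id, "/L")] <- p$light$sequence
  }
  for (i in seq_along(unpaired)) {
    u <- unpaired[[i]]
    seqs[sprintf("U%06d/%s", i, toupper(substr(u$chain, 1, 1)))] <- u$sequence
  }
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

encode_regions <- function(regions) {
  paste(vapply(names(regions), function(nm) {
    sprintf("%s:%d-%d", nm, regions[[nm]][1], regions[[nm]][2])
  }, character(1)), collapse = ";")
}

decode_regions <- function(txt) {
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  regions <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([^:]+):(\\d+)-(\\d+)$", p))[[1L]]
    c(start = as.integer(m[3]), end = as.integer(m[4]))
  })
  names(regions) <- sub(":.*$", "", parts)
  regions
}

chain_row <- function(seq, pair_id) {
  data.frame(pair_id = pair_id, chain = seq$chain, sequence = seq$sequence,
             regions = encode_regions(seq$regions),
             mutation_count = seq$mutation_count,
             germline_id = seq$germline_id,
             specificity = if (is.null(seq$specificity)) NA_character_ else seq$specificity,
             stringsAsFactors = FALSE)
}

#' @rdname write_repertoire_fasta
#' @export
write_repertoire_csv <- function(paired, unpaired, path) {
  rows <- list()
  for (p in paired) {
    rows[[length(rows) + 1L]] <- chain_row(p$heavy, p$pair_id)
    rows[[length(rows) + 1L]] <- chain_row(p$light, p$pair_id)
  }
  for (i in seq_along(unpaired)) {
    rows[[length(rows) + 1L]] <- chain_row(unpaired[[i]], sprintf("U%06d", i))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    chain_row(antibody_sequence("heavy", "Q", list(FR1 = c(0, 1))), "x")[0, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a repertoire CSV back into records
#'
#' Inverse of [write_repertoire_csv()]: rows sharing a `pair_id` with one
#' heavy and one light chain become [paired_record()]s; singleton rows
#' become unpaired [antibody_sequence()]s.
#'
#' @param path CSV file written by [write_repertoire_csv()].
#' @return A list with elements `paired` and `unpaired`.
#' @export
read_repertoire_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  row_to_seq <- function(r) {
    antibody_sequence(r$chain, r$sequence, decode_regions(r$regions),
                      r$mutation_count, r$germline_id,
                      if (is.na(r$specificity)) NULL else r$specificity)
  }
  paired <- list(); unpaired <- list()
  for (pid in unique(df$pair_id)) {
    sub <- df[df$pair_id == pid, , drop = FALSE]
    if (nrow(sub) == 2L && setequal(sub$chain, c("heavy", "light"))) {
      h <- row_to_seq(sub[sub$chain == "heavy", ][1, ])
      l <- row_to_seq(sub[sub$chain == "light", ][1, ])
      paired[[length(paired) + 1L]] <- paired_record(h, l, pid)
    } else {
      for (i in seq_len(nrow(sub))) {
        unpaired[[length(unpaired) + 1L]] <- row_to_seq(sub[i, ])
      }
    }
  }
  list(paired = paired, unpaired = unpaired)
}
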