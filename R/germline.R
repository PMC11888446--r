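#' Built-in germline segment library
#'
#' Antibody variable domains are assembled from germline gene segments: a V
#' segment contributing framework regions FR1-FR3 and the first two CDRs, a
#' largely non-templated CDR3 junction, and a J segment contributing FR4.
#' The package ships a small self-contained library of amino-acid V and J
#' segments (4 V and 2 J per chain type) whose lengths were chosen so that
#' assembled heavy chains span 115-130 aa and light chains 105-115 aa,
#' bracketing typical human variable-domain lengths. Segment sequences are
#' human-germline-like but synthetic; no biological fidelity is claimed.
#'
#' @param heavy_v,light_v Named lists of V segments. Each element is a named
#'   character vector of region strings (`FR1`, `CDR1`, `FR2`, `CDR2`,
#'   `FR3`); all V segments of a chain type must share region lengths.
#' @param heavy_j,light_j Named character vectors of J (FR4) segments.
#' @param heavy_junction,light_junction Integer length-2 vectors giving the
#'   inclusive range of CDR3 junction lengths drawn at assembly time.
#'
#' @return An object of class `germline_library`: segment tables plus the
#'   per-chain region templates (0-based half-open intervals within the V
#'   portion) used to annotate assembled chains.
#' @export
germline_library <- function(heavy_v = NULL, heavy_j = NULL,
                             light_v = NULL, light_j = NULL,
                             heavy_junction = c(5L, 20L),
                             light_junction = c(5L, 15L)) {
  if (is.null(heavy_v)) {
    built <- builtin_segments()
    heavy_v <- built$heavy_v; heavy_j <- built$heavy_j
    light_v <- built$light_v; light_j <- built$light_j
  }
  if (length(heavy_v) == 0L || length(heavy_j) == 0L ||
      length(light_v) == 0L || length(light_j) == 0L) {
    stop_config("germline library must contain at least one V and one J segment per chain type")
  }
  lib <- structure(list(
    heavy_v = heavy_v, heavy_j = heavy_j,
    light_v = light_v, light_j = light_j,
    heavy_junction = as.integer(heavy_junction),
    light_junction = as.integer(light_junction)
  ), class = "germline_library")
  lib$heavy_template <- v_region_template(heavy_v)
  lib$light_template <- v_region_template(light_v)
  validate_germline_library(lib)
  lib
}

V_REGIONS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")
CHAIN_REGIONS <- c(V_REGIONS, "CDR3", "FR4")

# Region intervals (0-based half-open) within the V portion, derived from
# the shared per-region lengths of a V segment list.
v_region_template <- function(v_segments) {
  lens <- nchar(v_segments[[1L]][V_REGIONS])
  for (v in v_segments) {
    if (!identical(unname(nchar(v[V_REGIONS])), unname(lens))) {
      stop_config("all V segments of a chain type must share region lengths")
    }
  }
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  template <- mapply(function(s, e) c(start = s, end = e), starts, ends,
                     SIMPLIFY = FALSE)
  names(template) <- V_REGIONS
  template
}

validate_germline_library <- function(lib) {
  check_seg <- function(x, what) {
    if (!all(grepl(sprintf("^[%s]+$", paste(CANONICAL_AA, collapse = "")), x))) {
      stop_config(what, " segments must be non-empty strings over the 20 canonical amino acids")
    }
  }
  check_seg(unlist(lapply(lib$heavy_v, paste, collapse = "")), "heavy V")
  check_seg(unlist(lapply(lib$light_v, paste, collapse = "")), "light V")
  check_seg(lib$heavy_j, "heavy J")
  check_seg(lib$light_j, "light J")
  for (jr in list(lib$heavy_junction, lib$light_junction)) {
    if (length(jr) != 2L || jr[1] < 1L || jr[2] < jr[1]) {
      stop_config("junction length range must be an increasing positive pair")
    }
  }
  invisible(lib)
}

# Hardcoded human-like base segments; V variants are derived from the base
# by fixed point substitutions so region lengths stay aligned by construction.
builtin_segments <- function() {
  heavy_base <- c(
    FR1  = "QVQLVQSGAEVKKPGASVKVSCKAS",                   # 25 aa
    CDR1 = "GYTFTSYG",                                    # 8 aa
    FR2  = "ISWVRQAPGQGLEWMGW",                           # 17 aa
    CDR2 = "ISAYNGNT",                                    # 8 aa
    FR3  = "NYAQKLQGRVTMTTDTSTSTAYMELRSLRSDDTAVYYCARD"    # 41 aa
  )
  light_base <- c(
    FR1  = "DIQMTQSPSSLSASVGDRVTITC",                     # 23 aa
    CDR1 = "QASQDISN",                                    # 8 aa
    FR2  = "YLNWYQQKPGKAPKL",                             # 15 aa
    CDR2 = "DASNLET",                                     # 7 aa
    FR3  = "GVPSRFSGSGSGTDFTFTISSLQPEDIATYYCQQYDN"        # 37 aa
  )
  variant <- function(base, ...) {
    repl <- c(...)
    base[names(repl)] <- repl
    base
  }
  heavy_v <- list(
    HV1 = heavy_base,
    HV2 = variant(heavy_base, CDR1 = "GGTFSSYA"),
    HV3 = variant(heavy_base, FR1 = "EVQLVESGGGLVQPGGSLRLSCAAS", CDR2 = "ISGSGGST"),
    HV4 = variant(heavy_base, CDR1 = "GFTFSNYW", FR2 = "MSWVRQAPGKGLEWVSY")
  )
  light_v <- list(
    LV1 = light_base,
    LV2 = variant(light_base, CDR1 = "QSISSYLN"),
    LV3 = variant(light_base, FR1 = "EIVLTQSPGTLSLSPGERATLSC", CDR2 = "GASSRAT"),
    LV4 = variant(light_base, CDR1 = "QDISRWLA", FR3 = "GVPSRFSGSGSGTEFTLTISSLQPDDFATYYCQQANS")
  )
  list(
    heavy_v = heavy_v,
    heavy_j = c(HJ1 = "WGQGTLVTVSS", HJ2 = "WGQGTTVTVSS"),  # 11 aa FR4
    light_v = light_v,
    light_j = c(LJ1 = "FGQGTKVEIK", LJ2 = "FGGGTKVEIK")     # 10 aa FR4
  )
}

#' @export
print.germline_library <- function(x, ...) {
  cat("Germline segment library\n")
  cat(sprintf("  heavy: %d V x %d J, junction %d-%d aa\n",
              length(x$heavy_v), length(x$heavy_j),
              x$heavy_junction[1], x$heavy_junction[2]))
  cat(sprintf("  light: %d V x %d J, junction %d-%d aa\n",
              length(x$light_v), length(x$light_j),
              x$light_junction[1], x$light_junction[2]))
  invisible(x)
}
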