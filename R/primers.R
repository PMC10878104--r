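# Degenerate primers: the built-in panel covering the 16S hypervariable
# regions, and IUPAC-aware mismatch counting.

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_EXPAND)

# match_matrix[p, t]: does template letter t satisfy primer symbol p?
# A template N (or other ambiguity) is unknowable and matches nothing,
# except against primer N which is a true wildcard.
.iupac_match_matrix <- local({
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  for (p in IUPAC_LETTERS) {
    m[p, intersect(IUPAC_EXPAND[[p]], c("A", "C", "G", "T"))] <- TRUE
  }
  m["N", ] <- TRUE
  m
})

#' Count mismatches between a degenerate primer and a template window
#'
#' Positionwise comparison of equal-length strings: a position mismatches
#' when the template base is not in the IUPAC expansion of the primer symbol.
#' A template `N` matches nothing unless the primer symbol is itself `N`.
#'
#' @param primer,template Equal-length nucleotide strings; the primer may
#'   contain IUPAC ambiguity codes.
#' @return Integer mismatch count.
#' @export
#' @examples
#' iupac_match("GTGCCAGCMGCCGCGG", "GTGCCAGCAGCCGCGG") # M = A/C -> 0
iupac_match <- function(primer, template) {
  if (nchar(primer) != nchar(template)) {
    abort("primer and template windows must have equal length")
  }
  length(.iupac_mismatch_positions(
    strsplit(toupper(primer), "")[[1]], strsplit(toupper(template), "")[[1]]
  ))
}

# Positions (1-based within window) where template fails the primer symbol.
.iupac_mismatch_positions <- function(p_chars, t_chars) {
  pi <- match(p_chars, IUPAC_LETTERS)
  ti <- match(t_chars, IUPAC_LETTERS)
  if (anyNA(pi)) abort("primer contains a non-IUPAC character")
  bad_t <- is.na(ti)
  ok <- !bad_t
  idx <- which(ok)
  res <- logical(length(p_chars))
  res[idx] <- .iupac_match_matrix[cbind(pi[idx], ti[idx])]
  # unknown template characters only match a primer N
  res[bad_t] <- p_chars[bad_t] == "N" # nolint
  which(!res)
}

#' Built-in 16S rRNA primer panel
#'
#' The eight primer sets spanning the 16S rRNA gene: full-length (27F/1492R)
#' plus seven partial regions (V1-V2, V1-V3, V3-V4, V4, V4-V6, V5-V7,
#' V7-V9). The V1-V2 and V1-V3 sets use a two-primer forward mixture,
#' fourfold 27F-A and onefold 27F-B, reflecting the wet-lab mixture used to
#' broaden amplification across vaginal taxa; in-silico site detection takes
#' the union over forward primers and the 4:1 weights only steer the
#' synthetic read simulator.
#'
#' @return Tibble with columns `region`, `primer`, `direction`
#'   (`"fwd"`/`"rev"`), `sequence` (IUPAC), `weight`.
#' @export
builtin_panel <- function() {
  tribble(
    ~region, ~primer, ~direction, ~sequence, ~weight,
    "full-length", "27F",   "fwd", "AGRGTTYGATYMTGGCTCAG", 1,
    "full-length", "1492R", "rev", "RGYTACCTTGTTACGACTT", 1,
    "V1-V2", "27F-A", "fwd", "AGAGTTYGATYMTGGCTYAG", 4,
    "V1-V2", "27F-B", "fwd", "AGARTTTGATCYTGGTTCAG", 1,
    "V1-V2", "338R",  "rev", "TGCTGCCTCCCGTAGGAGT", 1,
    "V1-V3", "27F-A", "fwd", "AGAGTTYGATYMTGGCTYAG", 4,
    "V1-V3", "27F-B", "fwd", "AGARTTTGATCYTGGTTCAG", 1,
    "V1-V3", "533R",  "rev", "ATTACCGCGGCTGCTGG", 1,
    "V3-V4", "338F", "fwd", "ACTCCTACGGGAGGCAGCAG", 1,
    "V3-V4", "806R", "rev", "GGACTACHVGGGTWTCTAAT", 1,
    "V4", "515F", "fwd", "GTGCCAGCMGCCGCGG", 1,
    "V4", "806R", "rev", "GGACTACHVGGGTWTCTAAT", 1,
    "V4-V6", "533F",  "fwd", "GTGCCAGCMGCCGCGGTAA", 1,
    "V4-V6", "1100R", "rev", "GGGTTGCGCTCGTTG", 1,
    "V5-V7", "799F",  "fwd", "AACMGGATTAGATACCCKG", 1,
    "V5-V7", "1175R", "rev", "ACGTCRTCCCCDCCTTCCT", 1,
    "V7-V9", "1115F", "fwd", "YAACGAGCGCAACCC", 1,
    "V7-V9", "1492R", "rev", "CGGTTACCTTGTTACGACTT", 1
  )
}

#' Read a primer panel from TSV
#'
#' Columns: `region`, `primer`, `direction` (fwd/rev), `sequence`, `weight`.
#'
#' @param path TSV path.
#' @return Panel tibble as from [builtin_panel()].
#' @export
read_primer_panel <- function(path) {
  p <- readr::read_tsv(path, col_types = "ccccd", progress = FALSE)
  names(p) <- c("region", "primer", "direction", "sequence", "weight")
  p$sequence <- toupper(p$sequence)
  for (g in unique(p$region)) get_primer_set(p, g) # validates each set
  p
}

# Extract and validate one region's primer set from a panel tibble.
get_primer_set <- function(panel, region) {
  ps <- panel[panel$region == region, , drop = FALSE]
  if (nrow(ps) == 0) abort(paste0("region not in panel: ", region))
  if (sum(ps$direction == "rev") != 1) {
    abort(paste0("region ", region, " must have exactly one reverse primer"))
  }
  if (sum(ps$direction == "fwd") < 1) {
    abort(paste0("region ", region, " must have at least one forward primer"))
  }
  if (any(ps$weight <= 0)) abort("primer weights must be positive")
  if (any(!grepl("^[ACGTRYSWKMBDHVN]+$", ps$sequence))) {
    abort("primer sequences must be IUPAC nucleotide strings")
  }
  if (any(nchar(ps$sequence) < 10)) abort("primers must be >= 10 nt")
  ps
}

# Reverse complement preserving IUPAC degeneracy.
revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}
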