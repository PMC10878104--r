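# Lineage handling: the seven canonical ranks, the three reference-database
# taxonomy-string dialects, and species-name normalization.

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

QIIME_PREFIXES <- c(
  d = "domain", k = "domain", p = "phylum", c = "class",
  o = "order", f = "family", g = "genus", s = "species"
)

#' Canonical taxonomic ranks
#'
#' The fixed rank order used throughout the package: domain, phylum, class,
#' order, family, genus, species. Lineages may be truncated from the tail
#' (e.g. a genus-level record has no species) but never have interior gaps.
#'
#' @return Character vector of the seven rank names, shallowest first.
#' @export
tax_ranks <- function() TAX_RANKS

#' The four key vaginal Lactobacillus species
#'
#' *L. crispatus*, *L. gasseri*, *L. iners* and *L. jensenii* — the clinically
#' pivotal species any vaginal-microbiota pipeline must separate. Used to tag
#' the "key Lactobacillus" subset in accuracy summaries.
#'
#' @return Character vector of four binomial species names.
#' @export
key_lactobacillus <- function() {
  c(
    "Lactobacillus crispatus", "Lactobacillus gasseri",
    "Lactobacillus iners", "Lactobacillus jensenii"
  )
}

#' Normalize a species name to a binomial key
#'
#' Reference databases format species names inconsistently (underscores,
#' strain suffixes, stray whitespace). Accuracy scoring and the combination
#' rule need one shared key space, so species names are normalized to the
#' leading binomial: underscores become spaces, whitespace is collapsed and
#' anything after the second word (strain designations and the like) is
#' dropped. Single-token names (e.g. "BVAB1") are kept as-is. Matching is
#' case-insensitive downstream; the case of the input is preserved here.
#'
#' @param x Character vector of species names (NA allowed).
#' @return Character vector of normalized binomials, NA where input was NA or
#'   empty.
#' @export
#' @examples
#' normalize_species("Lactobacillus_crispatus ST1")
normalize_species <- function(x) {
  out <- str_squish(str_replace_all(x, "_", " "))
  out[!is.na(out) & out == ""] <- NA_character_
  keep2 <- function(s) {
    if (is.na(s)) return(NA_character_)
    w <- strsplit(s, " ", fixed = TRUE)[[1]]
    paste(w[seq_len(min(2L, length(w)))], collapse = " ")
  }
  vapply(out, keep2, character(1), USE.NAMES = FALSE)
}

supported_dialects <- function() {
  c("qiime-generic", "greengenes2", "silva", "rdp", "none")
}

# Parse one lineage string under a dialect. Returns a named character vector
# over TAX_RANKS (NA for missing) or NULL when the string does not parse.
parse_lineage_one <- function(x, dialect) {
  if (dialect == "none" || is.na(x) || !nzchar(str_squish(x))) {
    return(setNames(rep(NA_character_, 7L), TAX_RANKS))
  }
  toks <- str_squish(strsplit(x, ";", fixed = TRUE)[[1]])
  vals <- setNames(rep(NA_character_, 7L), TAX_RANKS)
  if (dialect %in% c("qiime-generic", "greengenes2")) {
    for (tk in toks) {
      if (!nzchar(tk)) next
      m <- regmatches(tk, regexec("^([A-Za-z])__(.*)$", tk))[[1]]
      if (length(m) == 0) return(NULL) # unknown layout: fail loudly per record
      rank <- QIIME_PREFIXES[m[2]]
      if (is.na(rank)) return(NULL)
      if (nzchar(m[3])) vals[rank] <- m[3]
    }
  } else if (dialect %in% c("silva", "rdp")) {
    if (dialect == "rdp" && length(toks) > 0 && toks[1] == "Root") toks <- toks[-1]
    toks <- toks[nzchar(toks)]
    if (length(toks) > 7L) return(NULL)
    vals[seq_along(toks)] <- toks
  } else {
    abort(paste0("unknown taxonomy dialect: ", dialect))
  }
  # no interior gaps: once a rank is missing, everything deeper must be too
  present <- !is.na(vals)
  if (any(present)) {
    deepest <- max(which(present))
    if (!all(present[seq_len(deepest)])) return(NULL)
  }
  vals
}

# Vectorized lineage parsing -> tibble with one row per input string,
# columns TAX_RANKS + species_norm + parsed (logical).
parse_lineages <- function(x, dialect) {
  dialect <- match.arg(dialect, supported_dialects())
  rows <- lapply(x, parse_lineage_one, dialect = dialect)
  failed <- vapply(rows, is.null, logical(1))
  rows[failed] <- list(setNames(rep(NA_character_, 7L), TAX_RANKS))
  out <- as_tibble(do.call(rbind, rows))
  out$species_norm <- normalize_species(out$species)
  out$parsed <- !failed
  out
}

# Format a lineage (one row of rank columns) back to a dialect string.
format_lineage <- function(ranks, dialect) {
  dialect <- match.arg(dialect, supported_dialects())
  if (dialect == "none") return("")
  vals <- unlist(ranks[TAX_RANKS], use.names = FALSE)
  if (dialect %in% c("qiime-generic", "greengenes2")) {
    pref <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
    keep <- !is.na(vals)
    paste0(pref[keep], str_replace_all(vals[keep], " ", "_"), collapse = "; ")
  } else {
    body <- paste(vals[!is.na(vals)], collapse = ";")
    if (dialect == "rdp") paste0("Root;", body) else body
  }
}

# Split a lineage string produced by lineage_string() back into ranks.
lineage_string <- function(ranks_row) {
  vals <- unlist(ranks_row[TAX_RANKS], use.names = FALSE)
  paste(vals[!is.na(vals)], collapse = "; ")
}
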