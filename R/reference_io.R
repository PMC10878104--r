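# Reference-database I/O: FASTA reading/writing with taxonomy dialects,
# record filters, and BLAST-style alignment-hit tables.

new_ref_db <- function(tbl, name = "custom", dialect = "none") {
  structure(
    tbl,
    class = c("ref_db", class(tibble())),
    db_name = name, dialect = dialect
  )
}

#' Read a reference FASTA with taxonomy
#'
#' Reads a (possibly gzipped, possibly line-wrapped) FASTA file into a
#' reference-database tibble with one row per record and the lineage split
#' into the seven canonical rank columns. Taxonomy comes either from the
#' FASTA header (everything after the first whitespace, interpreted under
#' `dialect`) or from a two-column sidecar TSV (`id<TAB>lineage`).
#'
#' Supported header dialects: `"qiime-generic"`/`"greengenes2"`
#' (`d__...; p__...; s__Genus_species`), `"silva"` (bare semicolon path),
#' `"rdp"` (semicolon path with a leading `Root;`), and `"none"` (no
#' taxonomy). A record whose taxonomy string fails to parse gets an empty
#' lineage and a warning; the count is in the `parse_report` attribute.
#'
#' @param path FASTA file path.
#' @param dialect Taxonomy-string dialect, see above.
#' @param taxonomy Optional path to a sidecar TSV (`id<TAB>lineage-string`);
#'   overrides header taxonomy.
#' @param name Database name stored on the result.
#' @return A `ref_db` tibble with columns `id`, `sequence`, `length`, the
#'   seven rank columns, `species_norm` and `lineage` (the raw taxonomy
#'   string). Attributes: `db_name`, `dialect`, `parse_report`.
#' @export
read_fasta <- function(path, dialect = "qiime-generic", taxonomy = NULL,
                       name = "custom") {
  dialect <- match.arg(dialect, supported_dialects())
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0) {
    empty <- tibble(
      id = character(), sequence = character(), length = integer(),
      !!!setNames(rep(list(character()), 7L), TAX_RANKS),
      species_norm = character(), lineage = character()
    )
    db <- new_ref_db(empty, name = name, dialect = dialect)
    attr(db, "parse_report") <- tibble(n_records = 0L, n_lineage_failed = 0L)
    return(db)
  }
  .validate_fasta_lines(lines)
  hdr_at <- which(str_starts(lines, ">"))
  hdr <- sub("^>", "", lines[hdr_at])
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), str_squish(sub("^\\S+\\s+", "", hdr)), "")
  seq_from <- hdr_at + 1L
  seq_to <- c(hdr_at[-1] - 1L, length(lines))
  sequence <- toupper(vapply(
    seq_along(hdr_at),
    function(i) paste0(lines[seq(seq_from[i], seq_to[i])], collapse = ""),
    character(1)
  ))
  if (anyDuplicated(id)) {
    abort(paste0(
      "duplicate record id(s) in ", path, ": ",
      paste(unique(id[duplicated(id)]), collapse = ", ")
    ))
  }
  bad <- grepl("[^ACGTRYSWKMBDHVNU]", sequence)
  if (any(bad)) {
    abort(paste0("non-nucleotide characters in record(s): ",
                 paste(id[bad], collapse = ", ")))
  }
  sequence <- gsub("U", "T", sequence, fixed = TRUE)

  lin_str <- desc
  if (!is.null(taxonomy)) {
    tx <- readr::read_tsv(taxonomy, col_names = c("id", "lineage"),
                          col_types = "cc", progress = FALSE)
    lin_str <- tx$lineage[match(id, tx$id)]
    lin_str[is.na(lin_str)] <- ""
  }
  ranks <- parse_lineages(lin_str, dialect)
  n_failed <- sum(!ranks$parsed & nzchar(lin_str) & dialect != "none")
  if (n_failed > 0) {
    warn(paste0(n_failed, " record(s) with unparseable taxonomy string; ",
                "lineage set empty"))
  }
  tbl <- tibble(
    id = id, sequence = sequence, length = nchar(sequence)
  ) |>
    bind_cols(ranks[TAX_RANKS], ranks["species_norm"]) |>
    mutate(lineage = lin_str)
  db <- new_ref_db(tbl, name = name, dialect = dialect)
  attr(db, "parse_report") <- tibble(
    n_records = length(id), n_lineage_failed = n_failed
  )
  db
}

# Structural FASTA validation with line numbers for error messages.
.validate_fasta_lines <- function(lines) {
  first <- which(nzchar(str_squish(lines)))[1]
  if (is.na(first) || !str_starts(lines[first], ">")) {
    abort(paste0("malformed FASTA: line ", if (is.na(first)) 1 else first,
                 " does not start a record"))
  }
  hdr_at <- which(str_starts(lines, ">"))
  empty_id <- hdr_at[!nzchar(str_squish(sub("^>", "", lines[hdr_at])))]
  if (length(empty_id) > 0) {
    abort(paste0("malformed FASTA: empty record id at line ", empty_id[1]))
  }
  nxt <- c(hdr_at[-1], length(lines) + 1L)
  no_seq <- hdr_at[nxt == hdr_at + 1L |
                     vapply(seq_along(hdr_at), function(i) {
                       rng <- seq(hdr_at[i] + 1L, length.out = nxt[i] - hdr_at[i] - 1L)
                       length(rng) == 0 || !any(nzchar(str_squish(lines[rng])))
                     }, logical(1))]
  if (length(no_seq) > 0) {
    abort(paste0("malformed FASTA: record with no sequence at line ", no_seq[1]))
  }
  invisible(TRUE)
}

#' Write a reference database to FASTA
#'
#' Headers are `>id lineage-string`; the raw `lineage` column is written
#' verbatim so that `read_fasta()` round-trips byte-identically.
#'
#' @param db A `ref_db` tibble (or any tibble with `id`, `sequence` and
#'   optionally `lineage` columns).
#' @param path Output path (".gz" suffix writes gzip).
#' @param width Line-wrap width, 0 for single-line records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 0L) {
  lin <- if ("lineage" %in% names(db)) db$lineage else rep("", nrow(db))
  hdr <- ifelse(nzchar(lin), paste(db$id, lin), db$id)
  seqs <- db$sequence
  if (width > 0) {
    seqs <- vapply(seqs, function(s) {
      paste(substring(s, seq(1, nchar(s), width),
                      pmin(seq(1, nchar(s), width) + width - 1L, nchar(s))),
            collapse = "\n")
    }, character(1), USE.NAMES = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", hdr, "\n", seqs), con)
  invisible(path)
}

#' Remove short and duplicated reference records
#'
#' Mirrors the record filtering applied to raw downloads: records shorter
#' than `min_bp` (default 200 bp) are dropped, then records with a duplicate
#' id, then records whose (upper-cased) sequence string duplicates an earlier
#' record. First occurrence in input order wins. Idempotent.
#'
#' @param db A `ref_db` tibble.
#' @param min_bp Minimum record length kept, inclusive.
#' @return A list with `db` (the filtered database, attributes preserved) and
#'   `report`, a tibble of removal counts per reason
#'   (`short_length`, `duplicate_id`, `duplicate_sequence`).
#' @export
deduplicate <- function(db, min_bp = 200L) {
  short <- db$length < min_bp
  keep1 <- db[!short, , drop = FALSE]
  dup_id <- duplicated(keep1$id)
  keep2 <- keep1[!dup_id, , drop = FALSE]
  dup_seq <- duplicated(keep2$sequence)
  out <- keep2[!dup_seq, , drop = FALSE]
  report <- tibble(
    reason = c("short_length", "duplicate_id", "duplicate_sequence"),
    n_removed = c(sum(short), sum(dup_id), sum(dup_seq))
  )
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       attributes(db)[c("class", "db_name", "dialect")])
  list(db = out, report = report)
}

#' Partition sequences by length
#'
#' Keeps sequences with `min_bp <= length <= max_bp` (both inclusive); the
#' partition is exhaustive and disjoint. The canonical use is the full-length
#' 16S CCS-read window of 1,000-1,800 bp.
#'
#' @param x A `ref_db`/tibble with a `sequence` column, or a character vector.
#' @param min_bp,max_bp Inclusive bounds; `max_bp = Inf` keeps everything long.
#' @return List with `kept` and `removed`, same type as the input.
#' @export
length_filter <- function(x, min_bp = 1000, max_bp = 1800) {
  stopifnot(min_bp <= max_bp)
  len <- if (is.character(x)) nchar(x) else nchar(x$sequence)
  keep <- len >= min_bp & len <= max_bp
  if (is.character(x)) {
    list(kept = x[keep], removed = x[!keep])
  } else {
    list(kept = x[keep, , drop = FALSE], removed = x[!keep, , drop = FALSE])
  }
}

#' Read BLAST outfmt-6 alignment hits
#'
#' Reads the 12-column tabular BLAST format (plus an optional 13th
#' subject-title column, from which a subject species name is extracted as
#' the leading binomial).
#'
#' @param path TSV path.
#' @return Tibble with `query_id`, `subject_id`, `identity` (0-100),
#'   `evalue`, `subject_title`, `species`.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- utils::read.table(path, sep = "\t", quote = "", fill = TRUE,
                           header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 12) abort("expected >= 12 tab-separated columns (outfmt 6)")
  names(raw)[1:12] <- cols
  title <- if (ncol(raw) >= 13) as.character(raw[[13]]) else rep("", nrow(raw))
  tibble(
    query_id = as.character(raw$qseqid),
    subject_id = as.character(raw$sseqid),
    identity = as.numeric(raw$pident),
    evalue = as.numeric(raw$evalue),
    subject_title = title,
    species = normalize_species(title)
  )
}

#' Default vague-species-name blacklist
#'
#' Tokens that mark a BLAST subject species name as non-standard or vague.
#' The exact list is a documented, configurable choice: names containing any
#' of these tokens (case-insensitive), bracketed genus markers (`[Genus]`)
#' or "Candidatus"-style markers are rejected by [filter_annotations()].
#'
#' @return Character vector of tokens.
#' @export
species_blacklist <- function() {
  c("sp.", "uncultured", "bacterium", "unidentified", "unclassified",
    "metagenome", "clone", "symbiont", "candidatus", "candidate")
}

.species_name_ok <- function(species, blacklist) {
  ok <- !is.na(species) & nzchar(species)
  low <- tolower(species)
  for (tok in blacklist) {
    tok_low <- tolower(tok)
    hit <- if (grepl("[.]$", tok_low)) {
      str_detect(low, stringr::fixed(tok_low))
    } else {
      str_detect(low, paste0("(^|\\s)", tok_low, "($|\\s)"))
    }
    ok <- ok & !hit
  }
  ok & !str_starts(species, stringr::fixed("["))
}

#' Filter alignment hits on e-value, identity and species-name quality
#'
#' A hit survives when its thresholds pass and its subject species name is a
#' usable binomial. With `logic = "or"` (default) a hit is discarded when it
#' fails *either* numeric threshold — the conventional reading; with
#' `logic = "and"` only hits failing both thresholds are discarded (the
#' literal reading of "e-value more than 1e-10 and identity less than 99%").
#' The name rule always applies.
#'
#' @param hits Tibble from [read_blast_hits()] (columns `identity`, `evalue`,
#'   `species`).
#' @param max_evalue Maximum e-value kept, default `1e-10`.
#' @param min_identity Minimum percent identity kept, default `99`.
#' @param blacklist Vague-name tokens, see [species_blacklist()].
#' @param logic `"or"` (discard on either threshold failing) or `"and"`.
#' @return The surviving hits, input order preserved.
#' @export
filter_annotations <- function(hits, max_evalue = 1e-10, min_identity = 99,
                               blacklist = species_blacklist(),
                               logic = c("or", "and")) {
  logic <- match.arg(logic)
  ev_ok <- hits$evalue <= max_evalue
  id_ok <- hits$identity >= min_identity
  thr_ok <- if (logic == "or") ev_ok & id_ok else ev_ok | id_ok
  hits[thr_ok & .species_name_ok(hits$species, blacklist), , drop = FALSE]
}

#' @export
print.ref_db <- function(x, ...) {
  cat("<ref_db> ", attr(x, "db_name"), " (dialect: ", attr(x, "dialect"),
      "), ", nrow(x), " records\n", sep = "")
  NextMethod()
}
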