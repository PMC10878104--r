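# In-silico PCR: degenerate-primer site detection on both strands, amplicon
# extraction with per-primer mismatch counts, and read truncation.

# Find binding sites of one degenerate primer on a plus-strand template.
# `clamp_end` says where the primer's 3' terminus sits within the window:
# "3p" for a forward primer (3' end = window end), "5p" for the
# reverse-complemented reverse primer (3' end = window start).
# Candidate search uses Biostrings::matchPattern (pattern ambiguities
# expanded, subject literal); every candidate is re-verified with the
# package's own IUPAC mismatch rule, which also applies the 3' clamp.
.find_sites <- function(template_dna, primer_seq, max_mismatch, clamp,
                        clamp_end = c("3p", "5p")) {
  clamp_end <- match.arg(clamp_end)
  L <- nchar(primer_seq)
  if (length(template_dna) < L) {
    return(tibble(start = integer(), end = integer(), mm = integer()))
  }
  hits <- matchPattern(DNAString(primer_seq), template_dna,
                       max.mismatch = max_mismatch, with.indels = FALSE,
                       fixed = "subject")
  if (length(hits) == 0) {
    return(tibble(start = integer(), end = integer(), mm = integer()))
  }
  p_chars <- strsplit(primer_seq, "")[[1]]
  starts <- start(hits)
  keep <- logical(length(starts))
  mm_tot <- integer(length(starts))
  tmpl_chars <- strsplit(as.character(template_dna), "")[[1]]
  clamp_pos <- if (clamp == 0) integer(0) else if (clamp_end == "3p") {
    seq(max(1L, L - clamp + 1L), L)
  } else {
    seq_len(min(clamp, L))
  }
  for (i in seq_along(starts)) {
    win <- tmpl_chars[seq(starts[i], length.out = L)]
    mm <- .iupac_mismatch_positions(p_chars, win)
    keep[i] <- length(mm) <= max_mismatch && !any(mm %in% clamp_pos)
    mm_tot[i] <- length(mm)
  }
  tibble(start = starts[keep], end = starts[keep] + L - 1L, mm = mm_tot[keep])
}

# Amplicons on one strand of a plus-strand template string.
.amplify_one_strand <- function(template, pset, max_mismatch, clamp,
                                min_len, max_len, all_products) {
  tmpl <- DNAString(template)
  fwd <- pset[pset$direction == "fwd", , drop = FALSE]
  rev <- pset[pset$direction == "rev", , drop = FALSE]
  rev_rc <- revcomp(rev$sequence[1])
  rev_sites <- .find_sites(tmpl, rev_rc, max_mismatch, clamp, "5p")
  if (nrow(rev_sites) == 0) return(NULL)
  out <- list()
  for (i in seq_len(nrow(fwd))) {
    fs <- .find_sites(tmpl, fwd$sequence[i], max_mismatch, clamp, "3p")
    if (nrow(fs) == 0) next
    for (j in seq_len(nrow(fs))) {
      down <- rev_sites[rev_sites$start > fs$end[j], , drop = FALSE]
      len <- down$end - fs$start[j] + 1L
      ok <- len >= min_len & len <= max_len
      down <- down[ok, , drop = FALSE]
      if (nrow(down) == 0) next
      down <- down[order(down$start), , drop = FALSE]
      if (!all_products) down <- down[1, , drop = FALSE]
      out[[length(out) + 1L]] <- tibble(
        fwd_primer = fwd$primer[i],
        start = fs$start[j], end = down$end,
        fwd_mismatch = fs$mm[j], rev_mismatch = down$mm
      )
    }
  }
  if (length(out) == 0) return(NULL)
  bind_rows(out)
}

#' Extract amplicons from one template with a primer set
#'
#' Scans both strands of a template for forward-primer sites and
#' (reverse-complemented) reverse-primer sites, allowing up to
#' `max_mismatch` mismatches per primer but none within the 3'-terminal
#' `clamp` bases (mismatches there abort polymerase extension). Each forward
#' site is paired with the nearest downstream reverse site (shortest
#' product); `all_products = TRUE` reports every pairing within the length
#' bounds. Products are primer-inclusive. For forward-primer mixtures the
#' union of matches is taken; identical spans found by several forward
#' primers are reported once, keeping the fewest-mismatch primer.
#'
#' Coordinates are 1-based inclusive on the plus strand of the template.
#' For `strand == "-"` the amplicon sequence is the reverse complement of
#' `substr(template, start, end)`.
#'
#' @param sequence Template nucleotide string.
#' @param id Source identifier recorded on each amplicon.
#' @param region Region label present in `panel`.
#' @param panel Primer panel tibble, default [builtin_panel()].
#' @param max_mismatch Maximum mismatches allowed per primer (default 1).
#' @param clamp Number of mismatch-free 3'-terminal bases required
#'   (default 4).
#' @param min_len,max_len Product-length bounds, primer-inclusive
#'   (defaults 50 and 5000 bp).
#' @param strip_primers Remove both primer-binding sites from the reported
#'   sequence (coordinates still span the full product).
#' @param all_products Report all forward/reverse pairings, not only the
#'   shortest product per forward site.
#' @return Tibble with one row per amplicon: `source_id`, `region`, `start`,
#'   `end`, `strand`, `fwd_primer`, `fwd_mismatch`, `rev_mismatch`,
#'   `length`, `sequence`; sorted by `start`. Zero rows when no site pairs.
#' @export
amplify <- function(sequence, id = "query", region, panel = builtin_panel(),
                    max_mismatch = 1L, clamp = 4L, min_len = 50L,
                    max_len = 5000L, strip_primers = FALSE,
                    all_products = FALSE) {
  stopifnot(max_mismatch >= 0, clamp >= 0)
  pset <- get_primer_set(panel, region)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  res <- list()
  plus <- .amplify_one_strand(sequence, pset, max_mismatch, clamp,
                              min_len, max_len, all_products)
  if (!is.null(plus)) res[["+"]] <- mutate(plus, strand = "+")
  rc <- revcomp(sequence)
  minus <- .amplify_one_strand(rc, pset, max_mismatch, clamp,
                               min_len, max_len, all_products)
  if (!is.null(minus)) {
    res[["-"]] <- minus |>
      mutate(
        start2 = L - .data$end + 1L, end2 = L - .data$start + 1L,
        strand = "-"
      ) |>
      select(-"start", -"end") |>
      rename(start = "start2", end = "end2")
  }
  if (length(res) == 0) {
    return(tibble(
      source_id = character(), region = character(), start = integer(),
      end = integer(), strand = character(), fwd_primer = character(),
      fwd_mismatch = integer(), rev_mismatch = integer(),
      length = integer(), sequence = character()
    ))
  }
  amp <- bind_rows(res) |>
    mutate(
      source_id = id, region = .env$region,
      length = .data$end - .data$start + 1L,
      sequence = substring(.env$sequence, .data$start, .data$end)
    )
  amp$sequence[amp$strand == "-"] <-
    vapply(amp$sequence[amp$strand == "-"], revcomp, character(1),
           USE.NAMES = FALSE)
  # union over forward primers: one row per physical product
  amp <- amp |>
    mutate(total_mm = .data$fwd_mismatch + .data$rev_mismatch) |>
    arrange(.data$start, .data$end, .data$strand, .data$total_mm,
            .data$fwd_primer) |>
    distinct(.data$start, .data$end, .data$strand, .keep_all = TRUE) |>
    select(-"total_mm")
  if (strip_primers) {
    fwd_len <- nchar(pset$sequence[match(amp$fwd_primer, pset$primer)])
    rev_len <- nchar(pset$sequence[pset$direction == "rev"][1])
    amp$sequence <- substring(amp$sequence, fwd_len + 1L,
                              nchar(amp$sequence) - rev_len)
  }
  amp |>
    select("source_id", "region", "start", "end", "strand", "fwd_primer",
           "fwd_mismatch", "rev_mismatch", "length", "sequence") |>
    arrange(.data$start, .data$end)
}

#' Amplify every record of a reference database
#'
#' Applies [amplify()] to each record and reports, per species, how many
#' records amplified — the per-region "uneven amplification" pattern that
#' motivates region benchmarking (species whose deposited sequences lack a
#' primer site simply drop out of that region).
#'
#' @param db A `ref_db` tibble.
#' @param region Region label in `panel`.
#' @param panel Primer panel tibble.
#' @param ... Passed to [amplify()].
#' @return List with `amplicons` (bound amplicon tibble) and `report`
#'   (per-species tibble: `species`, `region`, `n_records`, `n_amplified`).
#' @export
amplify_database <- function(db, region, panel = builtin_panel(), ...) {
  amps <- map2(db$sequence, db$id,
               function(s, i) amplify(s, i, region = region, panel = panel, ...))
  amplicons <- bind_rows(amps)
  got <- vapply(amps, nrow, integer(1)) > 0
  species <- if ("species_norm" %in% names(db)) db$species_norm else
    rep(NA_character_, nrow(db))
  report <- tibble(species = species, amplified = got) |>
    group_by(.data$species) |>
    summarise(n_records = n(), n_amplified = sum(.data$amplified),
              .groups = "drop") |>
    mutate(region = .env$region, .after = "species")
  list(amplicons = amplicons, report = report)
}

#' Truncate reads to a fixed length
#'
#' Keeps the first `length_bp` bases of each sequence (shorter sequences are
#' unchanged). This mimics using only the forward reads of a short-read run,
#' e.g. 223 bp Novaseq forward reads over V1-V3 amplicons.
#'
#' @param x Character vector of sequences, or a tibble with a `sequence`
#'   column.
#' @param length_bp Positive truncation length.
#' @return Same type as input, order preserved.
#' @export
truncate_reads <- function(x, length_bp = 223L) {
  if (length_bp < 1) abort("length_bp must be positive")
  if (is.character(x)) return(substr(x, 1L, length_bp))
  x$sequence <- substr(x$sequence, 1L, length_bp)
  x
}

#' Write amplicons to FASTA
#'
#' Headers are `sourceID|region|start-end|strand|mmF,mmR` with 1-based
#' inclusive plus-strand coordinates.
#'
#' @param amplicons Tibble from [amplify()]/[amplify_database()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicons <- function(amplicons, path) {
  hdr <- sprintf("%s|%s|%d-%d|%s|%d,%d", amplicons$source_id,
                 amplicons$region, amplicons$start, amplicons$end,
                 amplicons$strand, amplicons$fwd_mismatch,
                 amplicons$rev_mismatch)
  write_fasta(tibble(id = hdr, sequence = amplicons$sequence), path)
}
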