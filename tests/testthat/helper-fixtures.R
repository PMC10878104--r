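# Shared fixture builders. Everything is generated in code; no data files.

# Write a FASTA (one line per sequence) and return its path.
write_tmp_fasta <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = env)
  writeLines(lines, path)
  path
}

# Small reference database built through the public FASTA reader (silva
# dialect sidesteps prefix bookkeeping). `species` may contain NA for
# genus-level records.
make_test_db <- function(sequences, species, name = "testdb",
                         ids = NULL, env = parent.frame()) {
  ids <- ids %||% sprintf("rec%02d", seq_along(sequences))
  genus <- vapply(strsplit(ifelse(is.na(species), "Unknown gen", species),
                           " "), `[`, character(1), 1L)
  lineage <- ifelse(
    is.na(species),
    paste("Bacteria", "Phylum1", "Class1", paste0(genus, "ales"),
          paste0(genus, "aceae"), genus, sep = ";"),
    paste("Bacteria", "Phylum1", "Class1", paste0(genus, "ales"),
          paste0(genus, "aceae"), genus, species, sep = ";")
  )
  path <- write_tmp_fasta(paste0(">", ids, " ", lineage, "\n", sequences),
                          env = env)
  read_fasta(path, dialect = "silva", name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, n_sub) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), n_sub)
  ch[pos] <- vapply(ch[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(ch, collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Expand an IUPAC string into all concrete ACGT strings.
iupac_expand_all <- function(x) {
  map <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  parts <- map[strsplit(x, "")[[1]]]
  apply(do.call(expand.grid, c(rev(parts), stringsAsFactors = FALSE)),
        1L, function(r) paste(rev(r), collapse = ""))
}

# Brute-force in-silico PCR oracle at zero mismatches: enumerate every
# concrete expansion of both primers, locate all exact occurrences by
# direct substring comparison, pair each forward site with the nearest
# downstream reverse site within the length bounds, on both strands.
oracle_amplify <- function(template, fwd, rev, min_len = 50, max_len = 5000) {
  fwd_set <- iupac_expand_all(fwd)
  rev_set <- iupac_expand_all(revcomp_chr(rev))
  Lf <- nchar(fwd); Lr <- nchar(rev)
  find_all <- function(tmpl, pats, L) {
    n <- nchar(tmpl)
    if (n < L) return(integer(0))
    wins <- substring(tmpl, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L)
    which(wins %in% pats)
  }
  scan <- function(tmpl) {
    fs <- find_all(tmpl, fwd_set, Lf)
    rs <- find_all(tmpl, rev_set, Lr)
    out <- list()
    for (f in fs) {
      ends <- rs + Lr - 1L
      okl <- rs > f + Lf - 1L & (ends - f + 1L) >= min_len &
        (ends - f + 1L) <= max_len
      if (!any(okl)) next
      r <- min(rs[okl])
      out[[length(out) + 1L]] <- c(start = f, end = r + Lr - 1L)
    }
    if (length(out) == 0) return(NULL)
    as.data.frame(do.call(rbind, out))
  }
  n <- nchar(template)
  plus <- scan(template)
  res <- list()
  if (!is.null(plus)) {
    plus$strand <- "+"
    plus$sequence <- substring(template, plus$start, plus$end)
    res$plus <- plus
  }
  rc <- revcomp_chr(template)
  minus <- scan(rc)
  if (!is.null(minus)) {
    seqs <- substring(rc, minus$start, minus$end)
    minus2 <- data.frame(
      start = n - minus$end + 1L, end = n - minus$start + 1L,
      strand = "-", sequence = seqs
    )
    res$minus <- minus2
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), sequence = character()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$start, out$end), , drop = FALSE]
}

# quiet wrapper: classification with bootstrap off and no truncation
classify_point <- function(model, queries, seed = 1) {
  classify_nb(model, queries, threshold = 0, n_bootstrap = 1L, seed = seed)
}
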