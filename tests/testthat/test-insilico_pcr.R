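# Primer panel, IUPAC matching and amplicon extraction.

test_that("built-in panel carries the eight published primer sets", {
  panel <- builtin_panel()
  expect_equal(length(unique(panel$region)), 8)
  v4 <- panel[panel$region == "V4", ]
  expect_equal(v4$sequence[v4$direction == "fwd"], "GTGCCAGCMGCCGCGG")
  expect_equal(v4$sequence[v4$direction == "rev"], "GGACTACHVGGGTWTCTAAT")
  v12 <- panel[panel$region == "V1-V2" & panel$direction == "fwd", ]
  expect_equal(nrow(v12), 2) # the 27F mixture
  expect_equal(sort(v12$weight), c(1, 4)) # fourfold 27F-A, onefold 27F-B
  expect_true(all(grepl("^[ACGTRYSWKMBDHVN]+$", panel$sequence)))
  expect_true(all(nchar(panel$sequence) >= 10))
  # the two 1492R variants are distinct oligos
  r1492 <- unique(panel$sequence[panel$primer == "1492R"])
  expect_length(r1492, 2)
})

test_that("iupac_match counts mismatches under IUPAC expansion", {
  expect_equal(iupac_match("GTGCCAGCMGCCGCGG", "GTGCCAGCAGCCGCGG"), 0)
  expect_equal(iupac_match("GTGCCAGCMGCCGCGG", "GTGCCAGCTGCCGCGG"), 1)
  expect_equal(iupac_match("ACGTACGT", "ACGTACGT"), 0)
  # template N matches nothing unless the primer symbol is N
  expect_equal(iupac_match("ACGT", "ACGN"), 1)
  expect_equal(iupac_match("ACGN", "ACGN"), 0)
  expect_error(iupac_match("ACGT", "ACGTA"), "length")
})

test_that("amplify finds the planted V4 product with exact coordinates", {
  fwd_site <- "GTGCCAGCAGCCGCGG" # 515F with M -> A
  rev_site <- "ATTAGATACCCGGGTAGTCC" # revcomp(806R) concretized
  withr::with_seed(5, tmpl <- paste0(strrep("A", 30), fwd_site,
                                     random_dna(100), rev_site,
                                     strrep("A", 30)))
  amp <- amplify(tmpl, "t1", "V4", max_mismatch = 0)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 136) # 16 + 100 + 20
  expect_equal(amp$start, 31)
  expect_equal(amp$end, 166)
  expect_equal(amp$strand, "+")
  expect_equal(amp$sequence, substr(tmpl, 31, 166))
  expect_equal(amp$fwd_mismatch + amp$rev_mismatch, 0)

  # one substitution in the forward site: gone at mm 0, found at mm 1
  tmpl_mut <- tmpl
  substr(tmpl_mut, 33, 33) <- "A" # position 3 of the site (G -> A)
  expect_equal(nrow(amplify(tmpl_mut, "t1", "V4", max_mismatch = 0)), 0)
  amp1 <- amplify(tmpl_mut, "t1", "V4", max_mismatch = 1)
  expect_equal(nrow(amp1), 1)
  expect_equal(amp1$fwd_mismatch, 1)

  # no reverse site anywhere -> nothing
  no_rev <- paste0(strrep("A", 30), fwd_site, strrep("C", 100))
  expect_equal(nrow(amplify(no_rev, "t1", "V4")), 0)
})

test_that("3' clamp vetoes terminal mismatches", {
  fwd_site <- "GTGCCAGCAGCCGCGG"
  rev_site <- "ATTAGATACCCGGGTAGTCC"
  withr::with_seed(6, insert <- random_dna(100))
  tmpl <- paste0(strrep("A", 20), fwd_site, insert, rev_site)
  # mismatch at the forward primer's last base (3' terminus)
  tmpl_3p <- tmpl
  substr(tmpl_3p, 36, 36) <- "A" # site position 16
  expect_equal(nrow(amplify(tmpl_3p, "t", "V4", max_mismatch = 1,
                            clamp = 4)), 0)
  expect_equal(nrow(amplify(tmpl_3p, "t", "V4", max_mismatch = 1,
                            clamp = 0)), 1)
})

test_that("amplify matches the brute-force expansion oracle at mm 0", {
  panel <- builtin_panel()
  fwd <- panel$sequence[panel$region == "V4" & panel$direction == "fwd"]
  rev <- panel$sequence[panel$region == "V4" & panel$direction == "rev"]
  withr::local_seed(11)
  for (i in 1:25) {
    tmpl <- random_dna(2000)
    # plant 0-2 forward and 0-2 reverse concrete sites
    for (s in sample(iupac_expand_all(fwd), sample(0:2, 1))) {
      at <- sample(1900, 1)
      substr(tmpl, at, at + nchar(s) - 1L) <- s
    }
    for (s in sample(iupac_expand_all(revcomp_chr(rev)), sample(0:2, 1))) {
      at <- sample(1900, 1)
      substr(tmpl, at, at + nchar(s) - 1L) <- s
    }
    got <- amplify(tmpl, "t", "V4", max_mismatch = 0)
    want <- oracle_amplify(tmpl, fwd, rev)
    expect_equal(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start, info = paste("case", i))
      expect_equal(got$end, want$end, info = paste("case", i))
      expect_equal(got$strand, want$strand, info = paste("case", i))
      expect_equal(got$sequence, want$sequence, info = paste("case", i))
    }
  }
})

test_that("amplicon sets grow monotonically with the mismatch allowance", {
  withr::local_seed(12)
  fwd_site <- "GTGCCAGCAGCCGCGG"
  rev_site <- "ATTAGATACCCGGGTAGTCC"
  for (i in 1:10) {
    tmpl <- paste0(random_dna(40), mutate_dna(fwd_site, sample(0:2, 1)),
                   random_dna(150), mutate_dna(rev_site, sample(0:2, 1)),
                   random_dna(40))
    keys <- lapply(0:2, function(m) {
      a <- amplify(tmpl, "t", "V4", max_mismatch = m, clamp = 0)
      paste(a$start, a$end, a$strand)
    })
    expect_true(all(keys[[1]] %in% keys[[2]]))
    expect_true(all(keys[[2]] %in% keys[[3]]))
  }
})

test_that("amplifying the reverse complement yields the same products", {
  withr::local_seed(13)
  tmpl <- paste0(random_dna(40), "GTGCCAGCAGCCGCGG", random_dna(150),
                 "ATTAGATACCCGGGTAGTCC", random_dna(40))
  a1 <- amplify(tmpl, "t", "V4", max_mismatch = 1)
  a2 <- amplify(revcomp_chr(tmpl), "t", "V4", max_mismatch = 1)
  expect_equal(sort(a1$sequence), sort(a2$sequence))
  expect_equal(a1$strand, "+")
  expect_equal(a2$strand, "-")
})

test_that("amplify_database reports species that fail to amplify", {
  withr::local_seed(14)
  with_site <- paste0(random_dna(30), "GTGCCAGCAGCCGCGG", random_dna(120),
                      "ATTAGATACCCGGGTAGTCC", random_dna(30))
  without <- random_dna(220)
  db <- make_test_db(c(with_site, with_site, without),
                     c("Aus bus", "Aus bus", "Cus dus"))
  res <- amplify_database(db, "V4")
  expect_equal(nrow(res$amplicons), 2)
  rep <- res$report
  expect_equal(rep$n_amplified[rep$species == "Cus dus"], 0)
  expect_equal(rep$n_amplified[rep$species == "Aus bus"], 2)
  expect_equal(rep$n_records[rep$species == "Aus bus"], 2)
  # empty database -> empty outputs
  empty <- db[0, ]
  res0 <- amplify_database(empty, "V4")
  expect_equal(nrow(res0$amplicons), 0)
  expect_equal(nrow(res0$report), 0)
})

test_that("truncate_reads keeps leading bases and is idempotent", {
  withr::local_seed(15)
  long <- random_dna(450)
  expect_equal(truncate_reads(long, 223), substr(long, 1, 223))
  short <- random_dna(150)
  expect_equal(truncate_reads(short, 223), short)
  tw <- truncate_reads(truncate_reads(c(long, short), 223), 223)
  expect_equal(tw, truncate_reads(c(long, short), 223))
  expect_error(truncate_reads(long, 0), "positive")
  tb <- truncate_reads(tibble::tibble(sequence = long), 10)
  expect_equal(nchar(tb$sequence), 10)
})

test_that("amplicon FASTA headers carry coordinates and mismatches", {
  withr::local_seed(16)
  tmpl <- paste0(random_dna(30), "GTGCCAGCAGCCGCGG", random_dna(100),
                 "ATTAGATACCCGGGTAGTCC", random_dna(30))
  amp <- amplify(tmpl, "recX", "V4", max_mismatch = 0)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_amplicons(amp, out)
  hdr <- readLines(out)[1]
  expect_match(hdr, "^>recX\\|V4\\|31-166\\|\\+\\|0,0$")
})
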