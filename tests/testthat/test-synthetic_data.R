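# The synthetic world generator and mock-community read simulator.

test_that("identical seeds regenerate the world byte-identically", {
  w1 <- make_reference_world(n_species = 10, n_sister_pairs = 1, seed = 51)
  w2 <- make_reference_world(n_species = 10, n_sister_pairs = 1, seed = 51)
  expect_identical(tibble::as_tibble(w1$truth), tibble::as_tibble(w2$truth))
  expect_identical(w1$manifest, w2$manifest)
  for (nm in names(w1$databases)) {
    expect_identical(tibble::as_tibble(w1$databases[[nm]]),
                     tibble::as_tibble(w2$databases[[nm]]))
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(w1, d1); write_world(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  w3 <- make_reference_world(n_species = 10, n_sister_pairs = 1, seed = 52)
  expect_false(identical(w1$truth$sequence, w3$truth$sequence))
  expect_error(make_reference_world(n_species = 4, n_sister_pairs = 3),
               "exceeds")
})

test_that("the three databases carry their engineered defects", {
  w <- make_reference_world(seed = 53)
  man <- w$manifest
  expect_true(any(!is.na(man$gg2_mislabeled_as)))
  expect_true(any(man$silva_omitted))
  expect_true(any(man$rdp_truncated))
  # disjoint subsets
  tags <- cbind(!is.na(man$gg2_mislabeled_as), man$silva_omitted,
                man$rdp_truncated)
  expect_true(all(rowSums(tags) <= 1))
  omitted <- man$species[man$silva_omitted]
  expect_false(any(w$databases$silva$species %in% omitted))
  truncated <- man$species[man$rdp_truncated]
  trunc_rows <- w$databases$rdp[
    w$databases$rdp$genus %in% sub(" .*", "", truncated), ]
  expect_true(all(is.na(trunc_rows$species) |
                    !trunc_rows$species %in% truncated))
  mislab <- man$species[!is.na(man$gg2_mislabeled_as)][1]
  gg2_rows <- w$databases$greengenes2[
    grepl(sub(" .*", "", mislab), w$databases$greengenes2$id), ]
  # records of a mislabeled species carry some other species' lineage
  expect_false(any(gg2_rows$species == mislab))
  # each database parses under its own dialect via FASTA round-trip
  d <- withr::local_tempdir()
  write_world(w, d)
  for (nm in names(w$databases)) {
    db <- read_fasta(file.path(d, paste0(nm, ".fasta")), dialect = nm,
                     name = nm)
    expect_equal(nrow(db), nrow(w$databases[[nm]]))
    expect_equal(db$species_norm, w$databases[[nm]]$species_norm)
  }
})

test_that("sister pairs are inseparable in regions excluding V1", {
  # noise-free records so the pair's V4 amplicons are strictly identical
  w <- make_reference_world(n_species = 8, n_sister_pairs = 1,
                            record_noise = 0, seed = 54)
  pair <- w$manifest$species_norm[!is.na(w$manifest$sister_group)]
  recs <- w$truth[w$truth$species_norm %in% pair, ]
  # identical V4 spans within the pair (first records are noise-free)
  a1 <- amplify(recs$sequence[1], "a", "V4")
  a2 <- amplify(recs$sequence[4], "b", "V4")
  expect_equal(a1$sequence, a2$sequence)
  # and a classifier cannot do better than one side of the pair
  amp <- amplify_database(recs, "V4")$amplicons
  m <- train_nb(w$truth)
  res <- classify_point(
    m, tibble::tibble(query_id = amp$source_id, sequence = amp$sequence)
  )
  truth <- tibble::tibble(
    query_id = recs$id,
    species = recs$species_norm
  )
  acc <- score_accuracy(dplyr::mutate(res, region = "V4"), truth)
  expect_lte(mean(acc$accuracy), 0.5 + 0.1)
  # the V1-containing region separates them
  ampv13 <- amplify_database(recs, "V1-V3")$amplicons
  resv13 <- classify_point(
    m, tibble::tibble(query_id = ampv13$source_id,
                      sequence = ampv13$sequence)
  )
  accv13 <- score_accuracy(dplyr::mutate(resv13, region = "V1-V3"), truth)
  expect_equal(mean(accv13$accuracy), 1)
})

test_that("reads from a silva-omitted species cannot hit their species", {
  w <- make_reference_world(seed = 55)
  omitted <- w$manifest$species[w$manifest$silva_omitted][1]
  rec <- w$truth[w$truth$species == omitted, ][1, ]
  amp <- amplify(rec$sequence, rec$id, "V1-V3")
  res <- classify_tophit(w$databases$silva, c(q = amp$sequence[1]))
  expect_true(is.na(res$species) ||
                tolower(res$species) != tolower(normalize_species(omitted)))
})

test_that("simulated reads recover the mock composition without errors", {
  w <- make_reference_world(seed = 56)
  mock <- tibble::tibble(
    species = c("Gardnerella vaginalis", "Atopobium vaginae"),
    abundance = c(0.8, 0.2)
  )
  rd <- simulate_reads(w, mock, region = "V1-V3", n_reads = 1000,
                       error_rate = 0, seed = 57)
  expect_equal(nrow(rd$reads), 1000)
  obs <- mean(rd$truth$species == "Gardnerella vaginalis")
  se <- sqrt(0.8 * 0.2 / 1000)
  expect_lt(abs(obs - 0.8), 3 * se)
  # read sequences are exact amplicon copies at error rate zero
  amp <- amplify_database(w$truth[w$truth$species_norm ==
                                    "Gardnerella vaginalis", ],
                          "V1-V3")$amplicons
  expect_true(all(rd$reads$sequence[rd$truth$species ==
                                      "Gardnerella vaginalis"] %in%
                    amp$sequence))
})

test_that("fixed seeds give identical FASTQ bytes", {
  w <- make_reference_world(n_species = 6, n_sister_pairs = 0, seed = 58)
  mock <- tibble::tibble(species = w$manifest$species[1:2],
                         abundance = c(0.5, 0.5))
  r1 <- simulate_reads(w, mock, region = "V4", n_reads = 50, seed = 59)
  r2 <- simulate_reads(w, mock, region = "V4", n_reads = 50, seed = 59)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1$reads, f1); write_fastq(r2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nchar(readLines(f1)[2]), nchar(readLines(f1)[4]))
})

test_that("primer dropout zeroes one region but not full-length", {
  drop <- tibble::tibble(species = "Gardnerella vaginalis",
                         region = "V3-V4")
  w <- make_reference_world(seed = 60, primer_dropout = drop)
  mock <- tibble::tibble(
    species = c("Gardnerella vaginalis", "Lactobacillus crispatus",
                "Atopobium vaginae"),
    abundance = c(0.3, 0.5, 0.2)
  )
  expect_warning(
    rd34 <- simulate_reads(w, mock, region = "V3-V4", n_reads = 1000,
                           error_rate = 0, seed = 61),
    "unamplifiable"
  )
  expect_equal(sum(rd34$truth$species == "Gardnerella vaginalis"), 0)
  rdfl <- simulate_reads(w, mock, region = "full-length", n_reads = 1000,
                         error_rate = 0, seed = 62)
  share <- mean(rdfl$truth$species == "Gardnerella vaginalis")
  expect_lt(abs(share - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  expect_match(w$manifest$dropout_sites[w$manifest$species ==
                                          "Gardnerella vaginalis"],
               "site338")
})

test_that("read counts follow the 4:1 forward-primer mixture weights", {
  w <- make_reference_world(n_species = 6, n_sister_pairs = 0, seed = 63)
  mock <- tibble::tibble(species = w$manifest$species[5], abundance = 1)
  rd <- simulate_reads(w, mock, region = "V1-V2", n_reads = 2000, seed = 64)
  frac_a <- mean(rd$truth$fwd_primer == "27F-A")
  expect_lt(abs(frac_a - 0.8), 3 * sqrt(0.8 * 0.2 / 2000))
})
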