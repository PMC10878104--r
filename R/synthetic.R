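# Synthetic 16S worlds: block-structured species sequences carrying the
# built-in panel's primer sites at realistic spacings, three derived
# reference databases with engineered complementary defects, and a mock
# community read simulator. Everything is deterministic given one seed.

# Concrete primer-site blocks shared by all species. Sites are shared
# between overlapping primer sets exactly as on the real gene: SITE338 is
# revcomp(338R) plus the extra 3' base of 338F; SITE515 carries 515F, 533F
# and revcomp(533R); SITE799 carries 799F and revcomp(806R); SITE1100 is
# both revcomp(1100R) and 1115F; SITE1492 carries the reverse sites of both
# 1492R variants.
SYN_SITES <- list(
  site27_A = "AGAGTTTGATCATGGCTCAG", # 27F + 27F-A exact; 27F-B at 2 mm
  site27_B = "AGAGTTTGATCCTGGTTCAG", # 27F-B exact; 27F/27F-A at 1 mm
  site338 = "ACTCCTACGGGAGGCAGCAG",
  site515 = "GTGCCAGCAGCCGCGGTAAT",
  site799 = "AACAGGATTAGATACCCGGGTAGTCC",
  site1100 = "CAACGAGCGCAACCC",
  site1175 = "AGGAAGGAGGGGACGACGT",
  site1492 = "AAGTCGTAACAAGGTAACCG"
)

# (block name, length) layout; variable blocks are per-species, conserved
# spacers and sites are shared. Total 1485 bp with the V1-V3 span ~515 bp
# and the V4 span ~296 bp, echoing real amplicon sizes.
SYN_LAYOUT <- tribble(
  ~block, ~type, ~len,
  "site27", "site", 20L,
  "v1", "variable", 150L,
  "cons1", "conserved", 150L,
  "site338", "site", 20L,
  "v2", "variable", 155L,
  "site515", "site", 20L,
  "v3", "variable", 130L,
  "cons2", "conserved", 120L,
  "site799", "site", 26L,
  "v4", "variable", 150L,
  "cons3", "conserved", 140L,
  "site1100", "site", 15L,
  "v5", "variable", 60L,
  "site1175", "site", 19L,
  "v6", "variable", 290L,
  "site1492", "site", 20L
)

# region -> the physical site scrambled by a primer dropout (regions that
# share the site drop together; the manifest records the site).
SYN_DROPOUT_SITE <- c(
  "full-length" = "site27", "V1-V2" = "site338", "V1-V3" = "site515",
  "V3-V4" = "site338", "V4" = "site515", "V4-V6" = "site515",
  "V5-V7" = "site799", "V7-V9" = "site1492"
)

SYN_PHYLUM <- c(
  Lactobacillus = "Firmicutes", Enterococcus = "Firmicutes",
  Streptococcus = "Firmicutes", Gemella = "Firmicutes",
  Anaerococcus = "Firmicutes", Aerococcus = "Firmicutes",
  Peptoniphilus = "Firmicutes", Murdochiella = "Firmicutes",
  Megasphaera = "Firmicutes",
  Gardnerella = "Actinobacteria", Atopobium = "Actinobacteria",
  Bifidobacterium = "Actinobacteria", Mobiluncus = "Actinobacteria",
  Prevotella = "Bacteroidetes",
  Sneathia = "Fusobacteria", Fusobacterium = "Fusobacteria",
  Mycoplasma = "Tenericutes", Ureaplasma = "Tenericutes",
  Mycoplasmoides = "Tenericutes",
  Chlamydia = "Chlamydiae", Neisseria = "Proteobacteria"
)
SYN_CLASS <- c(
  Firmicutes = "Bacilli", Actinobacteria = "Actinomycetia",
  Bacteroidetes = "Bacteroidia", Fusobacteria = "Fusobacteriia",
  Tenericutes = "Mollicutes", Chlamydiae = "Chlamydiia",
  Proteobacteria = "Betaproteobacteria"
)

# Vaginal species name pool; the key Lactobacillus quartet comes first so
# default worlds always contain it.
syn_species_pool <- function() {
  c(
    key_lactobacillus(),
    "Gardnerella vaginalis", "Atopobium vaginae", "Prevotella bivia",
    "Sneathia amnii", "Mobiluncus curtisii", "Megasphaera lornae",
    "Megasphaera hutchinsoni", "Megasphaera vaginalis",
    "Mycoplasma hominis", "Mycoplasma girerdii", "Ureaplasma parvum",
    "Ureaplasma urealyticum", "Chlamydia trachomatis",
    "Neisseria gonorrhoeae", "Mycoplasmoides genitalium",
    "Bifidobacterium breve", "Enterococcus faecium",
    "Fusobacterium nucleatum", "Streptococcus mitis",
    "Gemella asaccharolytica", "Murdochiella asaccharolytica",
    "Anaerococcus obesiensis", "Aerococcus christensenii",
    "Peptoniphilus harei"
  )
}

.syn_lineage <- function(species) {
  genus <- vapply(strsplit(species, " "), `[`, character(1), 1L)
  phylum <- unname(SYN_PHYLUM[genus])
  phylum[is.na(phylum)] <- "Firmicutes"
  tibble(
    domain = "Bacteria", phylum = phylum,
    class = unname(SYN_CLASS[phylum]),
    order = paste0(genus, "ales"), family = paste0(genus, "aceae"),
    genus = genus, species = species,
    species_norm = normalize_species(species)
  )
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# iid substitutions at `rate`; each hit base becomes one of the other three
.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) > 0) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic reference world
#'
#' Builds `n_species` block-structured ~1.5 kb 16S-like sequences: conserved
#' blocks carrying every built-in primer-binding site at realistic spacings,
#' alternating with variable blocks mutated off a shared backbone at
#' `divergence` substitutions per base. Sister pairs differ *only* in the V1
#' variable block, so regions that do not cover V1 cannot separate them —
#' the key-Lactobacillus phenomenon. Three reference databases are derived
#' with disjoint engineered defects so that no single database is best for
#' all species: `greengenes2` mislabels a species subset (cyclic label swap
#' within the subset), `silva` omits a subset, and `rdp` truncates a
#' subset's lineages at genus.
#'
#' Each species gets `records_per_species` records: the exact species
#' sequence plus copies with `record_noise` iid substitutions (noise can
#' occasionally hit a primer site, reproducing the uneven amplification of
#' real deposits). The 27F forward site is the A-type variant with
#' probability 0.8, otherwise B-type, mirroring the 4:1 27F primer mixture.
#'
#' @param n_species Number of species (>= 2), default 20.
#' @param n_sister_pairs Number of sister pairs (2 per pair drawn from the
#'   head of the species list, i.e. the key Lactobacilli), default 2.
#' @param records_per_species Records per species in the truth database,
#'   default 3.
#' @param divergence Per-base substitution rate of variable blocks off the
#'   backbone, default 0.10.
#' @param record_noise Per-base substitution rate of non-first records,
#'   default 0.005.
#' @param defect_fraction Fraction of species in each database's defect
#'   subset (disjoint across the three), default 0.15.
#' @param primer_dropout Optional tibble (`species`, `region`): scramble the
#'   physical primer site that region uses for those species. Regions
#'   sharing the site drop together; the manifest records the scrambled
#'   site.
#' @param seed Integer seed; identical seeds give byte-identical worlds.
#' @return A `synthetic_world`: list with `truth` (ref_db), `databases`
#'   (list of three ref_dbs), `manifest` (per-species tibble) and `params`.
#' @export
make_reference_world <- function(n_species = 20L, n_sister_pairs = 2L,
                                 records_per_species = 3L, divergence = 0.10,
                                 record_noise = 0.005, defect_fraction = 0.15,
                                 primer_dropout = NULL, seed = NULL) {
  if (n_species < 2) abort("n_species must be >= 2")
  if (n_sister_pairs * 2 > n_species) {
    abort("n_sister_pairs x 2 exceeds n_species")
  }
  build <- function() {
    pool <- syn_species_pool()
    species <- if (n_species <= length(pool)) pool[seq_len(n_species)] else {
      c(pool, sprintf("Synthetica specium%d", seq_len(n_species - length(pool))))
    }
    lineages <- .syn_lineage(species)
    var_blocks <- SYN_LAYOUT$block[SYN_LAYOUT$type == "variable"]
    backbone <- list()
    for (i in seq_len(nrow(SYN_LAYOUT))) {
      b <- SYN_LAYOUT$block[i]
      backbone[[b]] <- switch(
        SYN_LAYOUT$type[i],
        site = if (b == "site27") NA_character_ else SYN_SITES[[b]],
        conserved = .rand_seq(SYN_LAYOUT$len[i]),
        variable = .rand_seq(SYN_LAYOUT$len[i])
      )
    }
    # per-species block sets
    sister_group <- rep(NA_integer_, n_species)
    if (n_sister_pairs > 0) {
      sister_group[seq_len(2 * n_sister_pairs)] <-
        rep(seq_len(n_sister_pairs), each = 2)
    }
    site27_type <- sample(c("A", "B"), n_species, replace = TRUE,
                          prob = c(0.8, 0.2))
    blocks <- vector("list", n_species)
    for (s in seq_len(n_species)) {
      partner <- if (!is.na(sister_group[s]) && s %% 2 == 0) s - 1L else NA
      bl <- list()
      for (b in var_blocks) {
        bl[[b]] <- if (!is.na(partner) && b != "v1") blocks[[partner]][[b]]
                   else .mutate_seq(backbone[[b]], divergence)
      }
      blocks[[s]] <- bl
    }
    assemble <- function(s, scrambled_sites = character(0)) {
      parts <- character(nrow(SYN_LAYOUT))
      for (i in seq_len(nrow(SYN_LAYOUT))) {
        b <- SYN_LAYOUT$block[i]
        parts[i] <- if (b %in% scrambled_sites) {
          .rand_seq(SYN_LAYOUT$len[i])
        } else if (b == "site27") {
          SYN_SITES[[paste0("site27_", site27_type[s])]]
        } else if (SYN_LAYOUT$type[i] == "variable") {
          blocks[[s]][[b]]
        } else {
          backbone[[b]]
        }
      }
      paste(parts, collapse = "")
    }
    dropout_sites <- rep("", n_species)
    if (!is.null(primer_dropout)) {
      for (i in seq_len(nrow(primer_dropout))) {
        s <- match(primer_dropout$species[i], species)
        if (is.na(s)) abort(paste0("dropout species not in world: ",
                                   primer_dropout$species[i]))
        site <- SYN_DROPOUT_SITE[[primer_dropout$region[i]]]
        dropout_sites[s] <- paste(
          unique(c(strsplit(dropout_sites[s], ",")[[1]], site)),
          collapse = ","
        )
      }
    }
    seqs <- vapply(seq_len(n_species), function(s) {
      assemble(s, strsplit(dropout_sites[s], ",")[[1]])
    }, character(1))
    # truth records
    abbrev <- gsub("[^A-Za-z]", "", vapply(
      strsplit(species, " "),
      function(w) paste0(substr(w[1], 1, 3), substr(w[length(w)], 1, 4)), character(1)
    ))
    rec <- list()
    for (s in seq_len(n_species)) {
      lin_str <- format_lineage(lineages[s, ], "qiime-generic")
      for (r in seq_len(records_per_species)) {
        sq <- if (r == 1) seqs[s] else .mutate_seq(seqs[s], record_noise)
        rec[[length(rec) + 1L]] <- bind_cols(
          tibble(id = sprintf("%s_%02d", abbrev[s], r), sequence = sq,
                 length = nchar(sq)),
          lineages[s, ], tibble(lineage = lin_str)
        )
      }
    }
    truth_tbl <- bind_rows(rec)
    truth <- new_ref_db(truth_tbl, name = "truth", dialect = "qiime-generic")
    # engineered defects, disjoint subsets
    m <- max(1L, round(defect_fraction * n_species))
    defect_pool <- sample(species, min(3L * m, n_species))
    sub_gg2 <- defect_pool[seq_len(m)]
    sub_silva <- defect_pool[seq_len(min(2L * m, length(defect_pool)))][-seq_len(m)]
    sub_rdp <- setdiff(defect_pool, c(sub_gg2, sub_silva))
    mislabel_to <- setNames(
      if (length(sub_gg2) > 1) sub_gg2[c(seq_along(sub_gg2)[-1], 1L)]
      else setdiff(species, sub_gg2)[1],
      sub_gg2
    )
    derive <- function(dbname, dialect) {
      tbl <- truth_tbl |> mutate(id = paste0(dbname, "_", .data$id))
      if (dbname == "greengenes2") {
        for (sp in names(mislabel_to)) {
          idx <- which(tbl$species == sp)
          rep_lin <- .syn_lineage(mislabel_to[[sp]])
          tbl[idx, names(rep_lin)] <- rep_lin[rep(1, length(idx)), ]
        }
      } else if (dbname == "silva") {
        tbl <- tbl[!tbl$species %in% sub_silva, , drop = FALSE]
      } else if (dbname == "rdp") {
        idx <- tbl$species %in% sub_rdp
        tbl$species[idx] <- NA_character_
        tbl$species_norm[idx] <- NA_character_
      }
      tbl$lineage <- vapply(seq_len(nrow(tbl)), function(i) {
        format_lineage(tbl[i, ], dialect)
      }, character(1))
      new_ref_db(tbl, name = dbname, dialect = dialect)
    }
    databases <- list(
      greengenes2 = derive("greengenes2", "greengenes2"),
      silva = derive("silva", "silva"),
      rdp = derive("rdp", "rdp")
    )
    manifest <- tibble(
      species = species, species_norm = normalize_species(species),
      sister_group = sister_group, site27_type = site27_type,
      gg2_mislabeled_as = unname(mislabel_to[species]),
      silva_omitted = species %in% sub_silva,
      rdp_truncated = species %in% sub_rdp,
      dropout_sites = dropout_sites
    )
    structure(
      list(
        truth = truth, databases = databases, manifest = manifest,
        params = list(
          n_species = n_species, n_sister_pairs = n_sister_pairs,
          records_per_species = records_per_species,
          divergence = divergence, record_noise = record_noise,
          defect_fraction = defect_fraction, seed = seed
        )
      ),
      class = "synthetic_world"
    )
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @export
print.synthetic_world <- function(x, ...) {
  p <- x$params
  cat("<synthetic_world> ", p$n_species, " species x ",
      p$records_per_species, " records; ", p$n_sister_pairs,
      " sister pair(s); databases: ",
      paste(names(x$databases), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate mock-community reads for one region
#'
#' Draws read counts multinomially from the mock's species abundances; each
#' read is one of that species' amplicons for the region (record chosen
#' uniformly, forward primer recorded by sampling the panel's mixture
#' weights, e.g. 4:1 for 27F-A:27F-B), optionally truncated to
#' `read_length`, with iid substitution errors at `error_rate`. A species
#' whose records yield no amplicon for the region (primer dropout) gets a
#' warning and zero reads — its reads vanish, inflating everyone else's
#' relative share, exactly the underestimation artefact seen with
#' dropout-prone primer sets.
#'
#' @param world A `synthetic_world`.
#' @param mock Tibble (`species`, `abundance`); abundances must sum to 1.
#' @param region Panel region label (default `"V1-V3"`) or `"full-length"`.
#' @param n_reads Total reads drawn (default 1000).
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param read_length Optional forward-read truncation length (e.g. 223).
#' @param sample_id Sample label used in read ids.
#' @param max_mismatch,clamp Passed to [amplify()].
#' @param seed Integer seed; fixed seed gives identical reads (and FASTQ
#'   bytes via [write_fastq()]).
#' @return List: `reads` (tibble `read_id`, `sequence`), `truth` (tibble
#'   `read_id`, `species`, `record_id`, `fwd_primer`), `region`,
#'   `sample_id`.
#' @export
simulate_reads <- function(world, mock, region = "V1-V3", n_reads = 1000L,
                           error_rate = 0.001, read_length = NULL,
                           sample_id = "mock1", max_mismatch = 1L,
                           clamp = 4L, seed = NULL) {
  stopifnot(n_reads > 0)
  if (abs(sum(mock$abundance) - 1) > 1e-6) {
    abort("mock abundances must sum to 1")
  }
  panel <- builtin_panel()
  pset <- get_primer_set(panel, region)
  fwd <- pset[pset$direction == "fwd", , drop = FALSE]
  run <- function() {
    pools <- vector("list", nrow(mock))
    for (i in seq_len(nrow(mock))) {
      recs <- world$truth[
        !is.na(world$truth$species_norm) &
          tolower(world$truth$species_norm) ==
          tolower(normalize_species(mock$species[i])), , drop = FALSE]
      if (nrow(recs) == 0) abort(paste0("species not in world: ",
                                        mock$species[i]))
      amp <- amplify_database(recs, region, panel,
                              max_mismatch = max_mismatch, clamp = clamp)
      pools[[i]] <- amp$amplicons |>
        group_by(.data$source_id) |>
        slice_head(n = 1) |>
        ungroup()
    }
    counts <- as.vector(rmultinom(1, n_reads, mock$abundance))
    reads <- list(); truth <- list()
    for (i in seq_len(nrow(mock))) {
      if (counts[i] == 0) next
      pool <- pools[[i]]
      if (nrow(pool) == 0) {
        warn(paste0("region ", region, " unamplifiable for ",
                    mock$species[i], "; zero reads emitted"))
        next
      }
      pick_rec <- sample.int(nrow(pool), counts[i], replace = TRUE)
      sqs <- pool$sequence[pick_rec]
      if (!is.null(read_length)) sqs <- substr(sqs, 1L, read_length)
      if (error_rate > 0) {
        sqs <- vapply(sqs, .mutate_seq, character(1), rate = error_rate,
                      USE.NAMES = FALSE)
      }
      primer <- sample(fwd$primer, counts[i], replace = TRUE,
                       prob = fwd$weight)
      reads[[i]] <- tibble(species = mock$species[i],
                           record_id = pool$source_id[pick_rec],
                           fwd_primer = primer, sequence = sqs)
    }
    rt <- bind_rows(reads)
    if (nrow(rt) > 0) {
      rt$read_id <- sprintf("%s_r%05d", sample_id, seq_len(nrow(rt)))
    } else {
      rt$read_id <- character(0)
    }
    list(
      reads = select(rt, "read_id", "sequence"),
      truth = select(rt, "read_id", "species", "record_id", "fwd_primer"),
      region = region, sample_id = sample_id
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write reads as FASTQ
#'
#' Constant quality (`I`, Q40). Deterministic: identical read tables give
#' identical bytes.
#'
#' @param reads Tibble with `read_id` and `sequence` (e.g.
#'   `simulate_reads()$reads`).
#' @param path Output path (".gz" supported).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    strrep("I", nchar(reads$sequence))), con)
  invisible(path)
}

#' Write a synthetic world to disk
#'
#' Emits the truth database and each derived database as FASTA (headers in
#' each database's own taxonomy dialect), a lineage TSV sidecar for the
#' truth set, and the manifest as JSON.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$truth, file.path(dir, "truth.fasta"))
  readr::write_tsv(
    tibble(id = world$truth$id, lineage = world$truth$lineage),
    file.path(dir, "truth_lineage.tsv"), col_names = FALSE
  )
  for (nm in names(world$databases)) {
    write_fasta(world$databases[[nm]], file.path(dir, paste0(nm, ".fasta")))
  }
  jsonlite::write_json(
    c(world$params, list(manifest = as.data.frame(world$manifest))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
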