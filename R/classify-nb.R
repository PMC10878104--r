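# k-mer multinomial naive Bayes classifier with RDP-style bootstrap
# confidence. One class per distinct training lineage; plus-strand k-mer
# counts only, with queries orientation-normalized against the model first.

# lineage strings ("; "-joined rank values) -> rank matrix (classes x 7)
.lineage_rank_matrix <- function(lineages) {
  parts <- str_split(lineages, stringr::fixed("; "))
  m <- matrix(NA_character_, length(lineages), 7L,
              dimnames = list(NULL, TAX_RANKS))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    p <- p[nzchar(p)]
    m[i, seq_along(p)] <- p
  }
  m
}

# tibble rank columns -> class label strings
.db_class_labels <- function(db) {
  apply(as.matrix(db[TAX_RANKS]), 1L, function(r) {
    paste(r[!is.na(r)], collapse = "; ")
  })
}

#' Train a k-mer naive Bayes taxonomic classifier
#'
#' Builds a multinomial naive Bayes model over overlapping k-mers of the
#' training sequences, one class per distinct lineage in the database, with
#' Laplace smoothing `alpha`. Counts come from the plus strand only; query
#' orientation is normalized at classification time. Class priors are the
#' training-record proportions.
#'
#' @param db A `ref_db` tibble with lineage columns (see [read_fasta()]).
#' @param k k-mer size, 4-12 (default 8). Memory grows as 4^k.
#' @param alpha Laplace smoothing pseudo-count (default 0.001); `alpha = 0`
#'   leaves unseen k-mers at probability zero (log-probability `-Inf`).
#' @return An object of class `nb_classifier`.
#' @export
train_nb <- function(db, k = 8L, alpha = 0.001) {
  if (nrow(db) == 0) abort("cannot train on an empty database")
  stopifnot(k >= 4, k <= 12, alpha >= 0)
  if (all(nchar(db$sequence) < k)) {
    abort("k is larger than every training sequence")
  }
  labels <- .db_class_labels(db)
  counts <- oligonucleotideFrequency(DNAStringSet(db$sequence), width = k)
  cls <- sort(unique(labels))
  class_counts <- rowsum(counts, group = factor(labels, levels = cls))
  sm <- class_counts + alpha
  log_prob <- log(sm) - log(rowSums(sm))
  prior <- as.numeric(table(factor(labels, levels = cls)))
  structure(
    list(
      k = as.integer(k), alpha = alpha,
      classes = cls,
      class_ranks = .lineage_rank_matrix(cls),
      log_prob = log_prob,
      log_prior = log(prior / sum(prior)),
      vocab_present = colSums(class_counts) > 0,
      database = attr(db, "db_name") %||% "custom"
    ),
    class = "nb_classifier"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Choose query orientation by shared k-mer types with the training vocabulary.
.orient_query <- function(seq, k, vocab_present) {
  if (nchar(seq) < k) return(seq)
  fw <- oligonucleotideFrequency(DNAString(seq), width = k) > 0
  rc <- revcomp(seq)
  rv <- oligonucleotideFrequency(DNAString(rc), width = k) > 0
  if (sum(rv & vocab_present) > sum(fw & vocab_present)) rc else seq
}

# Deepest-first truncation: ranks assigned while confidence >= threshold.
.assign_depth <- function(rank_conf, depth_available, threshold) {
  d <- 0L
  for (r in seq_len(depth_available)) {
    if (rank_conf[r] >= threshold) d <- r else break
  }
  d
}

.unclassified_row <- function(id, method, database) {
  tibble(
    query_id = id, lineage = NA_character_, species = NA_character_,
    confidence = 0, method = method, database = database
  )
}

#' Classify sequences with a naive Bayes model
#'
#' Point prediction is the posterior argmax over classes given the query's
#' k-mer counts. Confidence per rank is the fraction of bootstrap k-mer
#' subsamples (multinomial resamples of `subsample` times the query's k-mer
#' total) whose argmax agrees with the point prediction at that rank; the
#' lineage is truncated below the first rank whose confidence falls under
#' `threshold`. Ties are broken lexicographically on the full lineage
#' string, so results are independent of training-record order. With a
#' `seed` the whole batch is reproducible.
#'
#' @param model An `nb_classifier` from [train_nb()].
#' @param queries Named character vector of sequences, or a tibble with
#'   `id`/`query_id` and `sequence` columns.
#' @param threshold Per-rank bootstrap confidence required to keep a rank
#'   (default 0.7); 0 keeps the full predicted lineage.
#' @param n_bootstrap Number of bootstrap subsamples (default 100).
#' @param subsample Fraction of the query's k-mer count drawn per bootstrap
#'   (default 1/8).
#' @param seed Optional integer seed for the batch.
#' @return Tibble: `query_id`, `lineage` (assigned prefix, `NA` if nothing
#'   assigned), `species` (normalized binomial or `NA`), `confidence`
#'   (agreement at the deepest assigned rank), `method` (`"nb"`),
#'   `database`.
#' @export
classify_nb <- function(model, queries, threshold = 0.7, n_bootstrap = 100L,
                        subsample = 1 / 8, seed = NULL) {
  q <- .as_query_tbl(queries)
  run <- function() {
    out <- vector("list", nrow(q))
    chunk <- 64L
    for (lo in seq(1L, nrow(q), by = chunk)) {
      hi <- min(lo + chunk - 1L, nrow(q))
      counts <- .query_kmer_counts(q$sequence[lo:hi], model$k,
                                   model$vocab_present)
      for (i in lo:hi) {
        out[[i]] <- .classify_nb_one(model, q$query_id[i],
                                     counts[i - lo + 1L, ],
                                     threshold, n_bootstrap, subsample)
      }
    }
    bind_rows(out)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Orientation-normalized k-mer count matrix for a batch of queries.
# Sequences shorter than k (or NA) get an all-zero row.
.query_kmer_counts <- function(seqs, k, vocab_present) {
  ok <- !is.na(seqs) & nchar(seqs) >= k
  counts <- matrix(0L, length(seqs), 4L^k)
  if (!any(ok)) return(counts)
  safe <- ifelse(ok, seqs, strrep("A", k))
  ss <- DNAStringSet(safe)
  fw <- oligonucleotideFrequency(ss, width = k)
  rc <- oligonucleotideFrequency(reverseComplement(ss), width = k)
  shared_fw <- as.numeric((fw > 0) %*% vocab_present)
  shared_rc <- as.numeric((rc > 0) %*% vocab_present)
  use_rc <- shared_rc > shared_fw
  counts[ok & !use_rc, ] <- fw[ok & !use_rc, , drop = FALSE]
  counts[ok & use_rc, ] <- rc[ok & use_rc, , drop = FALSE]
  counts
}

.as_query_tbl <- function(queries) {
  if (is.character(queries)) {
    ids <- names(queries) %||% paste0("query", seq_along(queries))
    if (is.null(names(queries)) && length(queries) == 1) ids <- "query"
    return(tibble(query_id = ids, sequence = toupper(unname(queries))))
  }
  nm <- intersect(c("query_id", "id", "read_id"), names(queries))[1]
  if (is.na(nm) || !"sequence" %in% names(queries)) {
    abort("queries must have an id (query_id/id/read_id) and a sequence column")
  }
  tibble(query_id = queries[[nm]], sequence = toupper(queries$sequence))
}

.classify_nb_one <- function(model, id, x, threshold, n_bootstrap,
                             subsample) {
  nz <- which(x > 0)
  if (length(nz) == 0) return(.unclassified_row(id, "nb", model$database))
  lp <- model$log_prob[, nz, drop = FALSE]
  scores <- as.numeric(lp %*% x[nz]) + model$log_prior
  win <- .argmax_lex(scores, model$classes)
  # bootstrap agreement per rank
  total <- sum(x[nz])
  m <- max(1L, as.integer(round(total * subsample)))
  boot <- rmultinom(n_bootstrap, m, prob = x[nz] / total)
  # clamp -Inf (alpha = 0) so absent k-mers with zero resampled count
  # contribute 0, not NaN
  bscores <- pmax(lp, -1e9) %*% boot + model$log_prior
  bwin <- apply(bscores, 2L, .argmax_lex, classes = model$classes)
  ranks <- model$class_ranks
  depth <- sum(!is.na(ranks[win, ]))
  conf_rank <- vapply(seq_len(7L), function(r) {
    if (r > depth) return(0)
    mean(!is.na(ranks[bwin, r]) & ranks[bwin, r] == ranks[win, r])
  }, numeric(1))
  d <- .assign_depth(conf_rank, depth, threshold)
  if (d == 0L) return(.unclassified_row(id, "nb", model$database))
  assigned <- ranks[win, seq_len(d)]
  tibble(
    query_id = id,
    lineage = paste(assigned, collapse = "; "),
    species = if (d == 7L) normalize_species(assigned[7L]) else NA_character_,
    confidence = conf_rank[d],
    method = "nb", database = model$database
  )
}

# argmax with deterministic lexicographic tie-break on the class label.
.argmax_lex <- function(scores, classes) {
  mx <- max(scores)
  cand <- which(scores >= mx - 1e-12)
  cand[order(classes[cand])][1]
}

#' Naive Bayes class scores for one query
#'
#' The per-class log joint score `log prior + sum_w n_w log p(w | class)`
#' over the query's k-mer counts, and the normalized posterior. Exposed so
#' the fast classifier can be checked against direct log-likelihood
#' computation.
#'
#' @param model An `nb_classifier`.
#' @param sequence One query sequence.
#' @param orient Orientation-normalize the query against the model first
#'   (default TRUE).
#' @return Tibble: `class`, `log_score`, `posterior` (softmax of the log
#'   scores), sorted by decreasing posterior.
#' @export
nb_posterior <- function(model, sequence, orient = TRUE) {
  stopifnot(length(sequence) == 1, nchar(sequence) >= model$k)
  if (orient) {
    sequence <- .orient_query(toupper(sequence), model$k,
                              model$vocab_present)
  }
  x <- oligonucleotideFrequency(DNAString(toupper(sequence)),
                                width = model$k)
  nz <- which(x > 0)
  scores <- as.numeric(model$log_prob[, nz, drop = FALSE] %*% x[nz]) +
    model$log_prior
  post <- exp(scores - max(scores))
  post <- post / sum(post)
  tibble(class = model$classes, log_score = scores, posterior = post) |>
    arrange(desc(.data$posterior), .data$class)
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat("<nb_classifier> k=", x$k, ", alpha=", x$alpha, ", ",
      length(x$classes), " classes, database: ", x$database, "\n", sep = "")
  invisible(x)
}

#' @describeIn train_nb One row per class: lineage, species, prior.
#' @param x An `nb_classifier`.
#' @param ... Unused.
#' @export
tidy.nb_classifier <- function(x, ...) {
  tibble(
    class = x$classes,
    species = normalize_species(x$class_ranks[, "species"]),
    prior = exp(x$log_prior)
  )
}

#' @describeIn train_nb One-row model summary.
#' @export
glance.nb_classifier <- function(x, ...) {
  tibble(
    k = x$k, alpha = x$alpha, n_classes = length(x$classes),
    n_features = ncol(x$log_prob), database = x$database
  )
}
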