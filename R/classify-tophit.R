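# Top-hit consensus classifier: global pairwise alignment of a query
# against k-mer-prefiltered candidate references, then a rank-wise majority
# consensus over the accepted hits. Self-contained (no external aligner).

#' Classify sequences by top-hit alignment consensus
#'
#' For each query, candidate references are ranked by shared k-mer types,
#' the best candidates are globally aligned (match +1, mismatch -1, gap
#' open -5, gap extend -2) and up to `max_accepts` hits with identity at
#' least `min_identity` are kept. The predicted lineage is the rank-wise
#' majority consensus: a rank is assigned when at least
#' `consensus_threshold` of the kept hits agree on its taxon, stopping at
#' the first failing rank. Confidence is the consensus fraction at the
#' species rank (0 when truncated above species). With `max_accepts = 1`
#' and a majority threshold this reduces to nearest-neighbor assignment by
#' alignment identity.
#'
#' Identity is computed as matching positions over alignment length (PID1).
#' Queries are orientation-normalized against the database first.
#'
#' @param db A `ref_db` tibble (non-empty).
#' @param queries Named character vector or tibble with `id`/`query_id` and
#'   `sequence` columns.
#' @param min_identity Minimum fractional identity of an accepted hit
#'   (default 0.8).
#' @param max_accepts Maximum hits used for the consensus (default 10).
#' @param consensus_threshold Agreement fraction required to assign a rank
#'   (default 0.51).
#' @param top_margin Only hits whose identity is within `top_margin` of the
#'   best hit join the consensus (default 0.005), so the consensus is taken
#'   over co-optimal hits rather than every passable alignment.
#' @param prefilter_k k-mer size of the candidate prefilter (default 8).
#' @param candidates_per_accept Candidates aligned per accepted hit slot
#'   (default 3).
#' @return Tibble as from [classify_nb()], `method = "tophit"`.
#' @export
classify_tophit <- function(db, queries, min_identity = 0.8,
                            max_accepts = 10L, consensus_threshold = 0.51,
                            top_margin = 0.005, prefilter_k = 8L,
                            candidates_per_accept = 3L) {
  if (nrow(db) == 0) abort("cannot classify against an empty database")
  q <- .as_query_tbl(queries)
  dbname <- attr(db, "db_name") %||% "custom"
  ref_set <- DNAStringSet(db$sequence)
  ref_pres <- oligonucleotideFrequency(ref_set, width = prefilter_k) > 0
  vocab <- colSums(ref_pres) > 0
  ranks <- as.matrix(db[TAX_RANKS])
  lineage_key <- .db_class_labels(db)
  submat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                         baseOnly = FALSE, type = "DNA")
  n_cand <- max_accepts * candidates_per_accept
  out <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    out[[i]] <- .classify_tophit_one(
      q$query_id[i], q$sequence[i], db, ref_set, ref_pres, vocab, ranks,
      lineage_key, submat, min_identity, max_accepts, consensus_threshold,
      top_margin, prefilter_k, n_cand, dbname
    )
  }
  bind_rows(out)
}

.classify_tophit_one <- function(id, seq, db, ref_set, ref_pres, vocab,
                                 ranks, lineage_key, submat, min_identity,
                                 max_accepts, consensus_threshold,
                                 top_margin, prefilter_k, n_cand, dbname) {
  if (is.na(seq) || nchar(seq) < prefilter_k) {
    return(.unclassified_row(id, "tophit", dbname))
  }
  seq <- .orient_query(seq, prefilter_k, vocab)
  qp <- oligonucleotideFrequency(DNAString(seq), width = prefilter_k) > 0
  shared <- as.numeric(ref_pres %*% qp)
  ord <- order(-shared, lineage_key, db$id)
  cand <- ord[shared[ord] > 0][seq_len(min(n_cand, sum(shared > 0)))]
  if (length(cand) == 0) return(.unclassified_row(id, "tophit", dbname))
  aln <- pairwiseAlignment(
    rep(DNAStringSet(seq), length(cand)), ref_set[cand],
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
    type = "global"
  )
  identity <- pid(aln, type = "PID1") / 100
  keep <- which(identity >= min_identity)
  if (length(keep) == 0) return(.unclassified_row(id, "tophit", dbname))
  keep <- keep[identity[keep] >= max(identity[keep]) - top_margin]
  keep <- keep[order(-identity[keep], lineage_key[cand[keep]],
                     db$id[cand[keep]])]
  keep <- keep[seq_len(min(max_accepts, length(keep)))]
  hit_ranks <- ranks[cand[keep], , drop = FALSE]
  n_hits <- nrow(hit_ranks)
  assigned <- character(0)
  conf_species <- 0
  for (r in seq_len(7L)) {
    taxa <- hit_ranks[, r]
    taxa[is.na(taxa)] <- "<none>"
    tt <- sort(table(taxa), decreasing = TRUE)
    top <- names(tt)[order(-tt, names(tt))][1]
    frac <- tt[[top]] / n_hits
    if (top == "<none>" || frac < consensus_threshold) break
    assigned <- c(assigned, top)
    if (r == 7L) conf_species <- frac
  }
  if (length(assigned) == 0) return(.unclassified_row(id, "tophit", dbname))
  tibble(
    query_id = id,
    lineage = paste(assigned, collapse = "; "),
    species = if (length(assigned) == 7L) normalize_species(assigned[7L])
              else NA_character_,
    confidence = conf_species,
    method = "tophit", database = dbname
  )
}

#' Classify queries with either method
#'
#' Convenience wrapper: trains a naive Bayes model on `db` (or aligns
#' directly for `"tophit"`) and returns a tidy classification table.
#'
#' @param queries Sequences, see [classify_nb()].
#' @param db Reference database.
#' @param method `"nb"` or `"tophit"`.
#' @param ... Passed to [classify_nb()] or [classify_tophit()]; for `"nb"`,
#'   `k` and `alpha` are forwarded to [train_nb()].
#' @return Classification tibble.
#' @export
classify_sequences <- function(queries, db, method = c("nb", "tophit"), ...) {
  method <- match.arg(method)
  if (method == "nb") {
    dots <- list(...)
    train_args <- dots[intersect(names(dots), c("k", "alpha"))]
    cls_args <- dots[setdiff(names(dots), c("k", "alpha"))]
    model <- do.call(train_nb, c(list(db = db), train_args))
    do.call(classify_nb, c(list(model = model, queries = queries), cls_args))
  } else {
    classify_tophit(db, queries, ...)
  }
}
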