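# End-to-end orchestration of the two evaluation designs: the in-silico
# region x method x database benchmark with the combined-database rule, and
# the mock-community partial-versus-full-length comparison.

#' Run the region x method x database benchmark
#'
#' Amplifies every truth record for each region, classifies the amplicons
#' with each (method, database) pipeline, scores per-species accuracy,
#' builds the species-to-best-database lookup per (region, method), applies
#' it to produce combined classifications, and summarises every pipeline
#' (including the combined one) as mean +/- sd accuracy across species,
#' with a separate key-Lactobacillus block when those species are present.
#' Fully reproducible given `seed`.
#'
#' @param truth_db Truth `ref_db` whose records carry true species labels;
#'   its amplicons are the evaluation queries.
#' @param databases Named list of reference `ref_db`s to benchmark.
#' @param regions Regions from `panel` to evaluate.
#' @param methods Classification methods, subset of `c("nb", "tophit")`.
#' @param panel Primer panel, default [builtin_panel()].
#' @param max_mismatch,clamp In-silico PCR parameters.
#' @param truncate_to Optional read-truncation length applied to every
#'   amplicon before classification (e.g. 223 to emulate Novaseq forward
#'   reads).
#' @param k,alpha,threshold,n_bootstrap,subsample Naive Bayes parameters.
#' @param min_identity,max_accepts,consensus_threshold Top-hit parameters.
#' @param priority Database tie-break priority for the lookup.
#' @param fallback_db Fallback database for the combined rule; default is
#'   the database with the best mean accuracy for each (region, method).
#' @param seed Integer seed covering all classifier randomness.
#' @return An `evaluation_result`: list with `truth` (query-level truth),
#'   `predictions` (per-pipeline and combined), `accuracy`
#'   (`accuracy_tbl`), `lookups` (named `combined_lookup` list,
#'   `region|method` keys), `amplification` (per-species amplification
#'   report) and `summary`.
#' @export
run_evaluation <- function(truth_db, databases,
                           regions = c("V1-V3", "V4"), methods = "nb",
                           panel = builtin_panel(), max_mismatch = 1L,
                           clamp = 4L, truncate_to = NULL, k = 8L,
                           alpha = 0.001, threshold = 0.7,
                           n_bootstrap = 100L, subsample = 1 / 8,
                           min_identity = 0.8, max_accepts = 10L,
                           consensus_threshold = 0.51,
                           priority = c("rdp", "silva", "greengenes2"),
                           fallback_db = NULL, seed = NULL) {
  stopifnot(all(methods %in% c("nb", "tophit")))
  if (is.null(names(databases)) || any(!nzchar(names(databases)))) {
    abort("`databases` must be a named list")
  }
  run <- function() {
    # queries: one amplicon per record per region
    truth_rows <- list(); queries <- list(); amp_reports <- list()
    for (rg in regions) {
      amp <- amplify_database(truth_db, rg, panel,
                              max_mismatch = max_mismatch, clamp = clamp)
      amp_reports[[rg]] <- amp$report
      a1 <- amp$amplicons |>
        group_by(.data$source_id) |>
        slice_head(n = 1) |>
        ungroup()
      if (nrow(a1) == 0) next
      qid <- paste(a1$source_id, rg, sep = "|")
      sq <- a1$sequence
      if (!is.null(truncate_to)) sq <- substr(sq, 1L, truncate_to)
      queries[[rg]] <- tibble(query_id = qid, sequence = sq)
      truth_rows[[rg]] <- tibble(
        query_id = qid, region = rg,
        species = truth_db$species_norm[match(a1$source_id, truth_db$id)]
      )
    }
    truth <- bind_rows(truth_rows)
    if (nrow(truth) == 0) abort("no region produced any amplicon")
    preds <- list()
    for (dbname in names(databases)) {
      db <- databases[[dbname]]
      model <- if ("nb" %in% methods) train_nb(db, k = k, alpha = alpha)
      for (mth in methods) {
        for (rg in names(queries)) {
          p <- if (mth == "nb") {
            classify_nb(model, queries[[rg]], threshold = threshold,
                        n_bootstrap = n_bootstrap, subsample = subsample)
          } else {
            classify_tophit(db, queries[[rg]], min_identity = min_identity,
                            max_accepts = max_accepts,
                            consensus_threshold = consensus_threshold)
          }
          p$database <- dbname # authoritative name, independent of db attrs
          preds[[paste(dbname, mth, rg, sep = "|")]] <- mutate(p, region = rg)
        }
      }
    }
    predictions <- bind_rows(preds)
    accuracy <- score_accuracy(predictions, truth)
    lookups <- list(); combined <- list()
    for (mth in methods) {
      for (rg in names(queries)) {
        lk <- build_lookup(accuracy, region = rg, method = mth,
                           priority = priority)
        lookups[[paste(rg, mth, sep = "|")]] <- lk
        fb <- fallback_db
        if (is.null(fb)) {
          means <- accuracy |>
            filter(.data$region == rg, .data$method == mth) |>
            group_by(.data$database) |>
            summarise(m = mean(.data$accuracy), .groups = "drop") |>
            arrange(desc(.data$m), .data$database)
          fb <- means$database[1]
        }
        slice_preds <- filter(predictions, .data$region == rg,
                              .data$method == mth)
        cmb <- combine_classifications(slice_preds, lk, fb) |>
          mutate(database = "combined")
        combined[[paste(rg, mth, sep = "|")]] <- cmb
      }
    }
    predictions <- bind_rows(predictions, bind_rows(combined))
    accuracy <- score_accuracy(predictions, truth)
    structure(
      list(
        truth = truth, predictions = predictions, accuracy = accuracy,
        lookups = lookups, amplification = bind_rows(amp_reports),
        summary = pipeline_summary(accuracy)
      ),
      class = "evaluation_result"
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> ", length(unique(x$truth$region)), " region(s), ",
      nrow(x$summary[x$summary$subset == "all", ]), " pipeline rows\n",
      sep = "")
  print(x$summary, n = 20)
  invisible(x)
}

#' @describeIn run_evaluation Per-species accuracy in long form.
#' @param x An `evaluation_result`.
#' @param ... Unused.
#' @export
tidy.evaluation_result <- function(x, ...) as_tibble(x$accuracy)

#' @describeIn run_evaluation One row per pipeline (the `"all"` summary).
#' @export
glance.evaluation_result <- function(x, ...) {
  filter(x$summary, .data$subset == "all")
}

#' Compare per-region mock profiles against full-length truth
#'
#' For each region: how many of the species identified by full-length
#' sequencing were recovered, the four profile dissimilarities against the
#' full-length profile per sample, and a pooled principal coordinates
#' embedding of all (sample, region) profiles together with the full-length
#' ones.
#'
#' @param profiles Long tibble of per-region profiles: `sample_id`,
#'   `region`, `species`, `abundance`.
#' @param truth_profiles Long tibble of full-length profiles: `sample_id`,
#'   `species`, `abundance`.
#' @param metrics Dissimilarity metrics to compute.
#' @param pcoa_metric Metric used for the pooled ordination.
#' @return A `mock_comparison`: list with `recovery` (per region:
#'   `n_truth_species`, `n_detected`), `dissimilarity` (per sample x region
#'   x metric) and `pcoa`.
#' @export
run_mock_comparison <- function(profiles, truth_profiles,
                                metrics = c("bray-curtis", "euclidean",
                                            "jaccard", "kulczynski"),
                                pcoa_metric = "bray-curtis") {
  metrics <- match.arg(metrics, several.ok = TRUE)
  truth_sp <- truth_profiles |>
    filter(.data$abundance > 0, .data$species != "unclassified")
  recovery <- profiles |>
    filter(.data$abundance > 0, .data$species != "unclassified") |>
    semi_join(truth_sp, by = c("sample_id", "species")) |>
    group_by(.data$region) |>
    summarise(n_detected = n_distinct(.data$species), .groups = "drop") |>
    complete(region = unique(profiles$region),
             fill = list(n_detected = 0L)) |>
    mutate(n_truth_species = n_distinct(truth_sp$species))
  pairs <- distinct(profiles, .data$sample_id, .data$region)
  dis <- list()
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$sample_id[i]; rg <- pairs$region[i]
    px <- filter(profiles, .data$sample_id == sid, .data$region == rg)
    pt <- filter(truth_profiles, .data$sample_id == sid)
    if (nrow(pt) == 0) next # region present but no truth: recorded missing
    for (mt in metrics) {
      dis[[length(dis) + 1L]] <- tibble(
        sample_id = sid, region = rg, metric = mt,
        dissimilarity = dissimilarity(px, pt, metric = mt)
      )
    }
  }
  pooled <- bind_rows(
    profiles |>
      mutate(sample_id = paste(.data$sample_id, .data$region, sep = "|")) |>
      select("sample_id", "species", "abundance"),
    truth_profiles |>
      mutate(sample_id = paste(.data$sample_id, "full-length", sep = "|")) |>
      select("sample_id", "species", "abundance")
  )
  ord <- pcoa(dissimilarity_matrix(pooled, metric = pcoa_metric))
  structure(
    list(recovery = recovery, dissimilarity = bind_rows(dis), pcoa = ord,
         pcoa_metric = pcoa_metric),
    class = "mock_comparison"
  )
}

#' @export
print.mock_comparison <- function(x, ...) {
  cat("<mock_comparison> regions: ",
      paste(x$recovery$region, collapse = ", "), "\n", sep = "")
  print(x$recovery)
  invisible(x)
}
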