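# Per-species accuracy scoring across (method, database, region) pipelines,
# the species -> best-database lookup, and the combined classification rule
# that delegates each species call to its most accurate database.

#' Score per-species classification accuracy
#'
#' Joins predictions to the ground truth and computes, for every
#' (species, region, method, database) cell, the fraction of that species'
#' queries assigned the correct species. A prediction truncated above
#' species, an unclassified result and a missing prediction all count as
#' incorrect. Species matching is on normalized binomials,
#' case-insensitive.
#'
#' @param predictions Tibble with `query_id`, `species`, `method`,
#'   `database` and optionally `region` columns (as produced by the
#'   classifiers, plus a region tag).
#' @param truth Tibble with `query_id`, `species` and optionally `region`.
#'   Every prediction's query must appear in the truth; every truth query is
#'   scored for every (method, database) pipeline present.
#' @return An `accuracy_tbl` tibble: `species`, `region`, `method`,
#'   `database`, `n_correct`, `n_total`, `accuracy`.
#' @export
score_accuracy <- function(predictions, truth) {
  keys <- intersect(intersect(names(predictions), names(truth)),
                    c("query_id", "region"))
  unknown <- anti_join(predictions, truth, by = keys)
  if (nrow(unknown) > 0) {
    abort(paste0("prediction(s) for unknown query: ",
                 paste(head(unique(unknown$query_id), 5), collapse = ", ")))
  }
  pipelines <- distinct(predictions, .data$method, .data$database)
  truth <- rename(truth, true_species = "species")
  grid <- cross_join(truth, pipelines)
  by <- c(keys, "method", "database")
  scored <- left_join(
    grid,
    select(predictions, any_of(c("query_id", "region", "method",
                                 "database", "species"))),
    by = by
  ) |>
    mutate(correct = !is.na(.data$species) &
             tolower(normalize_species(.data$species)) ==
             tolower(normalize_species(.data$true_species)))
  grp <- c("true_species", intersect("region", names(scored)),
           "method", "database")
  out <- scored |>
    group_by(across(all_of(grp))) |>
    summarise(n_correct = sum(.data$correct), n_total = n(),
              .groups = "drop") |>
    mutate(accuracy = .data$n_correct / .data$n_total) |>
    rename(species = "true_species")
  if (!"region" %in% names(out)) out$region <- NA_character_
  out <- select(out, "species", "region", "method", "database",
                "n_correct", "n_total", "accuracy")
  class(out) <- c("accuracy_tbl", class(out))
  out
}

#' Summarise pipelines as mean accuracy across species
#'
#' One row per (region, method, database) pipeline: the unweighted mean and
#' standard deviation of per-species accuracy, for all species and
#' optionally for a tagged subset (e.g. the key Lactobacillus quartet).
#'
#' @param accuracy An `accuracy_tbl` from [score_accuracy()].
#' @param subsets Named list of species vectors to summarise separately, in
#'   addition to the `"all"` rows; default adds `key_lactobacillus` when any
#'   of those species are present.
#' @return Tibble: `subset`, `region`, `method`, `database`, `n_species`,
#'   `mean_accuracy`, `sd_accuracy`.
#' @export
pipeline_summary <- function(accuracy, subsets = NULL) {
  if (is.null(subsets)) {
    subsets <- list()
    if (any(tolower(accuracy$species) %in% tolower(key_lactobacillus()))) {
      subsets$key_lactobacillus <- key_lactobacillus()
    }
  }
  one <- function(tbl, tag) {
    tbl |>
      group_by(.data$region, .data$method, .data$database) |>
      summarise(n_species = n(), mean_accuracy = mean(.data$accuracy),
                sd_accuracy = sd(.data$accuracy), .groups = "drop") |>
      mutate(subset = tag, .before = 1)
  }
  rows <- list(one(accuracy, "all"))
  for (nm in names(subsets)) {
    sub <- accuracy[tolower(accuracy$species) %in%
                      tolower(subsets[[nm]]), , drop = FALSE]
    if (nrow(sub) > 0) rows[[length(rows) + 1L]] <- one(sub, nm)
  }
  bind_rows(rows)
}

#' Build the species-to-best-database lookup
#'
#' For one (region, method) slice of an accuracy table, maps every species
#' to the database that classifies it most accurately. A species absent
#' from a database's predictions counts as accuracy 0 there; exact ties go
#' to the earliest database in `priority`; species with all-zero accuracy
#' are still mapped (to the priority head) and flagged.
#'
#' @param accuracy An `accuracy_tbl`.
#' @param region,method Slice selectors (use `NA` region for unregioned
#'   tables).
#' @param priority Ordered database names used for tie-breaking.
#' @return A `combined_lookup` tibble: `species`, `database`, `accuracy`,
#'   `flagged`; attributes `region`, `method`, `priority` and
#'   `accuracy_slice` (the full species x database accuracy grid used at
#'   combination time).
#' @export
build_lookup <- function(accuracy, region, method,
                         priority = c("rdp", "silva", "greengenes2")) {
  slice <- accuracy[
    (is.na(region) & is.na(accuracy$region) |
       !is.na(accuracy$region) & accuracy$region %in% region) &
      accuracy$method == method, , drop = FALSE]
  if (nrow(slice) == 0) abort("no accuracy entries for that region/method")
  dbs <- unique(slice$database)
  prio_rank <- function(d) {
    r <- match(d, priority)
    ifelse(is.na(r), length(priority) + match(d, sort(unique(d))), r)
  }
  grid <- slice |>
    select("species", "database", "accuracy") |>
    complete(species = unique(slice$species), database = dbs,
             fill = list(accuracy = 0))
  map <- grid |>
    mutate(prio = prio_rank(.data$database)) |>
    group_by(.data$species) |>
    arrange(desc(.data$accuracy), .data$prio, .by_group = TRUE) |>
    summarise(database = first(.data$database),
              accuracy = first(.data$accuracy),
              flagged = all(.data$accuracy == 0), .groups = "drop") |>
    arrange(.data$species)
  structure(
    map,
    class = c("combined_lookup", class(tibble())),
    region = region, method = method, priority = priority,
    accuracy_slice = grid
  )
}

#' Combine per-database classifications with a best-database lookup
#'
#' The inference-time rule behind "apply the most accurate database for each
#' species": a database's species call is accepted only when that database
#' is the designated authority for the species it called. With several
#' accepted candidates for one query, the one whose (species, database)
#' accuracy in the lookup's source grid is highest wins (ties resolved by
#' the lookup's priority order); with none, the fallback database's result
#' is returned and flagged.
#'
#' @param predictions Tibble of per-database results for the same query set:
#'   `query_id`, `species`, `database` (+ any other classifier columns).
#'   Every database named in the lookup must have a row for every query.
#' @param lookup A `combined_lookup` from [build_lookup()].
#' @param fallback_db Database whose result is used when no database is the
#'   authority for its own call.
#' @return Tibble with one row per query: the winning prediction's columns
#'   plus `database` (the source database), `fallback` (logical) and
#'   `method` unchanged, tagged `combined_database = TRUE` via the
#'   `database_rule` attribute.
#' @export
combine_classifications <- function(predictions, lookup, fallback_db) {
  dbs <- unique(attr(lookup, "accuracy_slice")$database)
  if (!fallback_db %in% unique(predictions$database)) {
    abort(paste0("fallback database has no predictions: ", fallback_db))
  }
  counts <- predictions |>
    filter(.data$database %in% dbs) |>
    distinct(.data$query_id, .data$database)
  missing <- tidyr::expand_grid(query_id = unique(predictions$query_id),
                                database = dbs) |>
    anti_join(counts, by = c("query_id", "database"))
  if (nrow(missing) > 0) {
    abort(paste0("missing per-database result(s), e.g. query ",
                 missing$query_id[1], " for database ", missing$database[1]))
  }
  slice <- attr(lookup, "accuracy_slice")
  priority <- attr(lookup, "priority")
  prio_rank <- function(d) {
    r <- match(d, priority)
    ifelse(is.na(r), length(priority) + 1L, r)
  }
  authority <- setNames(lookup$database, tolower(lookup$species))
  preds <- predictions |>
    filter(.data$database %in% dbs) |>
    mutate(
      sp_key = tolower(.data$species),
      is_candidate = !is.na(.data$species) &
        !is.na(authority[.data$sp_key]) &
        authority[.data$sp_key] == .data$database
    ) |>
    left_join(
      slice |>
        mutate(sp_key = tolower(.data$species)) |>
        select("sp_key", "database", sp_acc = "accuracy"),
      by = c("sp_key", "database")
    ) |>
    mutate(sp_acc = ifelse(is.na(.data$sp_acc), 0, .data$sp_acc),
           prio = prio_rank(.data$database))
  winners <- preds |>
    filter(.data$is_candidate) |>
    group_by(.data$query_id) |>
    arrange(desc(.data$sp_acc), .data$prio, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    mutate(fallback = FALSE)
  fellback <- preds |>
    filter(!.data$query_id %in% winners$query_id,
           .data$database == fallback_db) |>
    mutate(fallback = TRUE)
  bind_rows(winners, fellback) |>
    select(-"sp_key", -"is_candidate", -"sp_acc", -"prio") |>
    arrange(.data$query_id)
}

#' @export
print.combined_lookup <- function(x, ...) {
  cat("<combined_lookup> region: ", attr(x, "region"), ", method: ",
      attr(x, "method"), ", priority: ",
      paste(attr(x, "priority"), collapse = " > "), "\n", sep = "")
  NextMethod()
}

#' Tidy a combined lookup
#'
#' @param x A `combined_lookup`.
#' @param ... Unused.
#' @return The species-to-database map as a plain tibble with region and
#'   method columns attached.
#' @export
tidy.combined_lookup <- function(x, ...) {
  as_tibble(x) |>
    mutate(region = attr(x, "region"), method = attr(x, "method"))
}

#' Serialize / read a combined lookup as JSON
#'
#' @param lookup A `combined_lookup`.
#' @param path JSON path.
#' @return `path` invisibly (`write_lookup`); a `combined_lookup`
#'   (`read_lookup`).
#' @export
write_lookup <- function(lookup, path) {
  obj <- list(
    region = attr(lookup, "region"), method = attr(lookup, "method"),
    priority = attr(lookup, "priority"),
    map = as.data.frame(lookup),
    accuracy_slice = as.data.frame(attr(lookup, "accuracy_slice"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    as_tibble(obj$map),
    class = c("combined_lookup", class(tibble())),
    region = obj$region, method = obj$method, priority = obj$priority,
    accuracy_slice = as_tibble(obj$accuracy_slice)
  )
}
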