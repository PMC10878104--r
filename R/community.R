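# Community-level evaluation: species abundance profiles, the four
# profile dissimilarities, principal coordinates analysis, and the
# confusion-matrix concordance metrics used for PCR validation.

#' Build a species-level abundance profile from classifications
#'
#' Counts reads per assigned species and normalizes by the total number of
#' reads; results truncated above species (or unclassified) pool into an
#' explicit `"unclassified"` key so abundances always sum to one.
#'
#' @param results Classification tibble (columns `query_id`, `species`).
#' @param sample_id Sample identifier stored on every row.
#' @return Tibble: `sample_id`, `species`, `abundance`, `n_reads` (total
#'   reads in the sample, constant).
#' @export
profile_from_classifications <- function(results, sample_id = "sample1") {
  if (nrow(results) == 0) abort("no classification results to profile")
  n <- nrow(results)
  results |>
    mutate(species = ifelse(is.na(.data$species), "unclassified",
                            .data$species)) |>
    count(.data$species, name = "n") |>
    transmute(
      sample_id = .env$sample_id, species = .data$species,
      abundance = .data$n / .env$n, n_reads = .env$n
    ) |>
    arrange(desc(.data$abundance))
}

.metric_vegan <- c(
  "bray-curtis" = "bray", "euclidean" = "euclidean",
  "jaccard" = "jaccard", "kulczynski" = "kulczynski"
)

# profiles (long tibbles or named vectors) -> aligned 2 x species matrix
.align_profiles <- function(x, y) {
  as_vec <- function(p) {
    if (is.numeric(p)) return(p)
    setNames(p$abundance, p$species)
  }
  xv <- as_vec(x); yv <- as_vec(y)
  sp <- union(names(xv), names(yv))
  rbind(
    x = setNames(ifelse(is.na(xv[sp]), 0, xv[sp]), sp),
    y = setNames(ifelse(is.na(yv[sp]), 0, yv[sp]), sp)
  )
}

#' Dissimilarity between two abundance profiles
#'
#' The four distances used for partial-versus-full-length profile
#' comparison, computed over the union of species (absent species count as
#' zero): Bray-Curtis `sum|x-y| / sum(x+y)`; Euclidean `sqrt(sum (x-y)^2)`;
#' Jaccard in its abundance-weighted (Bray-derived) form `2B/(1+B)`; and
#' quantitative Kulczynski `1 - (sum min / sum x + sum min / sum y) / 2`.
#' Computation is delegated to [vegan::vegdist()], whose definitions these
#' are.
#'
#' @param x,y Profiles: long tibbles with `species`/`abundance` columns, or
#'   named numeric vectors.
#' @param metric One of `"bray-curtis"`, `"euclidean"`, `"jaccard"`,
#'   `"kulczynski"`.
#' @param binary Use presence/absence instead of abundances (for the binary
#'   Jaccard variant).
#' @return A single non-negative dissimilarity; 0 for identical profiles,
#'   and at most 1 for the three bounded metrics on relative abundances.
#' @export
dissimilarity <- function(x, y, metric = c("bray-curtis", "euclidean",
                                           "jaccard", "kulczynski"),
                          binary = FALSE) {
  metric <- match.arg(metric)
  m <- .align_profiles(x, y)
  if (any(rowSums(m) == 0)) {
    abort("dissimilarity undefined for an all-zero profile")
  }
  as.numeric(vegan::vegdist(m, method = .metric_vegan[[metric]],
                            binary = binary))
}

#' Pairwise dissimilarity matrix over samples
#'
#' @param profiles Long tibble: `sample_id`, `species`, `abundance`.
#' @param metric As in [dissimilarity()].
#' @return A `dist` object over the samples.
#' @export
dissimilarity_matrix <- function(profiles, metric = "bray-curtis") {
  metric <- match.arg(metric, names(.metric_vegan))
  wide <- profiles |>
    select("sample_id", "species", "abundance") |>
    pivot_wider(names_from = "species", values_from = "abundance",
                values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  if (any(rowSums(m) == 0)) {
    abort("dissimilarity undefined for an all-zero profile")
  }
  vegan::vegdist(m, method = .metric_vegan[[metric]])
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: the squared distance matrix is double-centered
#' and eigendecomposed; axes with positive eigenvalues are kept, sorted by
#' decreasing eigenvalue. Negative eigenvalues are reported, not corrected.
#' Axis signs are fixed deterministically by making each axis's
#' largest-magnitude coordinate positive.
#'
#' @param d A `dist`, or a square symmetric non-negative matrix with zero
#'   diagonal.
#' @return An `amplibench_pcoa` object: list with `coordinates` (tibble,
#'   `sample` + `Axis1..AxisK`), `eigenvalues` (all, descending) and
#'   `proportion_explained` (positive eigenvalues over their sum).
#' @export
pcoa <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m)) abort("distance matrix must be square")
    if (max(abs(m - t(m))) > 1e-8) abort("distance matrix must be symmetric")
    if (any(diag(m) != 0)) abort("distance matrix must have a zero diagonal")
    if (any(m < 0)) abort("distances must be non-negative")
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive; we keep the
  # positive axes ourselves, so ask for all and silence that advisory
  sc <- suppressWarnings(cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- sc$eig
  tol <- 1e-8 * max(abs(eig), 1)
  pos <- which(eig > tol)
  coords <- sc$points[, pos, drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  samples <- attr(d, "Labels") %||% as.character(seq_len(n))
  structure(
    list(
      coordinates = bind_cols(tibble(sample = samples), as_tibble(coords)),
      eigenvalues = sort(eig, decreasing = TRUE),
      proportion_explained = eig[pos] / sum(eig[pos])
    ),
    class = "amplibench_pcoa"
  )
}

#' @export
print.amplibench_pcoa <- function(x, ...) {
  cat("<pcoa> ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates) - 1L, " positive axes; Axis1 explains ",
      round(100 * x$proportion_explained[1], 1), "%\n", sep = "")
  invisible(x)
}

#' @describeIn pcoa Coordinates in long form.
#' @param x An `amplibench_pcoa`.
#' @param ... Unused.
#' @export
tidy.amplibench_pcoa <- function(x, ...) {
  pivot_longer(x$coordinates, -"sample", names_to = "axis",
               values_to = "coordinate")
}

#' @describeIn pcoa One-row summary.
#' @export
glance.amplibench_pcoa <- function(x, ...) {
  tibble(
    n_samples = nrow(x$coordinates),
    n_axes = ncol(x$coordinates) - 1L,
    n_negative_eigenvalues = sum(x$eigenvalues < 0),
    prop_axis1 = x$proportion_explained[1]
  )
}

#' Call STI positivity from an abundance profile
#'
#' A pathogen is called positive in a sample when its relative abundance is
#' greater than or equal to `threshold` (default 0.1%); an absent species is
#' negative.
#'
#' @param profile Profile tibble (`species`, `abundance`) for one sample.
#' @param pathogens Character vector of pathogen species names.
#' @param threshold Positivity threshold in (0, 1); default `0.001`.
#' @return Tibble: `species`, `abundance`, `positive` (logical).
#' @export
sti_positivity <- function(profile, pathogens, threshold = 0.001) {
  stopifnot(threshold > 0, threshold < 1)
  ab <- setNames(profile$abundance, tolower(profile$species))
  found <- ab[tolower(pathogens)]
  found[is.na(found)] <- 0
  tibble(
    species = pathogens,
    abundance = unname(found),
    positive = unname(found) >= threshold
  )
}

#' Confusion-matrix concordance metrics
#'
#' The seven metrics used to validate sequencing-based pathogen calls
#' against PCR: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)`, recall (= sensitivity),
#' F1 `2*precision*recall/(precision+recall)`,
#' accuracy `(TP+TN)/total`, and Cohen's kappa `(accuracy - Pe)/(1 - Pe)`
#' with expected agreement
#' `Pe = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / total^2`.
#' Cells with a zero denominator yield `NaN` with a warning.
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts; the total must be
#'   positive.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `precision`, `recall`, `f1`, `accuracy`, `kappa`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) abort("confusion matrix is all zero")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined (zero denominator); returning NaN"))
      return(NaN)
    }
    num / den
  }
  sensitivity <- safe_div(tp, tp + fn, "sensitivity")
  specificity <- safe_div(tn, tn + fp, "specificity")
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- sensitivity
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  accuracy <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- safe_div(accuracy - pe, 1 - pe, "kappa")
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sensitivity, specificity = specificity,
    precision = precision, recall = recall, f1 = f1,
    accuracy = accuracy, kappa = kappa
  )
}

#' Validate sequencing-based pathogen calls against PCR results
#'
#' Applies the abundance positivity rule per sample and pathogen, builds
#' the confusion matrix against the PCR reference per pathogen, and returns
#' the concordance metrics.
#'
#' @param profiles Long profile tibble: `sample_id`, `species`,
#'   `abundance`.
#' @param pcr Tibble: `sample_id`, `species`, `result` (`"pos"`/`"neg"`).
#' @param threshold Positivity threshold, default 0.001.
#' @return Tibble with one row per pathogen: the pathogen name plus the
#'   [confusion_metrics()] columns.
#' @export
validate_sti <- function(profiles, pcr, threshold = 0.001) {
  stopifnot(all(pcr$result %in% c("pos", "neg")))
  # absent species = abundance zero
  calls <- pcr |>
    mutate(sp_key = tolower(.data$species)) |>
    left_join(
      profiles |>
        mutate(sp_key = tolower(.data$species)) |>
        select("sample_id", "sp_key", "abundance"),
      by = c("sample_id", "sp_key")
    ) |>
    mutate(
      abundance = ifelse(is.na(.data$abundance), 0, .data$abundance),
      predicted = .data$abundance >= threshold,
      reference = .data$result == "pos"
    )
  calls |>
    group_by(.data$species) |>
    summarise(
      res = list(confusion_metrics(
        tp = sum(.data$predicted & .data$reference),
        fp = sum(.data$predicted & !.data$reference),
        tn = sum(!.data$predicted & !.data$reference),
        fn = sum(!.data$predicted & .data$reference)
      )),
      .groups = "drop"
    ) |>
    tidyr::unnest("res")
}
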