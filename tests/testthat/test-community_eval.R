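# Profiles, dissimilarities, PCoA and concordance metrics.

test_that("profiles normalize counts and pool unclassified mass", {
  res <- tibble::tibble(
    query_id = paste0("r", 1:100),
    species = c(rep("Aus bus", 80), rep("Cus dus", 20))
  )
  p <- profile_from_classifications(res, "s1")
  expect_equal(p$abundance[p$species == "Aus bus"], 0.8)
  expect_equal(p$abundance[p$species == "Cus dus"], 0.2)
  expect_equal(sum(p$abundance), 1)

  all_na <- tibble::tibble(query_id = "r1", species = NA_character_)
  p2 <- profile_from_classifications(all_na, "s1")
  expect_equal(p2$species, "unclassified")
  expect_equal(p2$abundance, 1)

  mixed <- tibble::tibble(query_id = paste0("r", 1:10),
                          species = c(rep("Aus bus", 7), rep(NA, 3)))
  expect_equal(sum(profile_from_classifications(mixed, "s")$abundance), 1)
  expect_error(profile_from_classifications(mixed[0, ], "s"), "no classification")
})

test_that("the four dissimilarities match their closed forms", {
  x <- c(a = 0.8, b = 0.2, c = 0)
  y <- c(a = 0.4, b = 0.4, c = 0.2)
  expect_equal(dissimilarity(x, y, "bray-curtis"), 0.4)
  expect_equal(dissimilarity(x, y, "kulczynski"), 0.4)
  expect_equal(dissimilarity(x, y, "jaccard"), 2 * 0.4 / 1.4)
  expect_equal(dissimilarity(x, y, "euclidean"), sqrt(0.24))
  # identity and disjoint support
  for (m in c("bray-curtis", "euclidean", "jaccard", "kulczynski")) {
    expect_equal(dissimilarity(x, x, m), 0, label = m)
  }
  d1 <- c(a = 0.5, b = 0.5)
  d2 <- c(c = 0.3, d = 0.7)
  for (m in c("bray-curtis", "jaccard", "kulczynski")) {
    expect_equal(dissimilarity(d1, d2, m), 1, label = m)
  }
  expect_error(dissimilarity(c(a = 0), c(a = 1), "bray-curtis"), "all-zero")
})

test_that("dissimilarities are symmetric, bounded and vanish only at identity", {
  withr::local_seed(41)
  bray_hand <- function(x, y) sum(abs(x - y)) / sum(x + y)
  kul_hand <- function(x, y) {
    1 - (sum(pmin(x, y)) / sum(x) + sum(pmin(x, y)) / sum(y)) / 2
  }
  for (i in 1:25) {
    x <- stats::runif(6); x <- setNames(x / sum(x), letters[1:6])
    y <- stats::runif(6); y <- setNames(y / sum(y), letters[1:6])
    for (m in c("bray-curtis", "jaccard", "kulczynski")) {
      dxy <- dissimilarity(x, y, m)
      expect_equal(dxy, dissimilarity(y, x, m))
      expect_gte(dxy, 0)
      expect_lte(dxy, 1)
    }
    # vegan-backed values equal the stated formulas
    expect_equal(dissimilarity(x, y, "bray-curtis"), bray_hand(x, y))
    expect_equal(dissimilarity(x, y, "kulczynski"), kul_hand(x, y))
    b <- bray_hand(x, y)
    expect_equal(dissimilarity(x, y, "jaccard"), 2 * b / (1 + b))
    expect_equal(dissimilarity(x, y, "euclidean"),
                 sqrt(sum((x - y)^2)))
  }
})

test_that("profiles align on the union of species", {
  x <- tibble::tibble(sample_id = "a", species = c("s1", "s2"),
                      abundance = c(0.8, 0.2))
  y <- tibble::tibble(sample_id = "b", species = c("s2", "s3"),
                      abundance = c(0.5, 0.5))
  # union alignment: |0.8-0| + |0.2-0.5| + |0-0.5| over 2
  expect_equal(dissimilarity(x, y, "bray-curtis"), 1.6 / 2)
})

test_that("pcoa reproduces Euclidean geometry", {
  # three collinear points: first axis recovers spacing, one positive axis
  d <- stats::dist(matrix(c(0, 1, 2), ncol = 1))
  p <- pcoa(d)
  expect_equal(ncol(p$coordinates) - 1L, 1L)
  expect_equal(stats::dist(p$coordinates$Axis1), d, ignore_attr = TRUE)
  expect_equal(sum(p$eigenvalues > 1e-8), 1)

  # two samples: one axis, coordinate difference equals the distance
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2))
  p2 <- pcoa(d2)
  expect_equal(abs(diff(p2$coordinates$Axis1)), 3)

  withr::local_seed(42)
  for (i in 1:5) {
    pts <- matrix(stats::rnorm(8 * 3), 8, 3)
    dd <- stats::dist(pts)
    pp <- pcoa(dd)
    rec <- stats::dist(as.matrix(pp$coordinates[, -1]))
    expect_equal(as.numeric(rec), as.numeric(dd), tolerance = 1e-8)
    # axis-sign convention: largest-magnitude loading positive
    for (j in 2:ncol(pp$coordinates)) {
      v <- pp$coordinates[[j]]
      expect_gte(v[which.max(abs(v))], 0)
    }
  }
})

test_that("pcoa agrees with the ape implementation up to sign", {
  withr::local_seed(43)
  pts <- matrix(stats::rnorm(7 * 2), 7, 2)
  d <- stats::dist(pts)
  ours <- pcoa(d)
  ref <- ape::pcoa(d)
  k <- min(ncol(ref$vectors), ncol(ours$coordinates) - 1L)
  for (j in seq_len(k)) {
    a <- ours$coordinates[[j + 1L]]
    b <- ref$vectors[, j]
    expect_equal(abs(a), unname(abs(b)), tolerance = 1e-8)
  }
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("sti positivity uses an inclusive 0.1% threshold", {
  prof <- tibble::tibble(
    sample_id = "s", species = c("Ureaplasma parvum", "Mycoplasma hominis"),
    abundance = c(0.0010, 0.000999)
  )
  res <- sti_positivity(prof, c("Ureaplasma parvum", "Mycoplasma hominis",
                                "Neisseria gonorrhoeae"))
  expect_equal(res$positive, c(TRUE, FALSE, FALSE))
  expect_equal(res$abundance[3], 0) # absent species is negative
})

test_that("confusion metrics match the hand-worked case", {
  m <- confusion_metrics(tp = 40, fp = 10, tn = 45, fn = 5)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$kappa, 0.7) # Pe = 0.5
  expect_equal(m$sensitivity, 8 / 9)
  expect_equal(m$recall, m$sensitivity)
  expect_equal(m$precision, 0.8)
  expect_equal(m$f1, 16 / 19)
  expect_equal(m$specificity, 45 / 55)
})

test_that("degenerate confusion matrices yield NaN sentinels or errors", {
  w <- capture_warnings(m <- confusion_metrics(10, 0, 0, 0))
  expect_true(any(grepl("kappa", w)))
  expect_true(any(grepl("specificity", w)))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$accuracy, 1)
  expect_true(is.nan(m$kappa)) # Pe = 1
  m2 <- confusion_metrics(50, 0, 50, 0)
  expect_equal(m2$kappa, 1)
  expect_error(confusion_metrics(0, 0, 0, 0), "all zero")
})

test_that("F1 is the harmonic mean of precision and recall", {
  withr::local_seed(44)
  for (i in 1:25) {
    cm <- sample(1:40, 4, replace = TRUE)
    m <- confusion_metrics(cm[1], cm[2], cm[3], cm[4])
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
  }
})

test_that("metrics agree with caret as an independent implementation", {
  withr::local_seed(45)
  for (i in 1:20) {
    cm <- sample(1:30, 4, replace = TRUE) # tp fp tn fn, all margins > 0
    m <- confusion_metrics(cm[1], cm[2], cm[3], cm[4])
    pred <- factor(c(rep("pos", cm[1] + cm[2]), rep("neg", cm[3] + cm[4])),
                   levels = c("pos", "neg"))
    ref <- factor(c(rep("pos", cm[1]), rep("neg", cm[2]),
                    rep("neg", cm[3]), rep("pos", cm[4])),
                  levels = c("pos", "neg"))
    cc <- caret::confusionMatrix(pred, ref, positive = "pos")
    expect_equal(m$accuracy, unname(cc$overall["Accuracy"]))
    expect_equal(m$kappa, unname(cc$overall["Kappa"]))
    expect_equal(m$sensitivity, unname(cc$byClass["Sensitivity"]))
    expect_equal(m$specificity, unname(cc$byClass["Specificity"]))
    expect_equal(m$precision, unname(cc$byClass["Precision"]))
    expect_equal(m$f1, unname(cc$byClass["F1"]))
  }
})

test_that("validate_sti builds per-pathogen confusion matrices", {
  profiles <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3", "s4"), each = 1),
    species = "Ureaplasma parvum",
    abundance = c(0.01, 0.0005, 0.002, 0)
  )
  pcr <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3", "s4"), 1),
    species = "Ureaplasma parvum",
    result = c("pos", "pos", "neg", "neg")
  )
  v <- validate_sti(profiles, pcr)
  expect_equal(v$tp, 1)
  expect_equal(v$fn, 1)
  expect_equal(v$fp, 1)
  expect_equal(v$tn, 1)
  expect_equal(v$accuracy, 0.5)
})
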