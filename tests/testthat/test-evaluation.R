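test_that("accuracy counts exact matches and never credits missing predictions", {
  expect_equal(predictionAccuracy(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(predictionAccuracy(c("a", "b"), c("a", NA)), 0.5)
  expect_equal(predictionAccuracy(c(NA, "b"), c("x", "b")), 0.5)
  expect_error(predictionAccuracy("a", c("a", "b")), "equal length")
  expect_error(predictionAccuracy(character(0), character(0)), "zero")
})

test_that("accuracy of random predictions concentrates at 1/k", {
  set.seed(601)
  k <- 8
  n <- 1e4
  truth <- sample(letters[1:k], n, replace = TRUE)
  pred <- sample(letters[1:k], n, replace = TRUE)
  p <- 1 / k
  expect_lt(abs(predictionAccuracy(truth, pred) - p),
            3 * sqrt(p * (1 - p) / n))
})

test_that("macro metrics match hand-computed and confusion-matrix oracles", {
  expect_equal(unname(macroMetrics(c("a", "b"), c("a", "b"))), c(1, 1, 1))
  # hand-computed: each class has TP=1, FP=1, FN=1
  mm <- macroMetrics(c("a", "a", "b", "b"), c("a", "b", "a", "b"))
  expect_equal(unname(mm), c(0.5, 0.5, 0.5))
  # a truth class that is never predicted contributes zero precision
  mm0 <- macroMetrics(c("a", "b"), c("a", "a"))
  expect_equal(mm0[["macroPrecision"]], 0.25)  # mean(1/2, 0)
  expect_equal(mm0[["macroRecall"]], 0.5)      # mean(1, 0)
  set.seed(602)
  for (rep in 1:30) {
    k <- sample(2:6, 1)
    n <- sample(20:200, 1)
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(c(letters[1:(k + 1)], NA), n, replace = TRUE)
    expect_equal(macroMetrics(truth, pred), oracleMacro(truth, pred))
  }
})

test_that("leave-one-out uses twins, excludes self, and respects the strict bound", {
  # every node has a Jaccard-1 twin carrying the same single label; full
  # purity makes every same-clique vote agree with the twin's label
  base <- generateFixture(nProteins = 30, multiLabelRate = 0,
                          incompleteRate = 0, classPurity = 1, seed = 61)
  twins <- annotationRows(paste0(base$accession, "t"),
                          as.list(base$domains), as.list(base$ec))
  rows <- rbind(base, twins)
  g <- buildGraph(rows)
  rep1 <- evaluateLOO(g, rows, minSim = 0, maxSim = 1)
  expect_equal(annotationCoverage(rep1), 1)
  expect_equal(perLevelMetrics(rep1)$accuracy, rep(1, 4))
  # strict upper bound: twins with identical compositions stop voting;
  # remaining same-clique neighbors still cover most queries but the
  # direct-mapping shortcut is gone
  repS <- evaluateLOO(g, rows, minSim = 0, maxSim = 1, strictMax = TRUE)
  expect_lte(annotationCoverage(repS), 1)
  # isolated twins only: with no other overlap, strict mode kills coverage
  iso <- annotationRows(c("A", "At"), list(c("u1", "u2"), c("u1", "u2")),
                        list("1.1.1.1", "1.1.1.1"))
  gIso <- buildGraph(iso)
  expect_equal(annotationCoverage(
    evaluateLOO(gIso, iso, minSim = 0, maxSim = 1, strictMax = TRUE)), 0)
  expect_equal(annotationCoverage(
    evaluateLOO(gIso, iso, minSim = 0, maxSim = 1)), 1)
})

test_that("evaluation validates ground truth and multi-EC handling", {
  rows <- annotationRows(c("A", "B"), list("d1", "d1"),
                         list(character(0), "1.1.1.1"))
  g <- buildGraph(rows)
  expect_error(evaluateLOO(g, rows), "no ground-truth")
  multi <- annotationRows(c("A", "B", "C"),
                          list(c("m1", "m2"), c("m1", "m2"), c("m1", "m2")),
                          list(c("1.1.1.1", "2.1.1.1"), "1.1.1.1", "1.1.1.1"))
  gm <- buildGraph(multi)
  excl <- evaluateLOO(gm, multi, minSim = 0)
  expect_equal(evaluationCounts(excl)[["total"]], 2L)  # A dropped
  incl <- evaluateLOO(gm, multi, minSim = 0, multiEC = "any")
  expect_equal(evaluationCounts(incl)[["total"]], 3L)
  # A's prediction 1.1.1.1 matches one of its two truths
  expect_equal(perLevelMetrics(incl)$accuracy, rep(1, 4))
})

test_that("level-wise accuracy is monotone for fully resolved labels", {
  rows <- generateFixture(nProteins = 150, incompleteRate = 0,
                          multiLabelRate = 0, classPurity = 0.7, seed = 62)
  g <- buildGraph(rows)
  rep1 <- evaluateLOO(g, rows, minSim = 0.05)
  acc <- perLevelMetrics(rep1)$accuracy
  expect_true(all(diff(acc) <= 1e-12))
  # prefix-match arithmetic: a level-4 miss can still be a level-3 hit
  truth <- c("1.1.1.1", "1.1.2.3")
  pred <- c("1.1.1.2", "1.1.2.3")
  byLevel <- vapply(1:4, function(lv)
    predictionAccuracy(ecTruncate(truth, lv), ecTruncate(pred, lv)),
    numeric(1))
  expect_equal(byLevel, c(1, 1, 1, 0.5))
})

test_that("threshold sweep emits the full grid with monotone coverage", {
  rows <- generateFixture(nProteins = 120, seed = 63)
  g <- buildGraph(rows)
  tab <- thresholdSweep(g, rows)
  expect_equal(nrow(tab), 10 * 2 * 4)  # 10 thresholds x 2 modes x 4 levels
  expect_length(attr(tab, "reports"), 20L)
  for (mode in c("inclusive", "strict")) {
    cov <- tab[tab$maxSimMode == mode & tab$level == 1, ]
    cov <- cov[order(cov$minSim), "coverage"]
    expect_true(all(diff(cov) <= 1e-12))
  }
  # one cell equals a direct leave-one-out call
  direct <- evaluateLOO(g, rows, minSim = 0.1, maxSim = 1)
  cell <- tab[tab$minSim == 0.1 & tab$maxSimMode == "inclusive", ]
  expect_equal(cell$accuracy, perLevelMetrics(direct)$accuracy)
  expect_equal(unique(cell$coverage), annotationCoverage(direct))
})

test_that("stratified k-fold cross-validation is valid, separable-exact and order-invariant", {
  # perfectly separable: the two classes share no domains
  sep <- generateFixture(nProteins = 60, nDomains = 40, nClasses = 2,
                         classPurity = 1, multiLabelRate = 0,
                         incompleteRate = 0, singleDomainRate = 0,
                         domainsPerProtein = c(2, 4), seed = 64,
                         labelFormat = "class")
  res <- evaluateKFoldBinary(sep, k = 5, seed = 9, minSims = 0.05)
  expect_equal(res$accuracy, 1)
  expect_gt(res$coverage, 0.8)
  # permutation of input rows leaves the result unchanged for a fixed seed
  perm <- sep[withr::with_seed(10, sample.int(nrow(sep))), , drop = FALSE]
  resPerm <- evaluateKFoldBinary(perm, k = 5, seed = 9, minSims = 0.05)
  expect_equal(resPerm, res)
  # parameter validation
  expect_error(evaluateKFoldBinary(sep, k = 5, minSims = 0.05), "seed")
  bad <- generateFixture(nProteins = 30, nClasses = 3, seed = 65,
                         incompleteRate = 0, multiLabelRate = 0,
                         labelFormat = "class")
  expect_error(evaluateKFoldBinary(bad, k = 5, seed = 1),
               "two label values")
  # a 2x2 fixture: folds computable by hand
  tiny <- annotationRows(c("A", "B", "C", "D"),
                         list(c("e1", "e2"), c("e1", "e2"),
                              c("n1", "n2"), c("n1", "n2")),
                         list("enzyme", "enzyme",
                              "non-enzyme", "non-enzyme"))
  tinyRes <- evaluateKFoldBinary(tiny, k = 2, seed = 3, minSims = 0)
  expect_equal(tinyRes$accuracy, 1)  # each held-out twin maps to its pair
  expect_equal(tinyRes$coverage, 1)
})
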