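test_that("Jaccard and shared-domain counts reproduce the worked example", {
  P1 <- c("d1", "d2", "d3", "d4")
  P2 <- c("d1", "d3", "d5")
  P5 <- c("d4", "d1", "d10", "d40", "d7", "d9", "d12", "d52", "d100")
  expect_equal(sharedDomainCount(P1, P2), 2L)
  expect_equal(sharedDomainCount(P1, P5), 2L)
  expect_equal(jaccardSimilarity(P1, P2), 0.4)
  expect_equal(jaccardSimilarity(P1, P5), 2 / 11)
  expect_equal(jaccardSimilarity(P1, P1), 1)
  expect_equal(jaccardSimilarity(P1, c("x1", "x2")), 0)
  expect_equal(sharedDomainCount(P1, c("x1")), 0L)
  expect_error(jaccardSimilarity(character(0), P1), "non-empty")
})

test_that("jaccard is a symmetric bounded similarity and 1-jaccard a metric", {
  set.seed(401)
  vocab <- sprintf("v%02d", 1:20)
  for (i in 1:50) {
    a <- sample(vocab, sample.int(8, 1))
    b <- sample(vocab, sample.int(8, 1))
    c_ <- sample(vocab, sample.int(8, 1))
    ab <- jaccardSimilarity(a, b)
    expect_equal(ab, jaccardSimilarity(b, a))
    expect_gte(ab, 0); expect_lte(ab, 1)
    expect_equal(ab == 1, setequal(a, b))
    # triangle inequality of the Jaccard distance
    expect_lte(1 - jaccardSimilarity(a, c_),
               (1 - ab) + (1 - jaccardSimilarity(b, c_)) + 1e-12)
  }
})

test_that("graph construction populates the exact inverted index", {
  g <- buildGraph(exampleProteins())
  expect_equal(length(g), 5L)
  expect_equal(sort(accessions(g)[g@index[["d1"]]]),
               c("P1", "P2", "P3", "P4", "P5"))
  expect_equal(sort(accessions(g)[g@index[["d5"]]]), c("P2", "P4"))
  expect_true(validObject(g))
  expect_equal(length(buildGraph(annotationRows(character(0), list()))), 0L)
  one <- buildGraph(annotationRows("A", list("d1")))
  expect_equal(nrow(findNeighbors(one, "d9")), 0L)
  expect_error(buildGraph(annotationRows(c("A", "A"), list("d1", "d2"))),
               "duplicate")
})

test_that("neighbor queries reproduce the worked example thresholds", {
  g <- buildGraph(exampleProteins())
  q <- c("d5", "d6", "d101")
  nb <- findNeighbors(g, q, minSim = 0, maxSim = 1)
  expect_equal(nb$accession, c("P4", "P2"))
  expect_equal(nb$weight, c(0.5, 0.2))
  expect_equal(findNeighbors(g, q, minSim = 0.3)$accession, "P4")
  # identical-composition exclusion under the strict upper bound
  twin <- rbind(exampleProteins(),
                annotationRows("P9", list(c("d5", "d6", "d101"))))
  g2 <- buildGraph(twin)
  incl <- findNeighbors(g2, q, minSim = 0, maxSim = 1)
  expect_true("P9" %in% incl$accession)
  strict <- findNeighbors(g2, q, minSim = 0, maxSim = 1, strictMax = TRUE)
  expect_false("P9" %in% strict$accession)
  expect_error(findNeighbors(g, q, minSim = 0.5, maxSim = 0.2), "minSim")
  expect_error(findNeighbors(g, character(0)), "empty")
})

test_that("inverted-index search equals the brute-force pairwise scan", {
  set.seed(402)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    rows <- randomRows(n, nDomains = sample(10:40, 1))
    g <- buildGraph(rows)
    for (j in 1:3) {
      q <- rows$domains[[sample.int(n, 1)]]
      minSim <- sample(c(0, 0.1, 0.3, 0.5), 1)
      strict <- sample(c(TRUE, FALSE), 1)
      excl <- sample(rows$accession, sample.int(3, 1))
      got <- findNeighbors(g, q, minSim = minSim, maxSim = 1,
                           strictMax = strict, exclude = excl)
      want <- bruteNeighbors(rows, q, minSim = minSim, maxSim = 1,
                             strictMax = strict, exclude = excl)
      expect_equal(got$accession, want$accession)
      expect_equal(got$weight, want$weight)
      expect_true(all(got$weight > 0))
    }
  }
})

test_that("neighbor counts shrink monotonically as minSim grows", {
  set.seed(403)
  rows <- randomRows(80)
  g <- buildGraph(rows)
  for (j in 1:5) {
    q <- rows$domains[[sample.int(80, 1)]]
    sizes <- vapply(seq(0, 1, by = 0.1), function(ms)
      nrow(findNeighbors(g, q, minSim = ms)), numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("edge export agrees with pairwise weights and writes both formats", {
  rows <- exampleProteins()
  g <- buildGraph(rows)
  edges <- exportEdges(g, cutoff = 0)
  # every exported edge weight matches a direct pairwise computation
  for (i in seq_len(nrow(edges))) {
    a <- rows$domains[[match(edges$source[[i]], rows$accession)]]
    b <- rows$domains[[match(edges$target[[i]], rows$accession)]]
    expect_equal(edges$weight[[i]], jaccardSimilarity(a, b))
  }
  # symmetric brute-force count of above-cutoff pairs
  cnt <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    w <- jaccardSimilarity(rows$domains[[i]], rows$domains[[j]])
    if (w > 0) cnt <- cnt + 1
  }
  expect_equal(nrow(edges), cnt)
  hi <- exportEdges(g, cutoff = 0.4)
  expect_true(all(hi$weight >= 0.4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportEdges(g, tsv, cutoff = 0)
  expect_equal(nrow(utils::read.delim(tsv)), nrow(edges))
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportEdges(g, gml, cutoff = 0, format = "graphml")
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), 5)
  expect_equal(igraph::gsize(ig), nrow(edges))
})
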