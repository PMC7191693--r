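#' Classification accuracy with missing predictions
#'
#' Plain multi-class accuracy \eqn{\frac{1}{N}\sum_i 1(y_i = y'_i)}. A
#' missing prediction (\code{NA}) never matches, and neither does an
#' undefined truth marker (an EC code not resolved at the scored level).
#'
#' @param truth,predicted equal-length character vectors; \code{NA} allowed.
#' @return fraction of exact matches in [0, 1].
#' @export
predictionAccuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (length(truth) == 0L) stop("cannot compute accuracy of zero cases")
  mean(!is.na(truth) & !is.na(predicted) & truth == predicted)
}

#' Macro-averaged precision, recall and F1
#'
#' The class set is the set of distinct labels present in the ground truth
#' of the evaluated set. For each class \eqn{l}: precision
#' \eqn{TP/(TP+FP)}, recall \eqn{TP/(TP+FN)}, F1 \eqn{2PR/(P+R)}; the macro
#' score is the unweighted mean over classes. A class that is never
#' predicted contributes precision 0 (and hence F1 0) rather than an
#' undefined division. Predictions of labels absent from the truth add
#' false positives to no tracked class and therefore only affect the
#' classes they were predicted instead of.
#'
#' @param truth,predicted equal-length character vectors; \code{NA} in
#'   \code{predicted} denotes no prediction.
#' @return named numeric vector \code{c(macroPrecision, macroRecall,
#'   macroF1)}.
#' @export
macroMetrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (length(truth) == 0L) stop("cannot compute metrics of zero cases")
  classes <- sort(unique(truth[!is.na(truth)]))
  if (length(classes) == 0L)
    return(c(macroPrecision = 0, macroRecall = 0, macroF1 = 0))
  prec <- rec <- f1 <- numeric(length(classes))
  for (j in seq_along(classes)) {
    l <- classes[[j]]
    isT <- !is.na(truth) & truth == l
    isP <- !is.na(predicted) & predicted == l
    tp <- sum(isT & isP)
    fp <- sum(!isT & isP)
    fn <- sum(isT & !isP)
    prec[[j]] <- if (tp + fp > 0L) tp / (tp + fp) else 0
    rec[[j]]  <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1[[j]]   <- if (prec[[j]] + rec[[j]] > 0)
      2 * prec[[j]] * rec[[j]] / (prec[[j]] + rec[[j]]) else 0
  }
  c(macroPrecision = mean(prec), macroRecall = mean(rec), macroF1 = mean(f1))
}

# top-1 predictions for a test table under leave-one-out exclusion
.looPredictions <- function(graph, test, minSim, maxSim, strictMax) {
  res <- annotateBatch(graph, test, minSim = minSim, maxSim = maxSim,
                       strictMax = strictMax, topK = 1)
  vapply(res, topLabel, character(1))
}

#' Leave-one-out evaluation of EC annotation
#'
#' Annotates every test protein against the graph with its own accession
#' excluded from the neighbor pool (so a protein present in the graph never
#' maps directly to itself), takes the top-ranked label, and scores it at
#' EC levels 1--4 after truncating both truth and prediction to each level.
#' Coverage is M/T, where T is the number of evaluated proteins and M the
#' number with at least one predicted label. By default accuracy and the
#' macro metrics are computed over the covered proteins only, so accuracy
#' reflects the quality of the predictions actually made while coverage
#' reports how many were made; \code{coveredOnly = FALSE} instead counts
#' every non-prediction as wrong.
#'
#' Test proteins annotated with more than one EC are excluded by default
#' (evaluation on single-EC proteins); with \code{multiEC = "any"} they are
#' kept and a prediction scores a hit when it matches any of the truths.
#' Ground-truth labels not resolved at a level truncate to the undefined
#' marker and can never be scored correct there.
#'
#' @param graph a \linkS4class{DomainGraph} (the training graph).
#' @param test annotation table with ground-truth EC labels.
#' @param minSim,maxSim,strictMax neighbor thresholds, see [findNeighbors()].
#' @param coveredOnly logical; compute metrics over covered proteins only
#'   (default) or over all test proteins.
#' @param multiEC \code{"exclude"} (default) or \code{"any"}.
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluateLOO <- function(graph, test, minSim = 0.3, maxSim = 1,
                        strictMax = FALSE, coveredOnly = TRUE,
                        multiEC = c("exclude", "any")) {
  multiEC <- match.arg(multiEC)
  if (any(lengths(test$ec) == 0L))
    stop("test protein ", test$accession[[which(lengths(test$ec) == 0L)[1]]],
         " has no ground-truth label")
  if (multiEC == "exclude")
    test <- test[lengths(test$ec) == 1L, , drop = FALSE]
  if (nrow(test) == 0L) stop("no evaluable test proteins")
  pred <- .looPredictions(graph, test, minSim, maxSim, strictMax)
  covered <- !is.na(pred)
  total <- nrow(test)
  M <- sum(covered)
  scope <- if (coveredOnly) covered else rep(TRUE, total)
  perLevel <- do.call(rbind, lapply(1:4, function(lv) {
    predLv <- ecTruncate(pred, lv)
    if (multiEC == "any") {
      # representative truth: the truth matching the prediction at this
      # level if one does, otherwise the alphabetically first truth
      truthLv <- vapply(seq_len(total), function(i) {
        tr <- ecTruncate(sort(test$ec[[i]]), lv)
        hit <- which(!is.na(tr) & !is.na(predLv[[i]]) & tr == predLv[[i]])
        if (length(hit)) tr[[hit[[1]]]] else tr[[1]]
      }, character(1))
    } else {
      truthLv <- ecTruncate(vapply(test$ec, `[[`, character(1), 1L), lv)
    }
    if (!any(scope)) {
      return(data.frame(level = lv, accuracy = NA_real_,
                        macroPrecision = NA_real_, macroRecall = NA_real_,
                        macroF1 = NA_real_))
    }
    acc <- predictionAccuracy(truthLv[scope], predLv[scope])
    mm <- macroMetrics(truthLv[scope], predLv[scope])
    data.frame(level = lv, accuracy = acc,
               macroPrecision = mm[["macroPrecision"]],
               macroRecall = mm[["macroRecall"]],
               macroF1 = mm[["macroF1"]])
  }))
  new("EvaluationReport",
      perLevel = perLevel,
      coverage = M / total,
      counts = c(total = as.integer(total), predicted = as.integer(M)),
      parameters = list(minSim = minSim, maxSim = maxSim,
                        strictMax = strictMax, topK = 1,
                        coveredOnly = coveredOnly, multiEC = multiEC))
}

#' Threshold sweep over minimum similarity and upper-bound mode
#'
#' Runs [evaluateLOO()] over a grid of minimum Jaccard similarity indices
#' (default 0.05--0.5, the range beyond which annotation coverage falls off
#' sharply) crossed with the two upper-bound modes: \code{"inclusive"}
#' (neighbors up to similarity 1 allowed) and \code{"strict"} (neighbors
#' with identical compositions excluded, weight < 1). Emits a long-format
#' table suitable for plotting accuracy/coverage curves.
#'
#' @param graph a \linkS4class{DomainGraph}.
#' @param test annotation table with ground truth.
#' @param minSims numeric vector of minimum similarities.
#' @param modes subset of \code{c("inclusive", "strict")}.
#' @param ... further arguments passed to [evaluateLOO()].
#' @return data.frame with one row per (minSim, mode, level) and columns
#'   \code{minSim}, \code{maxSimMode}, \code{level}, \code{accuracy},
#'   \code{macroPrecision}, \code{macroRecall}, \code{macroF1},
#'   \code{coverage}, \code{total}, \code{predicted}. The underlying
#'   \linkS4class{EvaluationReport} objects are attached as attribute
#'   \code{"reports"}.
#' @export
thresholdSweep <- function(graph, test,
                           minSims = seq(0.05, 0.5, by = 0.05),
                           modes = c("inclusive", "strict"), ...) {
  modes <- match.arg(modes, several.ok = TRUE)
  cells <- expand.grid(minSim = minSims, mode = modes,
                       stringsAsFactors = FALSE)
  reports <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    rep_i <- evaluateLOO(graph, test, minSim = cells$minSim[[i]],
                         maxSim = 1, strictMax = cells$mode[[i]] == "strict",
                         ...)
    reports[[i]] <- rep_i
    pl <- perLevelMetrics(rep_i)
    rows[[i]] <- data.frame(minSim = cells$minSim[[i]],
                            maxSimMode = cells$mode[[i]],
                            pl,
                            coverage = annotationCoverage(rep_i),
                            total = evaluationCounts(rep_i)[["total"]],
                            predicted = evaluationCounts(rep_i)[["predicted"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

# deterministic stratified fold assignment: the seeded shuffle is applied to
# the class-wise *sorted* accession list, so fold membership is invariant
# under permutation of the input rows
.stratifiedFolds <- function(accession, class, k, seed) {
  fold <- integer(length(accession))
  names(fold) <- accession
  withSeed(seed, {
    for (cl in sort(unique(class))) {
      accs <- sort(accession[class == cl])
      ids <- rep_len(seq_len(k), length(accs))
      fold[accs] <- sample(ids, length(ids))
    }
  })
  fold[accession]
}

#' Stratified k-fold cross-validation for binary classification
#'
#' The enzyme vs. non-enzyme protocol: records carry exactly one of two
#' label values; folds are stratified by class under an explicit seed; for
#' each fold the graph is built on the remaining k-1 folds, the held-out
#' fold is annotated by label propagation (top label only), and accuracy
#' (over covered queries), macro-precision/recall/F1 and coverage are
#' computed. Unweighted fold means are reported per minimum-similarity
#' threshold.
#'
#' @param rows annotation table; every row must have exactly one label, and
#'   exactly two label values must occur overall.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the stratified shuffle (mandatory).
#' @param minSims numeric vector of minimum similarity thresholds.
#' @param maxSim,strictMax upper-bound settings, see [findNeighbors()].
#' @return data.frame with one row per threshold: \code{minSim},
#'   \code{macroPrecision}, \code{macroRecall}, \code{macroF1},
#'   \code{accuracy}, \code{coverage}.
#' @export
evaluateKFoldBinary <- function(rows, k = 10, seed, minSims = 0.3,
                                maxSim = 1, strictMax = FALSE) {
  stopifnot(k >= 2)
  if (missing(seed)) stop("a seed is required for the stratified split")
  if (any(lengths(rows$ec) != 1L))
    stop("binary mode requires exactly one label per record")
  class <- vapply(rows$ec, `[[`, character(1), 1L)
  if (length(unique(class)) != 2L)
    stop("binary mode requires exactly two label values, got ",
         length(unique(class)))
  fold <- .stratifiedFolds(rows$accession, class, k, seed)
  for (f in seq_len(k)) {
    if (length(unique(class[fold == f])) < 2L)
      stop("fold ", f, " lacks one of the two classes; ",
           "use fewer folds or more data")
  }
  out <- lapply(minSims, function(ms) {
    per <- vapply(seq_len(k), function(f) {
      train <- rows[fold != f, , drop = FALSE]
      heldOut <- rows[fold == f, , drop = FALSE]
      g <- buildGraph(train)
      pred <- .looPredictions(g, heldOut, ms, maxSim, strictMax)
      truth <- class[fold == f]
      covered <- !is.na(pred)
      acc <- if (any(covered))
        predictionAccuracy(truth[covered], pred[covered]) else NA_real_
      mm <- if (any(covered))
        macroMetrics(truth[covered], pred[covered])
      else c(macroPrecision = NA_real_, macroRecall = NA_real_,
             macroF1 = NA_real_)
      c(mm, accuracy = acc, coverage = mean(covered))
    }, numeric(5))
    data.frame(minSim = ms,
               macroPrecision = mean(per["macroPrecision", ]),
               macroRecall = mean(per["macroRecall", ]),
               macroF1 = mean(per["macroF1", ]),
               accuracy = mean(per["accuracy", ]),
               coverage = mean(per["coverage", ]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
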