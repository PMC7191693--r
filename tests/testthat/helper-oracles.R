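# Independent oracles: brute-force implementations of neighbor search,
# propagation and macro metrics that share no code path with the package,
# used for equivalence checks on small random instances.

# exhaustive pairwise scan over all rows
bruteNeighbors <- function(rows, query, minSim = 0, maxSim = 1,
                           strictMax = FALSE, exclude = character(0)) {
  q <- unique(query)
  acc <- character(0); wt <- numeric(0)
  for (i in seq_len(nrow(rows))) {
    a <- rows$accession[[i]]
    if (a %in% exclude) next
    d <- rows$domains[[i]]
    w <- length(intersect(q, d)) / length(union(q, d))
    if (w <= 0 || w < minSim) next
    if (if (strictMax) w >= maxSim else w > maxSim) next
    acc <- c(acc, a); wt <- c(wt, w)
  }
  ord <- order(-wt, acc, method = "radix")
  data.frame(accession = acc[ord], weight = wt[ord],
             stringsAsFactors = FALSE)
}

# direct evaluation of the weighted-frequency formula over all labels
brutePropagate <- function(rows, query, minSim = 0, maxSim = 1,
                           strictMax = FALSE, exclude = character(0)) {
  nb <- bruteNeighbors(rows, query, minSim, maxSim, strictMax, exclude)
  if (nrow(nb) == 0L)
    return(data.frame(label = character(0), weight = numeric(0),
                      score = numeric(0)))
  total <- sum(nb$weight)
  labs <- unique(unlist(rows$ec[match(nb$accession, rows$accession)]))
  if (is.null(labs) || length(labs) == 0L)
    return(data.frame(label = character(0), weight = numeric(0),
                      score = numeric(0)))
  cum <- vapply(labs, function(l) {
    s <- 0
    for (j in seq_len(nrow(nb))) {
      carried <- rows$ec[[match(nb$accession[[j]], rows$accession)]]
      if (l %in% carried) s <- s + nb$weight[[j]]
    }
    s
  }, numeric(1))
  out <- data.frame(label = labs, weight = unname(cum),
                    score = unname(cum) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$label, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# macro metrics from a full cross-tabulated confusion matrix; a missing
# prediction is tabulated as the pseudo-label "<none>" so it contributes a
# false negative to its truth class
oracleMacro <- function(truth, predicted) {
  classes <- sort(unique(truth[!is.na(truth)]))
  truth <- ifelse(is.na(truth), "<none>", truth)
  predicted <- ifelse(is.na(predicted), "<none>", predicted)
  lv <- sort(unique(c(truth, predicted)))
  tab <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  p <- r <- f <- numeric(length(classes))
  for (j in seq_along(classes)) {
    l <- classes[[j]]
    tp <- tab[l, l]
    fp <- sum(tab[, l]) - tp
    fn <- sum(tab[l, ]) - tp
    p[[j]] <- if (tp + fp > 0) tp / (tp + fp) else 0
    r[[j]] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f[[j]] <- if (p[[j]] + r[[j]] > 0)
      2 * p[[j]] * r[[j]] / (p[[j]] + r[[j]]) else 0
  }
  c(macroPrecision = mean(p), macroRecall = mean(r), macroF1 = mean(f))
}

# random annotation table with uniform (non-clique) domain sharing,
# independent of generateFixture
randomRows <- function(n, nDomains = 30, maxSize = 6, nLabels = 4) {
  sizes <- sample.int(maxSize, n, replace = TRUE)
  domains <- lapply(sizes, function(s)
    sample(sprintf("r%03d", seq_len(nDomains)), s))
  ec <- lapply(seq_len(n), function(i)
    sprintf("L%d", sample.int(nLabels, sample.int(2, 1))))
  annotationRows(sprintf("R%04d", seq_len(n)), domains, ec)
}
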