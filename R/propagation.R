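#' Annotate a query composition by weighted label propagation
#'
#' Single-hop label propagation: the query's neighbors are retrieved from
#' the graph (see [findNeighbors()]), each neighbor casts its Jaccard edge
#' weight as a vote for every label it carries, and candidate labels are
#' ranked by cumulative weight
#' \deqn{w(i) = \sum_{v \in N(u)} W_{u,v}\,\delta(v, i),}
#' where \eqn{\delta(v, i)} is 1 when neighbor \eqn{v} carries label
#' \eqn{i}. The normalized score divides by the total neighbor weight
#' \eqn{\sum_{v \in N(u)} W_{u,v}} (the weighted frequency of the label),
#' which leaves the ranking unchanged since the denominator is constant per
#' query. A multi-label neighbor contributes its full edge weight to each of
#' its labels. If no neighbor passes the thresholds the ranking is empty —
#' the no-prediction case that reduces annotation coverage.
#'
#' Ties in cumulative weight are broken by ascending label string; a tie at
#' the top rank is additionally flagged in the result.
#'
#' @param graph a \linkS4class{DomainGraph}.
#' @param query character vector of domain signatures (non-empty).
#' @param minSim minimum Jaccard similarity for a neighbor to vote; the
#'   default 0.3 trades accuracy against coverage well in practice.
#' @param maxSim upper similarity bound (default 1, i.e. no exclusion).
#' @param strictMax logical; exclude neighbors at exactly \code{maxSim}
#'   (with \code{maxSim = 1}, drops identical-composition neighbors).
#' @param exclude accessions removed from the neighbor pool.
#' @param topK number of ranked labels to keep (\code{Inf} for all).
#' @param queryAccession optional accession recorded in the result.
#' @return a \linkS4class{PropagationResult}.
#' @examples
#' g <- buildGraph(exampleProteins())
#' propagate(g, c("d5", "d6", "d101"), minSim = 0)
#' @export
propagate <- function(graph, query, minSim = 0.3, maxSim = 1,
                      strictMax = FALSE, exclude = character(0),
                      topK = Inf, queryAccession = NA_character_) {
  nb <- findNeighbors(graph, query, minSim = minSim, maxSim = maxSim,
                      strictMax = strictMax, exclude = exclude)
  params <- list(minSim = minSim, maxSim = maxSim, strictMax = strictMax,
                 topK = topK)
  if (nrow(nb) == 0L) {
    return(new("PropagationResult", query = as.character(queryAccession),
               ranking = data.frame(label = character(0), weight = numeric(0),
                                    score = numeric(0)),
               neighbors = nb, parameters = params, tieAtTop = FALSE))
  }
  idx <- match(nb$accession, graph@accession)
  labs <- graph@labels[idx]
  nlab <- lengths(labs)
  total <- sum(nb$weight)
  votes <- data.frame(label = unlist(labs, use.names = FALSE),
                      weight = rep.int(nb$weight, nlab),
                      stringsAsFactors = FALSE)
  if (nrow(votes) == 0L) {
    ranked <- data.frame(label = character(0), weight = numeric(0),
                         score = numeric(0))
    tie <- FALSE
  } else {
    cum <- rowsum(votes$weight, votes$label)
    ranked <- data.frame(label = rownames(cum), weight = cum[, 1L],
                         stringsAsFactors = FALSE)
    ranked$score <- ranked$weight / total
    ord <- order(-ranked$weight, ranked$label, method = "radix")
    ranked <- ranked[ord, , drop = FALSE]
    rownames(ranked) <- NULL
    tie <- sum(ranked$weight >= ranked$weight[[1L]] - 1e-12) > 1L
    if (is.finite(topK) && nrow(ranked) > topK)
      ranked <- ranked[seq_len(topK), , drop = FALSE]
  }
  new("PropagationResult", query = as.character(queryAccession),
      ranking = ranked, neighbors = nb, parameters = params, tieAtTop = tie)
}

#' Annotate a batch of query proteins
#'
#' Driver over [propagate()], one result per query row in input order. Each
#' query's own accession is always added to the exclusion set, so a query
#' already present in the graph never votes for itself (the leave-one-out
#' discipline). Per-query errors are collected rather than fatal: a failed
#' query yields an empty result and the error messages are attached as the
#' \code{"errors"} attribute and summarized in a message.
#'
#' @param graph a \linkS4class{DomainGraph}.
#' @param queries annotation table of query proteins.
#' @param minSim,maxSim,strictMax,topK as in [propagate()]; \code{topK}
#'   defaults to 1 here (top-ranked annotation only).
#' @return list of \linkS4class{PropagationResult}, parallel to
#'   \code{queries}; failed queries carry empty rankings.
#' @export
annotateBatch <- function(graph, queries, minSim = 0.3, maxSim = 1,
                          strictMax = FALSE, topK = 1) {
  errors <- character(0)
  out <- lapply(seq_len(nrow(queries)), function(i) {
    acc <- queries$accession[[i]]
    tryCatch(
      propagate(graph, queries$domains[[i]], minSim = minSim,
                maxSim = maxSim, strictMax = strictMax,
                exclude = acc, topK = topK, queryAccession = acc),
      error = function(e) {
        errors[[acc]] <<- conditionMessage(e)
        new("PropagationResult", query = acc,
            ranking = data.frame(label = character(0),
                                 weight = numeric(0), score = numeric(0)),
            neighbors = data.frame(accession = character(0),
                                   weight = numeric(0)),
            parameters = list(minSim = minSim, maxSim = maxSim,
                              strictMax = strictMax, topK = topK),
            tieAtTop = FALSE)
      })
  })
  if (length(errors)) {
    message(length(errors), " of ", nrow(queries),
            " queries failed: ", paste(names(errors), collapse = ", "))
    attr(out, "errors") <- errors
  }
  out
}
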