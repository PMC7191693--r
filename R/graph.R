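#' Jaccard similarity of two domain compositions
#'
#' The link weight of the graph: \eqn{|A \cap B| / |A \cup B|} for the two
#' sets of domain signatures. A raw shared-domain count does not reflect the
#' relative strength of a relationship (two proteins sharing 2 of 5 domains
#' are closer than two sharing 2 of 11), which is why the ratio is used.
#' Inputs are de-duplicated; order never matters.
#'
#' @param a,b character vectors of domain signatures (non-empty).
#' @return similarity in [0, 1]; 1 iff the sets are equal, 0 iff disjoint.
#' @examples
#' jaccardSimilarity(c("d1", "d2", "d3", "d4"), c("d1", "d3", "d5")) # 0.4
#' @export
jaccardSimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("jaccardSimilarity requires non-empty domain sets")
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Number of shared domains between two compositions
#'
#' @param a,b character vectors of domain signatures.
#' @return \eqn{|A \cap B|}, a non-negative integer.
#' @examples
#' sharedDomainCount(c("d1", "d2", "d3", "d4"), c("d1", "d3", "d5")) # 2
#' @export
sharedDomainCount <- function(a, b) {
  length(intersect(unique(a), unique(b)))
}

#' Build a domain-composition similarity graph
#'
#' Every annotation row becomes one node; the inverted domain -> protein
#' index is populated; no edges are materialized (they are implied by shared
#' domains and computed on demand by [findNeighbors()]).
#'
#' @param rows annotation table as from [annotationRows()],
#'   [readAnnotationTable()] or [generateFixture()].
#' @return a \linkS4class{DomainGraph}.
#' @examples
#' g <- buildGraph(exampleProteins())
#' g
#' @export
buildGraph <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("accession", "domains") %in% names(rows)))
  acc <- as.character(rows$accession)
  dup <- acc[duplicated(acc)]
  if (length(dup)) stop("duplicate accession: ", dup[[1]])
  comp <- lapply(rows$domains, function(d) unique(as.character(d)))
  labs <- if ("ec" %in% names(rows)) {
    lapply(rows$ec, as.character)
  } else rep(list(character(0)), length(acc))
  n <- length(acc)
  ids <- rep.int(seq_len(n), lengths(comp))
  index <- split(ids, unlist(comp, use.names = FALSE))
  new("DomainGraph", accession = acc, composition = comp,
      labels = labs, index = index)
}

# candidate ids and Jaccard weights for a query composition, unfiltered
.candidateWeights <- function(graph, query) {
  q <- unique(as.character(query))
  hit <- graph@index[names(graph@index) %in% q]
  ids <- unlist(hit, use.names = FALSE)
  n <- length(graph@accession)
  if (length(ids) == 0L)
    return(list(id = integer(0), weight = numeric(0)))
  inter <- tabulate(ids, nbins = n)
  cand <- which(inter > 0L)
  sizes <- lengths(graph@composition)[cand]
  w <- inter[cand] / (sizes + length(q) - inter[cand])
  list(id = cand, weight = w)
}

#' Thresholded neighbor query against a domain graph
#'
#' Candidates are gathered through the inverted index (the union of index
#' entries over the query's domains), so only proteins sharing at least one
#' domain are ever touched; each candidate's weight is the Jaccard
#' similarity with the query composition. A candidate is retained iff
#' \code{weight >= minSim} and \code{weight <= maxSim} (or strictly
#' \code{< maxSim} when \code{strictMax = TRUE}; with \code{maxSim = 1} this
#' excludes exactly the neighbors with an identical composition). Results
#' are sorted by descending weight, ties broken by ascending accession, so
#' output is fully deterministic. Zero-overlap proteins are never neighbors.
#'
#' @param graph a \linkS4class{DomainGraph}.
#' @param query character vector of domain signatures (non-empty).
#' @param minSim,maxSim similarity bounds in [0, 1], \code{minSim <= maxSim}.
#' @param strictMax logical; use \code{weight < maxSim} for the upper bound,
#'   implementing the identical-composition exclusion mode.
#' @param exclude accessions to drop from the candidate pool (e.g. the query
#'   itself in leave-one-out validation).
#' @return data.frame with columns \code{accession}, \code{weight}.
#' @examples
#' g <- buildGraph(exampleProteins())
#' findNeighbors(g, c("d5", "d6", "d101"), minSim = 0, maxSim = 1)
#' @export
findNeighbors <- function(graph, query, minSim = 0, maxSim = 1,
                          strictMax = FALSE, exclude = character(0)) {
  q <- unique(trimws(as.character(query)))
  q <- q[nzchar(q)]
  if (length(q) == 0L) stop("query composition is empty")
  if (minSim > maxSim) stop("minSim must not exceed maxSim")
  cw <- .candidateWeights(graph, q)
  keep <- cw$weight >= minSim &
    (if (strictMax) cw$weight < maxSim else cw$weight <= maxSim)
  if (length(exclude))
    keep <- keep & !(graph@accession[cw$id] %in% exclude)
  id <- cw$id[keep]
  w <- cw$weight[keep]
  acc <- graph@accession[id]
  ord <- order(-w, acc, method = "radix")
  data.frame(accession = acc[ord], weight = w[ord],
             stringsAsFactors = FALSE)
}

#' Export the implicit edge set
#'
#' Materializes the (otherwise implicit) edges above a weight cutoff, either
#' as a TSV edge list (\code{source}, \code{target}, \code{weight}) or as
#' GraphML via \pkg{igraph}. Full materialization is quadratic in the worst
#' case, hence the explicit cutoff.
#'
#' @param graph a \linkS4class{DomainGraph}.
#' @param path output file, or \code{NULL} to only return the edge table.
#' @param cutoff minimum Jaccard weight for an edge to be emitted.
#' @param format \code{"tsv"} or \code{"graphml"}.
#' @return data.frame of edges (source, target, weight), invisibly when
#'   written to a file.
#' @export
exportEdges <- function(graph, path = NULL, cutoff = 0.1,
                        format = c("tsv", "graphml")) {
  format <- match.arg(format)
  n <- length(graph@accession)
  src <- character(0); tgt <- character(0); wt <- numeric(0)
  for (i in seq_len(n)) {
    cw <- .candidateWeights(graph, graph@composition[[i]])
    keep <- cw$id > i & cw$weight >= cutoff
    if (any(keep)) {
      src <- c(src, rep.int(graph@accession[[i]], sum(keep)))
      tgt <- c(tgt, graph@accession[cw$id[keep]])
      wt <- c(wt, cw$weight[keep])
    }
  }
  edges <- data.frame(source = src, target = tgt, weight = wt,
                      stringsAsFactors = FALSE)
  ord <- order(edges$source, edges$target, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(path)) return(edges)
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    ig <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = graph@accession))
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(edges)
}
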