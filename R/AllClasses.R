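#' @import methods
NULL

#' DomainGraph: a domain-composition similarity graph over proteins
#'
#' Each node is a protein carrying an unordered set of domain signatures (its
#' domain composition) and zero or more function labels (typically EC
#' numbers). Two proteins are implicitly linked whenever their compositions
#' share at least one domain; the link weight is the Jaccard similarity
#' \eqn{|A \cap B| / |A \cup B|} of the two compositions, so weights lie in
#' (0, 1]. Edges are never materialized: neighbor queries run through an
#' inverted index mapping each domain signature to the integer ids of the
#' proteins containing it, which keeps query cost proportional to the number
#' of candidate proteins rather than to the full quadratic edge set.
#'
#' @slot accession character vector of unique protein accessions.
#' @slot composition list of character vectors, one de-duplicated non-empty
#'   domain set per protein, parallel to \code{accession}.
#' @slot labels list of character vectors of function labels (possibly
#'   empty), parallel to \code{accession}.
#' @slot index named list: domain signature -> integer ids of the proteins
#'   whose composition contains it (the exact transpose of the
#'   protein -> domain relation).
#'
#' @seealso [buildGraph()], [findNeighbors()], [propagate()]
#' @export
setClass("DomainGraph",
  representation(
    accession   = "character",
    composition = "list",
    labels      = "list",
    index       = "list"
  )
)

setValidity("DomainGraph", function(object) {
  n <- length(object@accession)
  if (length(object@composition) != n || length(object@labels) != n)
    return("accession, composition and labels must have equal length")
  if (anyDuplicated(object@accession))
    return(paste0("duplicate accession: ",
                  object@accession[duplicated(object@accession)][[1]]))
  for (i in seq_len(n)) {
    d <- object@composition[[i]]
    if (!is.character(d) || length(d) == 0L)
      return(paste0("protein ", object@accession[[i]],
                    " has an empty domain composition"))
    if (anyDuplicated(d))
      return(paste0("protein ", object@accession[[i]],
                    " has duplicate domains"))
  }
  # index must be the exact transpose of the composition relation
  fwd <- sort(paste(rep.int(seq_len(n), lengths(object@composition)),
                    unlist(object@composition, use.names = FALSE)))
  bwd <- sort(paste(unlist(object@index, use.names = FALSE),
                    rep.int(names(object@index), lengths(object@index))))
  if (!identical(fwd, bwd))
    return("inverted index is not the transpose of the composition relation")
  TRUE
})

#' PropagationResult: ranked candidate labels for one query protein
#'
#' Produced by [propagate()]. The ranking holds, for every label carried by
#' at least one retained neighbor, the cumulative Jaccard edge weight voting
#' for it and the normalized score (cumulative weight divided by the total
#' weight of all retained neighbors). Rows are ordered by descending
#' cumulative weight, ties broken by ascending label string; a tie at the
#' top rank is flagged.
#'
#' @slot query accession of the query protein (may be \code{NA} for an
#'   anonymous composition).
#' @slot ranking data.frame with columns \code{label}, \code{weight}
#'   (cumulative), \code{score} (normalized), possibly trimmed to the
#'   requested top k.
#' @slot neighbors data.frame with columns \code{accession}, \code{weight}:
#'   every neighbor that passed the similarity thresholds.
#' @slot parameters list: \code{minSim}, \code{maxSim}, \code{strictMax},
#'   \code{topK}.
#' @slot tieAtTop logical: more than one label attained the maximal
#'   cumulative weight.
#' @export
setClass("PropagationResult",
  representation(
    query      = "character",
    ranking    = "data.frame",
    neighbors  = "data.frame",
    parameters = "list",
    tieAtTop   = "logical"
  )
)

setValidity("PropagationResult", function(object) {
  r <- object@ranking
  if (!all(c("label", "weight", "score") %in% names(r)))
    return("ranking must have columns label, weight, score")
  if (!all(c("accession", "weight") %in% names(object@neighbors)))
    return("neighbors must have columns accession, weight")
  if (nrow(r) > 1L && any(diff(r$weight) > 1e-12))
    return("ranking is not sorted by descending cumulative weight")
  if (nrow(r) > 0L) {
    if (any(r$score < -1e-12 | r$score > 1 + 1e-12))
      return("normalized scores must lie in [0, 1]")
    total <- sum(object@neighbors$weight)
    if (any(r$weight > total + 1e-9))
      return("a cumulative weight exceeds the total neighbor weight")
  }
  TRUE
})

#' EvaluationReport: level-wise annotation metrics with coverage
#'
#' Produced by [evaluateLOO()]. Holds accuracy and macro-averaged
#' precision/recall/F1 at EC levels 1--4, plus annotation coverage
#' M/T where T is the number of evaluated proteins and M the number that
#' received at least one predicted label.
#'
#' @slot perLevel data.frame with columns \code{level}, \code{accuracy},
#'   \code{macroPrecision}, \code{macroRecall}, \code{macroF1}.
#' @slot coverage fraction M/T in [0, 1].
#' @slot counts named integer vector \code{c(total = T, predicted = M)}.
#' @slot parameters list of the evaluation parameters used.
#' @export
setClass("EvaluationReport",
  representation(
    perLevel   = "data.frame",
    coverage   = "numeric",
    counts     = "integer",
    parameters = "list"
  )
)

setValidity("EvaluationReport", function(object) {
  ct <- object@counts
  if (!all(c("total", "predicted") %in% names(ct)))
    return("counts must be named c(total=, predicted=)")
  if (ct[["predicted"]] > ct[["total"]] || ct[["predicted"]] < 0L)
    return("counts must satisfy total >= predicted >= 0")
  if (ct[["total"]] > 0L &&
      abs(object@coverage - ct[["predicted"]] / ct[["total"]]) > 1e-12)
    return("coverage must equal predicted / total exactly")
  m <- object@perLevel
  num <- unlist(m[c("accuracy", "macroPrecision", "macroRecall", "macroF1")])
  if (any(!is.na(num) & (num < -1e-12 | num > 1 + 1e-12)))
    return("all metrics must lie in [0, 1]")
  TRUE
})
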