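#' @rdname DomainGraph-class
#' @export
setMethod("accessions", "DomainGraph", function(x) x@accession)

#' @rdname DomainGraph-class
#' @export
setMethod("compositions", "DomainGraph", function(x) {
  stats::setNames(x@composition, x@accession)
})

#' @rdname DomainGraph-class
#' @export
setMethod("proteinLabels", "DomainGraph", function(x) {
  stats::setNames(x@labels, x@accession)
})

#' @rdname DomainGraph-class
#' @export
setMethod("domainVocabulary", "DomainGraph", function(x) sort(names(x@index)))

#' @rdname DomainGraph-class
#' @export
setMethod("length", "DomainGraph", function(x) length(x@accession))

#' @rdname DomainGraph-class
#' @export
setMethod("show", "DomainGraph", function(object) {
  cat("DomainGraph with", length(object@accession), "proteins and",
      length(object@index), "distinct domain signatures\n")
  nl <- sum(lengths(object@labels) > 0L)
  cat("  labeled proteins:", nl, "\n")
  if (length(object@accession)) {
    shown <- utils::head(object@accession, 5L)
    cat("  accessions:", paste(shown, collapse = ", "),
        if (length(object@accession) > 5L) "..." else "", "\n")
  }
  invisible(NULL)
})

#' @rdname PropagationResult-class
#' @export
setMethod("ranking", "PropagationResult", function(x) x@ranking)

#' @rdname PropagationResult-class
#' @export
setMethod("neighborsUsed", "PropagationResult", function(x) x@neighbors)

#' @rdname PropagationResult-class
#' @export
setMethod("topLabel", "PropagationResult", function(x) {
  if (nrow(x@ranking) == 0L) NA_character_ else x@ranking$label[[1L]]
})

#' @rdname PropagationResult-class
#' @export
setMethod("queryAccession", "PropagationResult", function(x) x@query)

#' @rdname PropagationResult-class
#' @export
setMethod("runParameters", "PropagationResult", function(x) x@parameters)

#' @rdname PropagationResult-class
#' @export
setMethod("show", "PropagationResult", function(object) {
  q <- if (is.na(object@query)) "<anonymous>" else object@query
  cat("PropagationResult for query", q, "\n")
  cat("  neighbors used:", nrow(object@neighbors), "\n")
  if (nrow(object@ranking) == 0L) {
    cat("  no label predicted (no neighbor passed the thresholds)\n")
  } else {
    cat("  top label:", object@ranking$label[[1L]],
        sprintf("(cumulative weight %.4g, normalized score %.4g)",
                object@ranking$weight[[1L]], object@ranking$score[[1L]]), "\n")
    if (object@tieAtTop) cat("  note: tie at the top rank\n")
    print(utils::head(object@ranking, 5L), row.names = FALSE)
  }
  invisible(NULL)
})

#' @rdname EvaluationReport-class
#' @export
setMethod("perLevelMetrics", "EvaluationReport", function(x) x@perLevel)

#' @rdname EvaluationReport-class
#' @export
setMethod("annotationCoverage", "EvaluationReport", function(x) x@coverage)

#' @rdname EvaluationReport-class
#' @export
setMethod("evaluationCounts", "EvaluationReport", function(x) x@counts)

#' @rdname EvaluationReport-class
#' @export
setMethod("runParameters", "EvaluationReport", function(x) x@parameters)

#' @rdname EvaluationReport-class
#' @export
setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", object@counts[["predicted"]], "of",
      object@counts[["total"]], "proteins annotated (coverage",
      sprintf("%.4g)", object@coverage), "\n")
  print(object@perLevel, row.names = FALSE)
  invisible(NULL)
})
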