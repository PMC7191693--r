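#' @rdname DomainGraph-class
#' @param x,object a \linkS4class{DomainGraph}, \linkS4class{PropagationResult}
#'   or \linkS4class{EvaluationReport}.
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname DomainGraph-class
#' @export
setGeneric("compositions", function(x) standardGeneric("compositions"))

#' @rdname DomainGraph-class
#' @export
setGeneric("proteinLabels", function(x) standardGeneric("proteinLabels"))

#' @rdname DomainGraph-class
#' @export
setGeneric("domainVocabulary", function(x) standardGeneric("domainVocabulary"))

#' @rdname PropagationResult-class
#' @param x,object see below.
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))

#' @rdname PropagationResult-class
#' @export
setGeneric("neighborsUsed", function(x) standardGeneric("neighborsUsed"))

#' @rdname PropagationResult-class
#' @export
setGeneric("topLabel", function(x) standardGeneric("topLabel"))

#' @rdname PropagationResult-class
#' @export
setGeneric("queryAccession", function(x) standardGeneric("queryAccession"))

#' @rdname EvaluationReport-class
#' @param x,object see below.
#' @export
setGeneric("perLevelMetrics", function(x) standardGeneric("perLevelMetrics"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("annotationCoverage", function(x) standardGeneric("annotationCoverage"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("evaluationCounts", function(x) standardGeneric("evaluationCounts"))

#' @rdname PropagationResult-class
#' @export
setGeneric("runParameters", function(x) standardGeneric("runParameters"))
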