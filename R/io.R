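#' Construct a protein annotation table in memory
#'
#' The package's tabular exchange unit: one row per protein holding its
#' accession, its domain composition (a set of signature identifiers) and
#' its function labels (EC numbers or, in binary mode, arbitrary class
#' strings; may be empty for query-only records). Domain identifiers are
#' opaque strings, so synthetic vocabularies work exactly like InterPro
#' accessions.
#'
#' @param accession character vector of unique, non-empty accessions.
#' @param domains list of character vectors (or a single character vector for
#'   one row); trimmed, empties dropped, duplicates collapsed. Every row must
#'   retain at least one domain.
#' @param ec list of character vectors of labels; defaults to no labels.
#' @return data.frame with columns \code{accession} (character),
#'   \code{domains} (list) and \code{ec} (list).
#' @examples
#' annotationRows("P1", list(c("d1", "d2")), list("1.1.1.1"))
#' @export
annotationRows <- function(accession, domains, ec = NULL) {
  if (is.character(domains)) domains <- list(domains)
  if (is.null(ec)) ec <- rep(list(character(0)), length(accession))
  if (is.character(ec)) ec <- list(ec)
  stopifnot(length(domains) == length(accession),
            length(ec) == length(accession))
  accession <- trimws(as.character(accession))
  if (any(!nzchar(accession))) stop("empty accession")
  dup <- accession[duplicated(accession)]
  if (length(dup)) stop("duplicate accession: ", dup[[1]])
  domains <- lapply(domains, function(d) unique(trimws(d)[nzchar(trimws(d))]))
  if (any(lengths(domains) == 0L))
    stop("protein ", accession[which(lengths(domains) == 0L)[[1]]],
         " has no domain signature; every protein must contain at least one")
  ec <- lapply(ec, function(e) unique(trimws(e)[nzchar(trimws(e))]))
  data.frame(accession = accession,
             domains = I(unname(domains)),
             ec = I(unname(ec)),
             stringsAsFactors = FALSE)
}

#' Read the native protein annotation table
#'
#' The native format is UTF-8 TSV with three columns: \code{accession},
#' \code{domains} (";"-joined) and \code{ec} (";"-joined, may be blank).
#' Lines starting with \code{#} are treated as comments/header and skipped.
#' Tokens are trimmed, empty tokens dropped, and duplicate domains within a
#' row collapsed. By default a row left with zero domains is an error (every
#' protein admitted into a graph must carry at least one signature);
#' \code{permissive = TRUE} skips such rows with a warning instead.
#'
#' @param path file path.
#' @param permissive logical; skip domain-less rows with a warning rather
#'   than failing.
#' @return annotation table as from [annotationRows()], rows in file order.
#' @seealso [writeAnnotationTable()], [readInterProScan()]
#' @export
readAnnotationTable <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  acc <- character(0); dom <- list(); ec <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop("malformed line (need at least accession and domains): ", ln)
    a <- trimws(fields[[1]])
    d <- trimws(strsplit(fields[[2]], ";", fixed = TRUE)[[1]])
    d <- unique(d[nzchar(d)])
    e <- if (length(fields) >= 3L) {
      e0 <- trimws(strsplit(fields[[3]], ";", fixed = TRUE)[[1]])
      unique(e0[nzchar(e0)])
    } else character(0)
    if (length(d) == 0L) {
      if (permissive) {
        warning("skipping protein ", a, ": no domain signature")
        next
      }
      stop("protein ", a, " has no domain signature")
    }
    if (a %in% acc) stop("duplicate accession: ", a)
    acc <- c(acc, a); dom <- c(dom, list(d)); ec <- c(ec, list(e))
  }
  annotationRows(acc, dom, ec)
}

#' Write the native protein annotation table
#'
#' @param rows annotation table as from [annotationRows()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationTable <- function(rows, path) {
  header <- "#accession\tdomains\tec"
  body <- vapply(seq_len(nrow(rows)), function(i) {
    paste(rows$accession[[i]],
          paste(rows$domains[[i]], collapse = ";"),
          paste(rows$ec[[i]], collapse = ";"),
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read InterProScan 5 tab-separated output
#'
#' Consumes the standard InterProScan TSV layout (>= 12 columns; column 1 is
#' the query identifier, column 12 the integrated InterPro accession, which
#' is \code{"-"} when a match has no InterPro integration). One annotation
#' row is produced per distinct query, its domain composition being the set
#' of distinct non-null InterPro accessions over all of that query's lines;
#' overlapping matches collapse naturally under set semantics. Queries whose
#' every line lacks an InterPro accession are omitted with a warning, since
#' a protein without a signature cannot enter the graph. EC labels are not
#' provided by InterProScan, so the \code{ec} column is empty.
#'
#' @param path file path to InterProScan TSV output.
#' @return annotation table; queries in order of first appearance.
#' @export
readInterProScan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  qids <- character(0)
  doms <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 12L)
      stop("line ", i, " has ", length(fields),
           " columns; InterProScan TSV requires at least 12")
    q <- trimws(fields[[1]])
    ipr <- trimws(fields[[12]])
    j <- match(q, qids)
    if (is.na(j)) {
      qids <- c(qids, q)
      doms <- c(doms, list(character(0)))
      j <- length(qids)
    }
    if (nzchar(ipr) && ipr != "-")
      doms[[j]] <- union(doms[[j]], ipr)
  }
  keep <- lengths(doms) > 0L
  if (any(!keep))
    warning("omitting ", sum(!keep),
            " quer", if (sum(!keep) == 1L) "y" else "ies",
            " without any integrated InterPro accession: ",
            paste(qids[!keep], collapse = ", "))
  annotationRows(qids[keep], doms[keep])
}

#' Write propagation results to JSON
#'
#' Serializes a list of \linkS4class{PropagationResult} objects to a JSON
#' array; each entry records the query accession, the run parameters, the
#' ranked labels with cumulative and normalized weights, the contributing
#' neighbors with their edge weights, and the top-rank tie flag. The file
#' round-trips losslessly through [readResults()].
#'
#' @param results list of \linkS4class{PropagationResult} objects (or one).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(results, path) {
  if (is(results, "PropagationResult")) results <- list(results)
  payload <- lapply(results, function(r) {
    params <- r@parameters
    if (!is.null(params$topK) && is.infinite(params$topK))
      params$topK <- "all"   # JSON has no Inf
    list(
      accession  = r@query,
      parameters = params,
      tieAtTop   = r@tieAtTop,
      ranking    = r@ranking,
      neighbors  = r@neighbors
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Read propagation results from JSON
#'
#' @param path JSON file written by [writeResults()].
#' @return list of \linkS4class{PropagationResult} objects.
#' @export
readResults <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    rk <- .bindRecords(p$ranking, c(label = "character", weight = "numeric",
                                    score = "numeric"))
    nb <- .bindRecords(p$neighbors, c(accession = "character",
                                      weight = "numeric"))
    params <- lapply(p$parameters, function(v) v)
    if (identical(params$topK, "all")) params$topK <- Inf
    new("PropagationResult",
        query      = if (is.null(p$accession)) NA_character_
                     else as.character(p$accession),
        ranking    = rk,
        neighbors  = nb,
        parameters = params,
        tieAtTop   = isTRUE(p$tieAtTop))
  })
}

# row-of-lists JSON -> typed data.frame with fixed columns
.bindRecords <- function(records, cols) {
  out <- lapply(names(cols), function(nm) {
    vals <- vapply(records, function(r) {
      v <- r[[nm]]
      if (is.null(v)) NA else v
    }, if (cols[[nm]] == "character") character(1) else numeric(1))
    vals
  })
  names(out) <- names(cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}
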