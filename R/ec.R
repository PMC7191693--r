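#' Parse Enzyme Commission numbers into canonical form
#'
#' EC numbers form a four-level hierarchy (class, subclass, sub-subclass,
#' sub-sub-subclass), written as up to four dot-separated positive integers,
#' e.g. \code{"3.1.21.4"} for a Type II site-specific deoxyribonuclease.
#' Incomplete codes leave trailing components unresolved, rendered as
#' \code{"-"}. \code{ecParse()} accepts an optional \code{"EC "} prefix and
#' missing trailing components, and returns the canonical four-component
#' string (e.g. \code{"3.1"} becomes \code{"3.1.-.-"}).
#'
#' A resolved component may never follow an unresolved one: \code{"3.-.21.4"}
#' is rejected, as are codes with more than four components or non-numeric
#' resolved tokens.
#'
#' @param x character vector of EC codes.
#' @return character vector of canonical dot-joined four-component codes.
#' @examples
#' ecParse(c("EC 3.1.21.4", "3.1.-.-", "3.1"))
#' @export
ecParse <- function(x) {
  if (length(x) == 0L) return(character(0))
  stopifnot(is.character(x))
  out <- character(length(x))
  for (i in seq_along(x)) {
    raw <- trimws(x[[i]])
    if (is.na(raw) || !nzchar(raw))
      stop("empty EC code at position ", i)
    body <- sub("^EC[ ]+", "", raw, ignore.case = TRUE)
    toks <- trimws(strsplit(body, ".", fixed = TRUE)[[1]])
    if (length(toks) > 4L)
      stop("EC code '", raw, "' has more than 4 components")
    if (length(toks) == 0L || !nzchar(toks[[1]]))
      stop("EC code '", raw, "' has no components")
    toks <- c(toks, rep("-", 4L - length(toks)))
    resolved <- grepl("^[0-9]+$", toks)
    unresolved <- toks == "-" | toks == ""
    if (any(!resolved & !unresolved))
      stop("EC code '", raw, "' has a non-numeric component '",
           toks[!resolved & !unresolved][[1]], "'")
    toks[unresolved] <- "-"
    depth <- match(TRUE, !resolved, nomatch = 5L) - 1L
    if (depth < 1L)
      stop("EC code '", raw, "' has no resolved leading component")
    if (any(resolved[seq_len(4L) > depth]))
      stop("EC code '", raw, "' has a resolved component after an unresolved one")
    if (any(resolved & toks == "0"))
      stop("EC code '", raw, "' has a non-positive component")
    toks[resolved] <- as.character(as.integer(toks[resolved]))
    out[[i]] <- paste(toks, collapse = ".")
  }
  out
}

#' Depth of an EC code
#'
#' The number of leading resolved components (1--4) of each code.
#'
#' @param x character vector of EC codes (parsed leniently via [ecParse()]).
#' @return integer vector of depths.
#' @examples
#' ecDepth(c("3.1.21.4", "3.1.-.-"))
#' @export
ecDepth <- function(x) {
  canon <- ecParse(x)
  vapply(strsplit(canon, ".", fixed = TRUE),
         function(t) match("-", t, nomatch = 5L) - 1L, integer(1))
}

#' Truncate EC codes to a hierarchy level
#'
#' Level-wise evaluation scores the first digit at level 1, the first two
#' digits at level 2, and so on. A code whose depth is smaller than the
#' requested level cannot be scored there and truncates to \code{NA}, the
#' undefined marker, which never matches any label.
#'
#' @param x character vector of EC codes.
#' @param level integer in 1--4.
#' @return character vector: the first \code{level} components dot-joined,
#'   or \code{NA} where the code is not resolved that deep.
#' @examples
#' ecTruncate("3.1.21.4", 2) # "3.1"
#' ecTruncate("3.1.-.-", 4)  # NA
#' @export
ecTruncate <- function(x, level) {
  stopifnot(length(level) == 1L, level %in% 1:4)
  if (length(x) == 0L) return(character(0))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  canon <- ecParse(x[ok])
  parts <- strsplit(canon, ".", fixed = TRUE)
  out[ok] <- vapply(parts, function(t) {
    if (match("-", t, nomatch = 5L) - 1L < level) NA_character_
    else paste(t[seq_len(level)], collapse = ".")
  }, character(1))
  out
}
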