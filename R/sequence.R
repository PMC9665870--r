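#' Coerce to a Sequence
#'
#' Accepts an integer vector over \code{[1..sigma]}, a single character
#' string, or a character vector of single characters.  Character symbols are
#' remapped to a dense integer alphabet; by default the map is the sorted set
#' of distinct symbols actually present, but a fixed \code{alphabet} can be
#' supplied so that several sequences share codes (required when comparing a
#' query and a text).
#'
#' @param x input sequence.
#' @param alphabet optional character vector fixing the code of each symbol;
#'   symbols of \code{x} absent from it are appended (queries may use
#'   symbols that the text lacks).
#' @param sigma optional alphabet size for integer inputs (defaults to
#'   \code{max(x)}).
#' @return a \code{\linkS4class{Sequence}}.
#' @examples
#' asSequence("abab")
#' asSequence(c(1L, 2L, 1L), sigma = 4L)
#' @export
asSequence <- function(x, alphabet = NULL, sigma = NULL) {
  if (is(x, "Sequence")) return(x)
  if (is.numeric(x)) {
    sym <- as.integer(x)
    if (length(sym) < 1L) stop("empty sequence")
    if (anyNA(sym) || min(sym) < 1L) stop("integer symbols must be >= 1")
    if (is.null(sigma)) sigma <- max(sym)
    if (max(sym) > sigma) stop("symbol out of range [1..sigma]")
    return(new("Sequence", symbols = sym, sigma = as.integer(sigma),
               alphabet = if (is.null(alphabet)) character(0) else alphabet))
  }
  if (is.character(x)) {
    chars <- if (length(x) == 1L && nchar(x) != 1L)
      strsplit(x, "", fixed = TRUE)[[1L]] else x
    if (length(chars) < 1L || (length(chars) == 1L && !nzchar(chars)))
      stop("empty sequence")
    ab <- if (is.null(alphabet)) sort(unique(chars)) else alphabet
    extra <- setdiff(unique(chars), ab)
    ab <- c(ab, sort(extra))
    sym <- match(chars, ab)
    return(new("Sequence", symbols = sym, sigma = length(ab), alphabet = ab))
  }
  stop("cannot coerce to Sequence")
}

#' @describeIn asSequence symbols as an integer vector.
#' @param s a Sequence.
#' @export
seqSymbols <- function(s) asSequence(s)@symbols

#' @describeIn asSequence length of a Sequence.
#' @export
seqLength <- function(s) length(asSequence(s)@symbols)

#' @describeIn asSequence the Sequence read right to left.
#' @export
reverseSequence <- function(s) {
  s <- asSequence(s)
  new("Sequence", symbols = rev(s@symbols), sigma = s@sigma,
      alphabet = s@alphabet)
}

#' @describeIn asSequence back to a character string (when an alphabet map
#'   exists) or the integer vector otherwise.
#' @export
seqToString <- function(s) {
  s <- asSequence(s)
  if (length(s@alphabet)) paste(s@alphabet[s@symbols], collapse = "")
  else s@symbols
}

## Put a query on the same dense code space as an indexed text.  Query
## symbols absent from the text's alphabet get fresh codes > sigma(text),
## which simply never occur in the BWT.
.harmonizeQuery <- function(S, idx) {
  S <- asSequence(S)
  if (length(idx@alphabet) == 0L) {
    if (length(S@alphabet)) stop("query is character but text was numeric")
    return(S@symbols)
  }
  if (length(S@alphabet) == 0L) return(S@symbols)
  code <- match(S@alphabet[S@symbols], idx@alphabet)
  miss <- is.na(code)
  if (any(miss)) {
    extra <- match(S@alphabet[S@symbols][miss],
                   sort(unique(S@alphabet[S@symbols][miss])))
    code[miss] <- idx@sigma + extra
  }
  code
}
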