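#' Read sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readBStringSet}: case-insensitive,
#' line-wrap agnostic, arbitrary alphabets.  Ambiguity codes (N etc.) are
#' kept as literal symbols.
#'
#' @param path FASTA file.
#' @return named character vector of record sequences (upper-cased).
#' @export
readFastaSeq <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file")
  out <- toupper(as.character(set))
  if (any(nchar(out) == 0L)) stop("FASTA record with empty sequence")
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  out
}

#' @rdname readFastaSeq
#' @param records named character vector.
#' @export
writeFastaSeq <- function(records, path) {
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Combine FASTA records into query/text sequences
#'
#' Modes: \code{separate} returns one \code{\linkS4class{Sequence}} per
#' record; \code{concat-sep} joins all records with a unique separator
#' symbol absent from the data, so that matches can never span a record
#' boundary (separator positions decode to MS value 0 by construction);
#' \code{concat-raw} joins records directly.
#'
#' @param records named character vector (as from \code{readFastaSeq}).
#' @param mode one of \code{"concat-sep"} (default), \code{"separate"},
#'   \code{"concat-raw"}.
#' @param alphabet optional fixed alphabet for code sharing.
#' @return a Sequence, or a list of Sequences for \code{mode="separate"}.
#' @export
concatRecords <- function(records, mode = c("concat-sep", "separate",
                                            "concat-raw"),
                          alphabet = NULL) {
  mode <- match.arg(mode)
  if (length(records) == 0L) stop("no records")
  if (mode == "separate")
    return(lapply(records, asSequence, alphabet = alphabet))
  if (mode == "concat-raw")
    return(asSequence(paste(records, collapse = ""), alphabet = alphabet))
  ## unique separator: first byte not present in any record
  used <- unique(unlist(strsplit(paste(records, collapse = ""), "",
                                 fixed = TRUE)))
  sepPool <- c("#", "+", "=", "@", "!", "%", "&", "*", "?", "~", "^")
  sep <- setdiff(sepPool, used)
  if (!length(sep)) stop("could not find an unused separator symbol")
  asSequence(paste(records, collapse = sep[1L]), alphabet = alphabet)
}

#' Synthetic mutated sequence pair
#'
#' Generates a text T uniformly at random over \code{[1..sigma]} and a
#' query S derived from T by independent per-position edits at rate
#' \code{rho}, mixing substitutions (to a different uniform symbol),
#' insertions and deletions according to \code{mix}.  Deterministic given
#' \code{seed}.  \code{rho = 0} gives \code{S = T}, hence
#' \code{MS[i] = |S| - i}.
#'
#' @param n text length.
#' @param rho per-position mutation rate in \code{[0, 1)}.
#' @param sigma alphabet size (default 4, DNA-like).
#' @param seed RNG seed (the generator restores the caller's RNG state).
#' @param mix named weights for \code{sub}, \code{ins}, \code{del}
#'   (default substitutions only).
#' @return list with Sequences \code{S} and \code{T}.
#' @examples
#' p <- synthPair(100, 0.05, seed = 7)
#' seqLength(p$S)
#' @export
synthPair <- function(n, rho, sigma = 4L, seed = 1L,
                      mix = c(sub = 1, ins = 0, del = 0)) {
  stopifnot(n >= 1L, rho >= 0, rho < 1, sigma >= 1L)
  mix <- mix / sum(mix)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  t <- sample.int(sigma, n, replace = TRUE)
  edit <- which(stats::runif(n) < rho)
  s <- as.list(t)
  for (p in edit) {
    kind <- sample(c("sub", "ins", "del"), 1L, prob = mix)
    if (kind == "sub") {
      if (sigma > 1L) {
        alt <- sample.int(sigma - 1L, 1L)
        s[[p]] <- if (alt >= t[p]) alt + 1L else alt
      }
    } else if (kind == "ins") {
      s[[p]] <- c(sample.int(sigma, 1L), s[[p]])
    } else {
      s[[p]] <- integer(0)
    }
  }
  sVec <- unlist(s, use.names = FALSE)
  if (!length(sVec)) sVec <- sample.int(sigma, 1L)
  list(S = asSequence(sVec, sigma = sigma), T = asSequence(t, sigma = sigma))
}
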