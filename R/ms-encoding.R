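.newMSBitvector <- function(bits, m, allowNegative = FALSE) {
  new("MSBitvector", bits = as.integer(bits), m = as.integer(m),
      onePos = which(bits == 1L) - 1L, allowNegative = allowNegative)
}

#' Encode a matching statistics array
#'
#' Appends, for each position i in increasing order,
#' \code{MS[i] - MS[i-1] + 1} zeros followed by a one (\code{MS[-1] = 1}),
#' then right-pads with zeros to 2m bits.  For true matching statistics the
#' last value is 0 or 1, so the result is always exactly 2m bits; arrays
#' ending above 1 (legal under the slope invariant but not produced by any
#' query/text pair) emit \code{2m + MS[m-1] - 1} bits and are kept unpadded.
#'
#' @param ms integer vector with \code{ms[i+1] >= ms[i] - 1} and all values
#'   \code{>= 0}.
#' @return an \code{\linkS4class{MSBitvector}}.
#' @examples
#' encodeMS(c(1L, 2L, 1L))@bits   # 0 1 0 0 1 1
#' @export
encodeMS <- function(ms) {
  ms <- as.integer(ms)
  m <- length(ms)
  stopifnot(m >= 1L)
  if (min(ms) < 0L) stop("matching statistics values must be non-negative")
  zeros <- diff(c(1L, ms)) + 1L
  if (min(zeros) < 0L)
    stop("invalid MS array: MS[i+1] >= MS[i] - 1 violated")
  lens <- as.integer(rbind(zeros, 1L))
  vals <- rep(c(0L, 1L), m)
  bits <- rep(vals, lens)
  if (length(bits) < 2L * m) bits <- c(bits, rep(0L, 2L * m - length(bits)))
  .newMSBitvector(bits, m)
}

#' Decode an ms bitvector
#'
#' \code{MS[i] = selectOne(bv, i) - 2*i}; trailing zeros after the m-th one
#' are padding and are ignored.
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @return integer vector of decoded values.
#' @examples
#' decodeMS(encodeMS(c(1L, 2L, 1L)))
#' @export
decodeMS <- function(bv) {
  if (bv@m == 0L) return(integer(0))
  vals <- bv@onePos - 2L * (0:(bv@m - 1L))
  if (!bv@allowNegative && length(vals) && min(vals) < 0L)
    stop("malformed bitvector: negative decoded value")
  vals
}

#' @describeIn decodeMS random access to \code{MS[i]} via select (0-based
#'   \code{i}).
#' @param i 0-based position in \code{[0..m-1]}.
#' @export
msAccess <- function(bv, i) {
  if (any(i < 0L) || any(i >= bv@m)) stop("position out of range")
  bv@onePos[i + 1L] - 2L * as.integer(i)
}

#' Rank and select over the one-bits
#'
#' 0-based contracts: \code{selectOne(bv, i)} is the position of the i-th
#' one (i starting at 0); \code{rankOne(bv, p)} counts ones in
#' \code{bits[0..p]}, inclusive.
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @param i 0-based one index.
#' @export
selectOne <- function(bv, i) {
  if (any(i < 0L) || any(i >= bv@m)) stop("select index out of range")
  bv@onePos[i + 1L]
}

#' @rdname selectOne
#' @param p 0-based bit position.
#' @export
rankOne <- function(bv, p) findInterval(p, bv@onePos)

## ---- serialization -------------------------------------------------------

.u64raw <- function(x) {                # little-endian 8-byte length field
  out <- raw(8L)
  for (k in 1:8) { out[k] <- as.raw(x %% 256); x <- x %/% 256 }
  out
}

.rawU64 <- function(r) sum(as.numeric(r) * 256^(0:7))

#' Serialize / deserialize an ms bitvector
#'
#' Binary layout: magic \code{"MSBV"}, version byte, flag byte (bit 0 =
#' negative-values mode), bit-length as 8-byte little-endian integer,
#' payload packed least-significant-bit first.  A plain-text 0/1 dialect is
#' provided for fixtures and debugging; both dialects decode to bit-equal
#' containers.
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @return \code{msbvSerialize}: a raw vector; \code{msbvDeserialize}: the
#'   reconstructed bitvector.
#' @examples
#' bv <- encodeMS(c(1L, 2L, 1L))
#' identical(msbvDeserialize(msbvSerialize(bv))@bits, bv@bits)
#' @export
msbvSerialize <- function(bv) {
  nb <- length(bv@bits)
  pad <- (8L - nb %% 8L) %% 8L
  payload <- packBits(as.logical(c(bv@bits, rep(0L, pad))), type = "raw")
  c(charToRaw("MSBV"), as.raw(1L), as.raw(as.integer(bv@allowNegative)),
    .u64raw(nb), payload)
}

#' @rdname msbvSerialize
#' @param bytes a raw vector produced by \code{msbvSerialize}.
#' @export
msbvDeserialize <- function(bytes) {
  if (length(bytes) < 14L) stop("truncated MSBV payload")
  if (!identical(bytes[1:4], charToRaw("MSBV"))) stop("bad magic")
  if (as.integer(bytes[5L]) != 1L) stop("unsupported MSBV version")
  neg <- as.integer(bytes[6L]) == 1L
  nb <- .rawU64(bytes[7:14])
  if (nb < 1) stop("empty payload rejected")
  bits <- as.integer(rawToBits(bytes[-(1:14)]))[seq_len(nb)]
  .newMSBitvector(bits, sum(bits), allowNegative = neg)
}

#' @rdname msbvSerialize
#' @export
msbvToText <- function(bv) paste(bv@bits, collapse = "")

#' @rdname msbvSerialize
#' @param text a 0/1 character string.
#' @param allowNegative negative-values flag for the rebuilt container.
#' @export
msbvFromText <- function(text, allowNegative = FALSE) {
  bits <- as.integer(strsplit(text, "", fixed = TRUE)[[1L]])
  if (length(bits) == 0L || anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("text dialect must be a non-empty 0/1 string")
  .newMSBitvector(bits, sum(bits), allowNegative = allowNegative)
}

#' @rdname msbvSerialize
#' @param path file path.
#' @export
writeMSBV <- function(bv, path) {
  writeBin(msbvSerialize(bv), path)
  invisible(path)
}

#' @rdname msbvSerialize
#' @export
readMSBV <- function(path) {
  msbvDeserialize(readBin(path, "raw", n = file.size(path)))
}
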