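# Greedy longest-match compression of a target base stream against the
# k-mer-indexed reference, and its exact inverse.

#' First-order compression of a base stream
#'
#' Greedy maximal-exact-match encoding of \code{target} against the
#' reference behind \code{idx}. At each cursor position the anchor k-mer is
#' looked up; every candidate occurrence is extended as far as the exact
#' match runs and the longest extension is emitted as a
#' \code{Match(position, length)} token. Ties go to the candidate whose
#' start position has the smallest absolute delta to the previous match's
#' end, then to the smallest position, which keeps the delta-encoded
#' positions in the archive small. Where no anchor of length \code{k} exists
#' the cursor advances one base into a pending \code{Literal}; adjacent
#' literals are merged. Every emitted match has length >= k; targets shorter
#' than k become a single literal.
#'
#' @param target target base stream (uppercase ACGT character scalar).
#' @param ref the reference base stream \code{idx} was built from; checked by
#'   content fingerprint.
#' @param idx a \linkS4class{KmerIndex} built from \code{ref}.
#' @param seqId ordinal stored in the returned stream.
#' @return a \linkS4class{FirstOrderStream} whose expansion reproduces
#'   \code{target} exactly.
#' @export
compressFirstOrder <- function(target, ref, idx, seqId = 0L) {
  stopifnot(is(idx, "KmerIndex"))
  if (!identical(fingerprintBytes(ref), idx@refFingerprint))
    sgcUsageError("index was not built from this reference stream")
  cols <- cpp_compress_first_order(idx@ptr, target)
  new("FirstOrderStream", seqId = as.integer(seqId), type = cols$type,
      pos = cols$pos, len = cols$len, lit = cols$lit)
}

#' First-order decompression
#'
#' Exact inverse of \code{\link{compressFirstOrder}}: concatenates reference
#' spans for matches and literal strings in token order.
#'
#' @param stream a \linkS4class{FirstOrderStream}.
#' @param ref the reference base stream.
#' @return the reconstructed target base stream.
#' @export
decompressFirstOrder <- function(stream, ref) {
  stopifnot(is(stream, "FirstOrderStream"))
  isMatch <- stream@type == 0L
  if (any(isMatch & (stream@pos + stream@len > nchar(ref))))
    sgcCorruptionError("first-order match outside reference bounds")
  tryCatch(
    cpp_decompress_first_order(ref, stream@type, stream@pos, stream@len, stream@lit),
    error = function(e) sgcCorruptionError(conditionMessage(e)))
}
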