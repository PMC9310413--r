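# Second-order compression: match first-order token streams against the
# streams of the first S compressed sequences, chain-compress the references
# themselves, and invert both.
#
# Matching granularity is whole first-order tokens: a Match token matches
# only an identical (position, length) pair and a Literal only an identical
# string, so equality is exact and the index stays simple. Single-token
# fingerprints anchor the search; run extension over consecutive equal
# tokens supplies specificity. Runs shorter than minRun are cheaper as
# Passthrough tokens and are not replaced.

#' Select the second-order references
#'
#' The second-order references are exactly the first \code{min(S, N)}
#' streams in seq_id order; the rest are non-references. The default number
#' of second-order references is 40.
#'
#' @param streams list of \linkS4class{FirstOrderStream}, in seq_id order.
#' @param S requested number of second-order references (clamped to the
#'   collection size).
#' @return list with \code{references} and \code{non_references}.
#' @export
selectSecondOrderReferences <- function(streams, S = 40L) {
  S <- as.integer(S)
  if (is.na(S) || S < 0L) sgcConfigError("S must be a non-negative integer")
  nRef <- min(S, length(streams))
  list(references = if (nRef > 0) streams[seq_len(nRef)] else list(),
       non_references = if (nRef < length(streams))
         streams[(nRef + 1):length(streams)] else list())
}

#' Build the token index over the second-order references
#'
#' Indexes every token of every reference exactly once under its
#' fingerprint (a Match's (position, length) pair, a Literal's string).
#'
#' @param references list of \linkS4class{FirstOrderStream} in seq_id order.
#' @return a \linkS4class{TokenIndex}.
#' @export
buildTokenIndex <- function(references) {
  ptr <- cpp_token_index_new()
  for (s in references) {
    stopifnot(is(s, "FirstOrderStream"))
    cpp_token_index_add(ptr, s@seqId, s@type, s@pos, s@len, s@lit)
  }
  new("TokenIndex", ptr = ptr)
}

#' Summary counts of a token index
#' @param idx a \linkS4class{TokenIndex}.
#' @return list with \code{n_refs}, \code{seq_ids}, \code{n_locations}.
#' @export
tokenIndexInfo <- function(idx) {
  stopifnot(is(idx, "TokenIndex"))
  cpp_token_index_info(idx@ptr)
}

#' Look up one first-order token in a token index
#'
#' @param idx a \linkS4class{TokenIndex}.
#' @param type 0 for Match, 1 for Literal.
#' @param pos,len Match fields (ignored for literals except \code{len}).
#' @param lit Literal string (ignored for matches).
#' @return integer matrix with columns (ref seq_id, token position).
#' @export
tokenLookup <- function(idx, type, pos = NA_integer_, len = NA_integer_,
                        lit = NA_character_) {
  stopifnot(is(idx, "TokenIndex"))
  m <- cpp_token_index_lookup(idx@ptr, as.integer(type),
                              if (is.na(pos)) 0L else as.integer(pos),
                              as.integer(len),
                              if (is.na(lit)) "" else lit)
  colnames(m) <- c("refSeqId", "tokenPosition")
  m
}

#' Second-order compression of a first-order stream
#'
#' Greedy over target tokens: at each token the fingerprint is looked up in
#' \code{idx}; each candidate location is extended over exactly-equal
#' consecutive tokens; the longest run of at least \code{minRun} tokens is
#' emitted as a \code{RefMatch(ref_seq_id, token_position, token_count)},
#' otherwise the token passes through unchanged. Ties go to the lowest
#' reference seq_id, then the lowest token position.
#'
#' @param target a \linkS4class{FirstOrderStream}.
#' @param idx a \linkS4class{TokenIndex} built from the references.
#' @param minRun minimum accepted run length in tokens (default 2; a
#'   one-token RefMatch costs more than most Passthrough encodings).
#' @param isReference flag stored on the returned stream.
#' @return a \linkS4class{SecondOrderStream}.
#' @export
compressSecondOrder <- function(target, idx, minRun = 2L, isReference = FALSE) {
  stopifnot(is(target, "FirstOrderStream"), is(idx, "TokenIndex"))
  minRun <- as.integer(minRun)
  if (is.na(minRun) || minRun < 1L) sgcConfigError("minRun must be >= 1")
  cols <- cpp_compress_second_order(idx@ptr, target@type, target@pos,
                                    target@len, target@lit, minRun)
  new("SecondOrderStream", seqId = target@seqId, isReference = isReference,
      kind = cols$kind, refId = cols$refId, tokPos = cols$tokPos,
      tokCount = cols$tokCount, foType = cols$foType, foPos = cols$foPos,
      foLen = cols$foLen, foLit = cols$foLit)
}

#' Chain-compress the second-order references
#'
#' Reference 0 is emitted all-Passthrough; reference i is compressed against
#' references 0..i-1 only, so the chain can be expanded front to back and
#' every reference reconstructed losslessly.
#'
#' @param references list of \linkS4class{FirstOrderStream} in seq_id order.
#' @param minRun minimum accepted run length in tokens.
#' @return list with \code{streams} (list of \linkS4class{SecondOrderStream})
#'   and \code{index} (the \linkS4class{TokenIndex} over all references,
#'   ready for compressing the non-references).
#' @export
chainCompressReferences <- function(references, minRun = 2L) {
  idx <- new("TokenIndex", ptr = cpp_token_index_new())
  out <- vector("list", length(references))
  for (i in seq_along(references)) {
    out[[i]] <- compressSecondOrder(references[[i]], idx, minRun = minRun,
                                    isReference = TRUE)
    s <- references[[i]]
    cpp_token_index_add(idx@ptr, s@seqId, s@type, s@pos, s@len, s@lit)
  }
  list(streams = out, index = idx)
}

#' Second-order decompression
#'
#' Exact inverse of second-order compression: every RefMatch is replaced by
#' the referenced token slice of the corresponding expanded reference
#' stream.
#'
#' @param stream a \linkS4class{SecondOrderStream}.
#' @param expanded_references list of \linkS4class{FirstOrderStream}; only
#'   the seq_ids actually referenced need to be present.
#' @return the original \linkS4class{FirstOrderStream}.
#' @export
decompressSecondOrder <- function(stream, expanded_references = list()) {
  stopifnot(is(stream, "SecondOrderStream"))
  refIds <- vapply(expanded_references, function(s) s@seqId, 1L)
  type <- list(); pos <- list(); len <- list(); lit <- list()
  for (i in seq_along(stream@kind)) {
    if (stream@kind[i] == 0L) {
      slot <- match(stream@refId[i], refIds)
      if (is.na(slot))
        sgcCorruptionError(sprintf(
          "dangling second-order reference id %d", stream@refId[i]))
      r <- expanded_references[[slot]]
      sel <- (stream@tokPos[i] + 1L):(stream@tokPos[i] + stream@tokCount[i])
      if (max(sel) > nTokens(r))
        sgcCorruptionError(sprintf(
          "RefMatch slice outside reference stream %d", stream@refId[i]))
      type[[i]] <- r@type[sel]; pos[[i]] <- r@pos[sel]
      len[[i]] <- r@len[sel]; lit[[i]] <- r@lit[sel]
    } else {
      type[[i]] <- stream@foType[i]; pos[[i]] <- stream@foPos[i]
      len[[i]] <- stream@foLen[i]; lit[[i]] <- stream@foLit[i]
    }
  }
  new("FirstOrderStream", seqId = stream@seqId,
      type = as.integer(unlist(type)), pos = as.integer(unlist(pos)),
      len = as.integer(unlist(len)),
      lit = as.character(unlist(lit)))
}

#' Expand a chain of second-order reference streams
#'
#' Expands chained reference streams front to back; stream i may reference
#' only seq_ids earlier in the chain (forward references raise a corruption
#' error through the dangling-id check).
#'
#' @param refStreams list of \linkS4class{SecondOrderStream} in seq_id order.
#' @return list of expanded \linkS4class{FirstOrderStream}.
#' @export
expandReferenceChain <- function(refStreams) {
  expanded <- list()
  for (s in refStreams)
    expanded[[length(expanded) + 1L]] <- decompressSecondOrder(s, expanded)
  expanded
}
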