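# S4 classes for the central data objects.

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Auxiliary data of one FASTA record
#'
#' Everything in a FASTA record besides its uppercase-ACGT base stream:
#' identifier, line layout (dominant width plus exceptions), soft-masked
#' (lowercase) intervals, N-run intervals, and rare non-ACGTN symbols.
#' Interval coordinates are 0-based and each auxiliary stream records
#' positions in the coordinate frame that exists at its own extraction step,
#' so reconstruction applies them in reverse order without remapping:
#' lowercase intervals and special-character positions live in the full
#' unwrapped symbol stream; N-run intervals live in the stream after special
#' symbols were removed.
#'
#' @slot identifier header line without the leading \code{>}.
#' @slot totalLength unwrapped symbol count of the record.
#' @slot nLines number of sequence lines.
#' @slot lineWidth dominant line width (bases per line).
#' @slot lineExceptions integer matrix (line index 0-based, length) of lines
#'   whose length differs from \code{lineWidth}.
#' @slot lowercase integer matrix (start, length) of lowercase runs.
#' @slot nRuns integer matrix (start, length) of \code{N} runs.
#' @slot specialPos 0-based positions of non-ACGTN symbols (after case
#'   folding).
#' @slot specialChars the folded symbols at those positions, as a character
#'   vector of single characters.
#' @slot finalNewline does the record end with a newline.
#' @export
setClass("AuxiliaryData",
  representation(identifier = "character", totalLength = "integer",
                 nLines = "integer", lineWidth = "integer",
                 lineExceptions = "matrix", lowercase = "matrix",
                 nRuns = "matrix", specialPos = "integer",
                 specialChars = "character", finalNewline = "logical"),
  prototype(identifier = "", totalLength = 0L, nLines = 0L, lineWidth = 0L,
            lineExceptions = matrix(integer(), ncol = 2),
            lowercase = matrix(integer(), ncol = 2),
            nRuns = matrix(integer(), ncol = 2),
            specialPos = integer(), specialChars = character(),
            finalNewline = TRUE))

.checkIntervals <- function(m, what) {
  if (ncol(m) != 2) return(sprintf("%s must have two columns", what))
  if (nrow(m) == 0) return(NULL)
  if (any(m[, 2] < 1)) return(sprintf("%s lengths must be >= 1", what))
  if (any(m[, 1] < 0)) return(sprintf("%s starts must be >= 0", what))
  ends <- m[, 1] + m[, 2]
  if (nrow(m) > 1 && any(m[-1, 1] < ends[-nrow(m)]))
    return(sprintf("%s must be sorted and non-overlapping", what))
  NULL
}

setValidity("AuxiliaryData", function(object) {
  msgs <- c(.checkIntervals(object@lowercase, "lowercase intervals"),
            .checkIntervals(object@nRuns, "N intervals"))
  if (length(object@specialPos) > 1 && any(diff(object@specialPos) <= 0))
    msgs <- c(msgs, "special positions must be strictly increasing")
  if (length(object@specialPos) != length(object@specialChars))
    msgs <- c(msgs, "special positions and symbols differ in length")
  if (length(msgs)) msgs else TRUE
})

#' A FASTA record split into base and auxiliary data
#'
#' @slot seqId 0-based ordinal of the record within the collection.
#' @slot base pure uppercase-ACGT base stream (single character string).
#' @slot aux an \linkS4class{AuxiliaryData}.
#' @export
setClass("SequenceRecord",
  representation(seqId = "integer", base = "character", aux = "AuxiliaryData"),
  prototype(seqId = 0L, base = ""))

setValidity("SequenceRecord", function(object) {
  if (grepl("[^ACGT]", object@base)) return("base stream contains non-ACGT symbols")
  expected <- nchar(object@base) + sum(object@aux@nRuns[, 2]) +
    length(object@aux@specialPos)
  if (expected != object@aux@totalLength)
    return("base length + N-run length + special count != total symbol count")
  TRUE
})

#' k-mer index of a reference base stream
#'
#' Hash index from every k-mer (2-bit packed) of the reference base stream to
#' the ordered list of its 0-based start positions. Held in native memory via
#' an external pointer; never serialized (decompression needs no index).
#'
#' @slot ptr external pointer to the native index.
#' @slot k k-mer length in bases.
#' @slot refLength length of the indexed stream.
#' @slot refFingerprint 8-byte content hash of the indexed stream.
#' @export
setClass("KmerIndex",
  representation(ptr = "externalptr", k = "integer", refLength = "numeric",
                 refFingerprint = "raw"))

#' First-order token stream
#'
#' Ordered tokens, each either a \code{Match(position, length)} into the
#' reference or a \code{Literal} of unmatched bases, stored column-wise:
#' \code{type} (0 match, 1 literal), \code{pos} (0-based reference start, NA
#' for literals), \code{len} (match length, or literal length), \code{lit}
#' (literal string, NA for matches). Concatenating reference spans and
#' literals in order reproduces the target base stream exactly.
#'
#' @slot seqId sequence ordinal.
#' @slot type,pos,len integer token columns.
#' @slot lit character token column.
#' @export
setClass("FirstOrderStream",
  representation(seqId = "integer", type = "integer", pos = "integer",
                 len = "integer", lit = "character"),
  prototype(seqId = 0L, type = integer(), pos = integer(), len = integer(),
            lit = character()))

setValidity("FirstOrderStream", function(object) {
  n <- length(object@type)
  if (length(object@pos) != n || length(object@len) != n || length(object@lit) != n)
    return("token columns differ in length")
  if (n && !all(object@type %in% c(0L, 1L))) return("token type must be 0 or 1")
  isLit <- object@type == 1L
  if (any(isLit & is.na(object@lit))) return("literal token without string")
  if (any(!isLit & is.na(object@pos))) return("match token without position")
  if (n > 1 && any(isLit[-1] & isLit[-n])) return("adjacent literals must be merged")
  TRUE
})

#' Second-order token stream
#'
#' Ordered tokens, each either a \code{RefMatch(ref_seq_id, token_position,
#' token_count)} into a second-order reference's first-order token list, or a
#' \code{Passthrough} first-order token. Stored column-wise: \code{kind} (0
#' RefMatch, 1 Passthrough), the RefMatch columns \code{refId},
#' \code{tokPos}, \code{tokCount}, and the embedded first-order columns
#' \code{foType}, \code{foPos}, \code{foLen}, \code{foLit} (NA where not
#' applicable).
#'
#' @slot seqId sequence ordinal.
#' @slot isReference is this stream one of the second-order references.
#' @slot kind,refId,tokPos,tokCount,foType,foPos,foLen integer token columns.
#' @slot foLit character token column.
#' @export
setClass("SecondOrderStream",
  representation(seqId = "integer", isReference = "logical", kind = "integer",
                 refId = "integer", tokPos = "integer", tokCount = "integer",
                 foType = "integer", foPos = "integer", foLen = "integer",
                 foLit = "character"),
  prototype(seqId = 0L, isReference = FALSE))

setValidity("SecondOrderStream", function(object) {
  n <- length(object@kind)
  lens <- c(length(object@refId), length(object@tokPos), length(object@tokCount),
            length(object@foType), length(object@foPos), length(object@foLen),
            length(object@foLit))
  if (any(lens != n)) return("token columns differ in length")
  if (n && !all(object@kind %in% c(0L, 1L))) return("token kind must be 0 or 1")
  rm <- object@kind == 0L
  if (any(rm & (is.na(object@refId) | is.na(object@tokPos) | is.na(object@tokCount))))
    return("RefMatch token with missing fields")
  TRUE
})

#' Token index over second-order references
#'
#' Maps a fingerprint of one first-order token to the ordered list of
#' (reference seq_id, token position) locations holding an equal token.
#' Native-memory object; also stores the reference token streams so runs can
#' be extended by exact token comparison.
#'
#' @slot ptr external pointer to the native index.
#' @export
setClass("TokenIndex", representation(ptr = "externalptr"))

#' Handle to an on-disk archive
#'
#' Parsed header, file manifest and block index of a \code{.sgc} archive;
#' block payloads stay on disk and are read selectively.
#'
#' @slot path archive file path.
#' @slot version format version.
#' @slot backend entropy backend identifier.
#' @slot k,S,minRun compression parameters stored in the header.
#' @slot nSeq number of sequences.
#' @slot refFingerprint 8-byte content hash of the reference base stream.
#' @slot files data.frame (name, nRecords, crlf) describing the original
#'   input files.
#' @slot blockLengths compressed block sizes, in seq_id order.
#' @slot blockOffsets absolute byte offset of each block.
#' @slot blockChecksums list of 8-byte per-block checksums.
#' @slot headerBytes bytes occupied by header + manifest + index.
#' @export
setClass("GenomeArchive",
  representation(path = "character", version = "integer", backend = "character",
                 k = "integer", S = "integer", minRun = "integer",
                 nSeq = "integer", refFingerprint = "raw", files = "data.frame",
                 blockLengths = "numeric", blockOffsets = "numeric",
                 blockChecksums = "list", headerBytes = "numeric"))

# ---------------------------------------------------------------------------
# generics and accessors
# ---------------------------------------------------------------------------

#' @describeIn FirstOrderStream-class sequence ordinal
#' @param x a stream, record or archive object.
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
setMethod("seqId", "FirstOrderStream", function(x) x@seqId)
setMethod("seqId", "SecondOrderStream", function(x) x@seqId)
setMethod("seqId", "SequenceRecord", function(x) x@seqId)

#' Number of tokens in a stream
#' @param x a \linkS4class{FirstOrderStream} or \linkS4class{SecondOrderStream}.
#' @export
setGeneric("nTokens", function(x) standardGeneric("nTokens"))
setMethod("nTokens", "FirstOrderStream", function(x) length(x@type))
setMethod("nTokens", "SecondOrderStream", function(x) length(x@kind))

#' Token columns of a stream as a data.frame
#' @param x a stream object.
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
setMethod("tokens", "FirstOrderStream", function(x)
  data.frame(type = x@type, pos = x@pos, len = x@len, lit = x@lit,
             stringsAsFactors = FALSE))
setMethod("tokens", "SecondOrderStream", function(x)
  data.frame(kind = x@kind, refId = x@refId, tokPos = x@tokPos,
             tokCount = x@tokCount, foType = x@foType, foPos = x@foPos,
             foLen = x@foLen, foLit = x@foLit, stringsAsFactors = FALSE))

#' k-mer length of an index
#' @param x a \linkS4class{KmerIndex}.
#' @export
kmerSize <- function(x) x@k

#' Length of the stream a \linkS4class{KmerIndex} was built from
#' @param x a \linkS4class{KmerIndex}.
#' @export
refLength <- function(x) x@refLength

#' Base stream of a \linkS4class{SequenceRecord}
#' @param x a \linkS4class{SequenceRecord}.
#' @export
baseStream <- function(x) x@base

#' Auxiliary data of a \linkS4class{SequenceRecord}
#' @param x a \linkS4class{SequenceRecord}.
#' @export
auxData <- function(x) x@aux

setMethod("show", "SequenceRecord", function(object) {
  cat(sprintf("SequenceRecord #%d '%s': %s bases, %d N run(s), %d special(s), %d lowercase run(s)\n",
              object@seqId, object@aux@identifier,
              format(nchar(object@base), big.mark = ","),
              nrow(object@aux@nRuns), length(object@aux@specialPos),
              nrow(object@aux@lowercase)))
})

setMethod("show", "KmerIndex", function(object) {
  info <- cpp_kmer_index_info(object@ptr)
  cat(sprintf("KmerIndex: k=%d over %s bases (%s stored positions, %s distinct k-mers)\n",
              object@k, format(object@refLength, big.mark = ","),
              format(info$n_positions, big.mark = ","),
              format(info$n_kmers, big.mark = ",")))
})

setMethod("show", "FirstOrderStream", function(object) {
  nm <- sum(object@type == 0L)
  cat(sprintf("FirstOrderStream #%d: %d tokens (%d matches, %d literals)\n",
              object@seqId, nTokens(object), nm, nTokens(object) - nm))
})

setMethod("show", "SecondOrderStream", function(object) {
  nr <- sum(object@kind == 0L)
  cat(sprintf("SecondOrderStream #%d%s: %d tokens (%d ref-matches, %d passthrough)\n",
              object@seqId, if (object@isReference) " [reference]" else "",
              nTokens(object), nr, nTokens(object) - nr))
})

setMethod("show", "GenomeArchive", function(object) {
  cat(sprintf("GenomeArchive '%s': %d sequence(s) in %d file(s)\n",
              object@path, object@nSeq, nrow(object@files)))
  cat(sprintf("  k=%d S=%d minRun=%d backend=%s version=%d\n",
              object@k, object@S, object@minRun, object@backend, object@version))
  cat(sprintf("  reference fingerprint %s\n",
              paste(format(object@refFingerprint), collapse = "")))
})
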