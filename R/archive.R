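# Indexed single-file archive container (.sgc).
#
# Layout:
#   magic "SGC1" | version u8 | backend u8 | header length u32 (LE)
#   header body: varints k, S, minRun, nSeq, nFiles
#                reference fingerprint (8 bytes)
#                per file: varint nameLen, name bytes, varint nRecords,
#                          flag byte (bit0 CRLF)
#                index: per sequence varint compressed block length,
#                       followed by an 8-byte block checksum
#   blocks: one entropy-coded payload per sequence, in seq_id order; the
#           blocks of the S chained second-order references form the shared
#           reference block group at the front.
#
# Each block payload is varint(auxLen) | aux bytes | serialized second-order
# token bytes; blocks are compressed independently so selective extraction
# stays cheap. All positions/lengths are 0-based half-open; deltas use
# zigzag varints.

.SGC_MAGIC <- charToRaw("SGC1")
.SGC_VERSION <- 1L
.BACKENDS <- c(gzip = 1L, bzip2 = 2L, xz = 3L)

#' Entropy-coding backends
#'
#' The final stage compresses every block with a pluggable general-purpose
#' backend; the default is bzip2, a block-sorting compressor. The backend
#' identifier is recorded in the archive header, so decompression needs no
#' flag.
#'
#' @param payload raw vector.
#' @param backend one of \code{"gzip"}, \code{"bzip2"}, \code{"xz"}.
#' @return \code{entropyCompress}: compressed raw vector;
#'   \code{entropyDecompress}: the original payload.
#' @export
entropyCompress <- function(payload, backend = "bzip2") {
  if (!backend %in% names(.BACKENDS))
    sgcConfigError(sprintf("unknown entropy backend '%s'", backend))
  memCompress(payload, type = backend)
}

#' @rdname entropyCompress
#' @export
entropyDecompress <- function(payload, backend = "bzip2") {
  if (!backend %in% names(.BACKENDS))
    sgcConfigError(sprintf("unknown entropy backend '%s'", backend))
  tryCatch(memDecompress(payload, type = backend),
           error = function(e) sgcCorruptionError(
             sprintf("block failed to decompress: %s", conditionMessage(e))))
}

#' Registered entropy backends
#' @return character vector of backend identifiers.
#' @export
entropyBackends <- function() names(.BACKENDS)

# serialize one sequence's block payload (uncompressed)
.blockPayload <- function(soStream, auxBytes) {
  so <- cpp_serialize_so(soStream@kind, soStream@refId, soStream@tokPos,
                         soStream@tokCount, soStream@foType, soStream@foPos,
                         soStream@foLen, soStream@foLit)
  c(encodeVarint(length(auxBytes)), auxBytes, so)
}

.parseBlockPayload <- function(payload, seqId, isReference) {
  r <- readVarints(payload, 0, 1)
  auxLen <- r$values
  if (r$offset + auxLen > length(payload))
    sgcCorruptionError("truncated block payload")
  auxBytes <- if (auxLen > 0) payload[(r$offset + 1):(r$offset + auxLen)] else raw()
  soBytes <- if (r$offset + auxLen < length(payload))
    payload[(r$offset + auxLen + 1):length(payload)] else raw()
  cols <- tryCatch(cpp_deserialize_so(soBytes),
                   error = function(e) sgcCorruptionError(conditionMessage(e)))
  stream <- new("SecondOrderStream", seqId = as.integer(seqId),
                isReference = isReference, kind = cols$kind, refId = cols$refId,
                tokPos = cols$tokPos, tokCount = cols$tokCount,
                foType = cols$foType, foPos = cols$foPos, foLen = cols$foLen,
                foLit = cols$foLit)
  list(stream = stream, aux = auxBytes)
}

#' Serialize compressed streams into an archive file
#'
#' Writes header, file manifest, block index and one independently
#' entropy-coded block per sequence.
#'
#' @param second_order list of \linkS4class{SecondOrderStream} in seq_id
#'   order.
#' @param aux list of encoded auxiliary byte vectors, same order.
#' @param path output file path.
#' @param k,S,minRun compression parameters recorded in the header.
#' @param backend entropy backend identifier.
#' @param refFingerprint 8-byte content hash of the reference base stream.
#' @param files data.frame with columns \code{name}, \code{nRecords},
#'   \code{crlf} describing the original input files.
#' @return invisibly, a list with the archive \code{path},
#'   \code{preEntropyTokenBytes} (serialized token bytes before entropy
#'   coding) and \code{blockLengths}.
#' @export
serializeStreams <- function(second_order, aux, path, k, S, minRun,
                             backend = "bzip2", refFingerprint = raw(8),
                             files = data.frame(name = character(),
                                                nRecords = integer(),
                                                crlf = logical())) {
  if (!backend %in% names(.BACKENDS))
    sgcConfigError(sprintf("unknown entropy backend '%s'", backend))
  nSeq <- length(second_order)
  stopifnot(length(aux) == nSeq)

  payloads <- vector("list", nSeq)
  preEntropy <- 0
  for (i in seq_len(nSeq)) {
    payloads[[i]] <- .blockPayload(second_order[[i]], aux[[i]])
    preEntropy <- preEntropy + length(payloads[[i]])
  }
  blocks <- lapply(payloads, entropyCompress, backend = backend)
  checksums <- lapply(blocks, fingerprintBytes)

  manifest <- raw()
  for (i in seq_len(nrow(files))) {
    nm <- charToRaw(as.character(files$name[i]))
    manifest <- c(manifest, encodeVarint(length(nm)), nm,
                  encodeVarint(files$nRecords[i]),
                  as.raw(as.integer(files$crlf[i])))
  }
  index <- raw()
  for (i in seq_len(nSeq))
    index <- c(index, encodeVarint(length(blocks[[i]])), checksums[[i]])

  headerBody <- c(encodeVarint(c(k, S, minRun, nSeq, nrow(files))),
                  refFingerprint, manifest, index)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.SGC_MAGIC, con)
  writeBin(as.raw(c(.SGC_VERSION, .BACKENDS[[backend]])), con)
  writeBin(length(headerBody), con, size = 4, endian = "little")
  writeBin(headerBody, con)
  for (b in blocks) writeBin(b, con)
  invisible(list(path = path, preEntropyTokenBytes = preEntropy,
                 blockLengths = vapply(blocks, length, 1L)))
}

#' Open an archive and parse its header and index
#'
#' Reads only the header, file manifest and block index; block payloads are
#' left on disk for selective extraction.
#'
#' @param path archive file path.
#' @return a \linkS4class{GenomeArchive}.
#' @export
openArchive <- function(path) {
  if (!file.exists(path)) sgcIOError(sprintf("cannot read archive '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readBin(con, "raw", 10)
  if (length(fixed) < 10 || !identical(fixed[1:4], .SGC_MAGIC))
    sgcFormatError("not an sgc archive (bad magic bytes)")
  version <- as.integer(fixed[5])
  if (version != .SGC_VERSION)
    sgcFormatError(sprintf("unsupported archive version %d", version))
  backendId <- as.integer(fixed[6])
  backend <- names(.BACKENDS)[match(backendId, .BACKENDS)]
  if (is.na(backend))
    sgcConfigError(sprintf("archive uses unregistered backend id %d", backendId))
  headerLen <- readBin(fixed[7:10], "integer", 1, size = 4, endian = "little")
  body <- readBin(con, "raw", headerLen)
  if (length(body) < headerLen) sgcCorruptionError("truncated archive header")

  r <- readVarints(body, 0, 5)
  k <- as.integer(r$values[1]); S <- as.integer(r$values[2])
  minRun <- as.integer(r$values[3]); nSeq <- as.integer(r$values[4])
  nFiles <- as.integer(r$values[5])
  off <- r$offset
  fp <- body[(off + 1):(off + 8)]
  off <- off + 8

  names_ <- character(nFiles); nRecords <- integer(nFiles); crlf <- logical(nFiles)
  for (i in seq_len(nFiles)) {
    r <- readVarints(body, off, 1)
    nl <- r$values
    names_[i] <- if (nl > 0) rawToChar(body[(r$offset + 1):(r$offset + nl)]) else ""
    off <- r$offset + nl
    r <- readVarints(body, off, 1)
    nRecords[i] <- as.integer(r$values)
    off <- r$offset
    crlf[i] <- as.integer(body[off + 1]) != 0L
    off <- off + 1
  }
  lens <- numeric(nSeq)
  checks <- vector("list", nSeq)
  for (i in seq_len(nSeq)) {
    r <- readVarints(body, off, 1)
    lens[i] <- r$values
    off <- r$offset
    checks[[i]] <- body[(off + 1):(off + 8)]
    off <- off + 8
  }
  headerBytes <- 10 + headerLen
  offsets <- headerBytes + cumsum(c(0, lens[-length(lens)] * (nSeq > 0)))
  if (nSeq == 0) offsets <- numeric(0)
  new("GenomeArchive", path = path, version = version, backend = backend,
      k = k, S = S, minRun = minRun, nSeq = nSeq, refFingerprint = fp,
      files = data.frame(name = names_, nRecords = nRecords, crlf = crlf,
                         stringsAsFactors = FALSE),
      blockLengths = lens, blockOffsets = offsets, blockChecksums = checks,
      headerBytes = headerBytes)
}

# read n bytes at offset, adding to the byte counter environment if given
.readAt <- function(con, offset, n, counter = NULL) {
  seek(con, where = offset, origin = "start")
  b <- readBin(con, "raw", n)
  if (length(b) < n) sgcCorruptionError("unexpected end of archive")
  if (!is.null(counter)) counter$bytes <- counter$bytes + n
  b
}

#' Extract and decode one block of an archive
#'
#' Reads only that block from disk, verifies its checksum, reverses the
#' entropy coding and deserializes the second-order stream and auxiliary
#' bytes.
#'
#' @param archive a \linkS4class{GenomeArchive}.
#' @param seqId 0-based sequence id, \code{< archive@nSeq}.
#' @param con optional open binary connection to the archive file (reused
#'   across calls).
#' @param counter optional environment with a \code{bytes} field used to
#'   instrument bytes read.
#' @return list with \code{stream} (a \linkS4class{SecondOrderStream}) and
#'   \code{aux} (encoded auxiliary bytes).
#' @export
deserializeBlock <- function(archive, seqId, con = NULL, counter = NULL) {
  stopifnot(is(archive, "GenomeArchive"))
  if (seqId < 0 || seqId >= archive@nSeq)
    sgcUsageError(sprintf("seq_id %d out of range [0, %d)", seqId, archive@nSeq))
  i <- seqId + 1L
  ownCon <- is.null(con)
  if (ownCon) {
    con <- file(archive@path, "rb")
    on.exit(close(con))
  }
  block <- .readAt(con, archive@blockOffsets[i], archive@blockLengths[i], counter)
  if (!identical(fingerprintBytes(block), archive@blockChecksums[[i]]))
    sgcCorruptionError(sprintf("block %d is corrupt (checksum mismatch)", seqId))
  payload <- entropyDecompress(block, archive@backend)
  .parseBlockPayload(payload, seqId, seqId < archive@S)
}
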