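# FASTA parsing and the lossless base/auxiliary split.
#
# Extraction order is fixed: record line lengths -> fold lowercase to
# uppercase (recording intervals) -> remove non-ACGTN symbols (recording
# (position, symbol)) -> remove N runs (recording intervals). Reconstruction
# applies the inverse steps in reverse order. Each auxiliary stream records
# 0-based coordinates in the frame that exists at its own extraction step.

.ACGT_RAW <- charToRaw("ACGT")
.N_RAW <- as.raw(0x4E)

# (start0, length) runs of TRUE in a logical vector
.runsFromMask <- function(mask) {
  if (!any(mask)) return(matrix(integer(), ncol = 2))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  cbind(starts[sel] - 1L, r$lengths[sel])
}

.intervalIdx <- function(m) {
  if (nrow(m) == 0) return(integer())
  rep(m[, 1], m[, 2]) + (sequence(m[, 2]) - 1L) + 1L  # 1-based positions
}

.dominantWidth <- function(lens) {
  if (length(lens) == 0) return(0L)
  tab <- table(lens)
  cands <- as.integer(names(tab)[tab == max(tab)])
  if (length(cands) == 1) return(cands)
  # tie: the earliest line with a candidate length sets the convention
  cands[which.min(match(cands, lens))]
}

#' Split one FASTA record into base and auxiliary data
#'
#' Losslessly decomposes a FASTA record into a pure uppercase-ACGT base
#' stream and the auxiliary streams needed to reconstruct the original bytes
#' exactly: identifier, line layout, lowercase intervals, N-run intervals and
#' non-ACGTN symbols. \code{reconstructRecord} is its exact inverse.
#'
#' @param raw_record one FASTA record as a character scalar or raw vector
#'   (LF line endings; CRLF handling lives at the file level).
#' @param seqId ordinal to assign to the record.
#' @return a \linkS4class{SequenceRecord}.
#' @examples
#' rec <- splitRecord(">x\nacGTN\nNACG\n")
#' baseStream(rec)
#' reconstructRecord(rec)
#' @export
splitRecord <- function(raw_record, seqId = 0L) {
  txt <- if (is.raw(raw_record)) rawToChar(raw_record) else raw_record
  stopifnot(is.character(txt), length(txt) == 1)
  if (!startsWith(txt, ">"))
    sgcParseError("malformed FASTA record: expected '>' at byte offset 0")
  finalNewline <- endsWith(txt, "\n")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  if (any(startsWith(lines[-1], ">")))
    sgcParseError("splitRecord expects a single FASTA record")
  .splitParsedRecord(substring(lines[1], 2), lines[-1], finalNewline,
                     as.integer(seqId))
}

.splitParsedRecord <- function(identifier, seqLines, finalNewline, seqId) {
  lineLens <- nchar(seqLines, type = "bytes")
  width <- .dominantWidth(lineLens)
  excIdx <- which(lineLens != width)
  exceptions <- cbind(excIdx - 1L, lineLens[excIdx])
  if (length(excIdx) == 0) exceptions <- matrix(integer(), ncol = 2)

  stream <- paste(seqLines, collapse = "")
  sraw <- charToRaw(stream)

  lower <- sraw >= as.raw(0x61) & sraw <= as.raw(0x7A)
  folded <- sraw
  if (any(lower))
    folded[lower] <- as.raw(as.integer(folded[lower]) - 32L)
  lowercase <- .runsFromMask(lower)

  isN <- folded == .N_RAW
  isBase <- folded %in% .ACGT_RAW
  special <- !(isN | isBase)
  specialPos <- which(special) - 1L
  specialChars <- vapply(folded[special], rawToChar, character(1))

  kept <- folded[!special]
  isN2 <- isN[!special]
  nRuns <- .runsFromMask(isN2)
  base <- rawToChar(kept[!isN2])

  aux <- new("AuxiliaryData", identifier = identifier,
             totalLength = length(sraw), nLines = length(seqLines),
             lineWidth = width, lineExceptions = exceptions,
             lowercase = lowercase, nRuns = nRuns,
             specialPos = as.integer(specialPos),
             specialChars = specialChars, finalNewline = finalNewline)
  new("SequenceRecord", seqId = seqId, base = base, aux = aux)
}

#' Reconstruct the original FASTA record bytes
#'
#' Exact inverse of \code{\link{splitRecord}}: insert N runs, insert special
#' symbols, restore case, re-wrap lines, prepend the identifier.
#'
#' @param rec a \linkS4class{SequenceRecord}.
#' @return the record as a character scalar, byte-identical to the original
#'   (LF line endings).
#' @export
reconstructRecord <- function(rec) {
  aux <- rec@aux
  baseRaw <- charToRaw(rec@base)

  # 1. insert N runs (coords in the post-special-removal frame)
  n2 <- length(baseRaw) + sum(aux@nRuns[, 2])
  nIdx <- .intervalIdx(aux@nRuns)
  if (any(nIdx > n2)) sgcCorruptionError("N interval out of range")
  res <- raw(n2)
  res[nIdx] <- .N_RAW
  fill <- rep(TRUE, n2)
  fill[nIdx] <- FALSE
  if (sum(fill) != length(baseRaw)) sgcCorruptionError("N intervals inconsistent with base length")
  res[fill] <- baseRaw

  # 2. insert special symbols (coords in the post-fold frame)
  n3 <- n2 + length(aux@specialPos)
  spIdx <- aux@specialPos + 1L
  if (any(spIdx > n3)) sgcCorruptionError("special position out of range")
  res3 <- raw(n3)
  res3[spIdx] <- as.raw(vapply(aux@specialChars, function(ch) as.integer(charToRaw(ch)), 1L))
  fill <- rep(TRUE, n3)
  fill[spIdx] <- FALSE
  res3[fill] <- res
  if (n3 != aux@totalLength) sgcCorruptionError("reconstructed length differs from recorded total")

  # 3. restore case
  lowIdx <- .intervalIdx(aux@lowercase)
  if (any(lowIdx > n3)) sgcCorruptionError("lowercase interval out of range")
  if (length(lowIdx))
    res3[lowIdx] <- as.raw(as.integer(res3[lowIdx]) + 32L)

  # 4. re-wrap lines
  widths <- rep(aux@lineWidth, aux@nLines)
  if (nrow(aux@lineExceptions)) {
    ei <- aux@lineExceptions[, 1] + 1L
    if (any(ei > aux@nLines)) sgcCorruptionError("line exception out of range")
    widths[ei] <- aux@lineExceptions[, 2]
  }
  if (sum(widths) != n3) sgcCorruptionError("line layout does not cover the symbol stream")
  streamStr <- rawToChar(res3)
  if (aux@nLines > 0) {
    ends <- cumsum(widths)
    starts <- ends - widths + 1L
    seqLines <- substring(streamStr, starts, ends)
  } else {
    seqLines <- character()
  }

  paste0(paste(c(paste0(">", aux@identifier), seqLines), collapse = "\n"),
         if (aux@finalNewline) "\n" else "")
}

# ---------------------------------------------------------------------------
# whole-file parsing (multi-record, CRLF flag, record order via seqId)
# ---------------------------------------------------------------------------

#' Parse a FASTA file into split records
#'
#' Reads a (possibly multi-record) FASTA file at the byte level, detects the
#' line-ending convention once per file, and splits every record. Record
#' order is preserved through consecutive \code{seqId}s starting at
#' \code{firstSeqId}.
#'
#' @param path FASTA file path.
#' @param firstSeqId seqId assigned to the first record.
#' @return list with \code{records} (list of \linkS4class{SequenceRecord}),
#'   \code{crlf} (logical), and \code{name} (basename of \code{path}).
#' @export
splitFastaFile <- function(path, firstSeqId = 0L) {
  if (!file.exists(path)) sgcIOError(sprintf("cannot read input file '%s'", path))
  bytes <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(bytes)
  countFixed <- function(pat) length(gregexpr(pat, txt, fixed = TRUE)[[1]][
    gregexpr(pat, txt, fixed = TRUE)[[1]] > 0])
  nCR <- countFixed("\r")
  nCRLF <- countFixed("\r\n")
  nLF <- countFixed("\n")
  crlf <- nCRLF > 0
  if (nCR != nCRLF || (crlf && nLF != nCRLF))
    sgcParseError(sprintf("mixed or bare CR line endings in '%s'", path))
  if (crlf) txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  if (!startsWith(txt, ">")) {
    off <- 0L
    sgcParseError(sprintf("malformed FASTA in '%s': expected '>' at byte offset %d",
                          path, off))
  }
  finalNewline <- endsWith(txt, "\n")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  headerAt <- which(startsWith(lines, ">"))
  bounds <- c(headerAt, length(lines) + 1L)
  records <- vector("list", length(headerAt))
  for (i in seq_along(headerAt)) {
    h <- headerAt[i]
    seqLines <- if (bounds[i + 1] > h + 1L) lines[(h + 1L):(bounds[i + 1] - 1L)] else character()
    isLast <- i == length(headerAt)
    records[[i]] <- .splitParsedRecord(substring(lines[h], 2), seqLines,
                                       if (isLast) finalNewline else TRUE,
                                       as.integer(firstSeqId) + i - 1L)
  }
  list(records = records, crlf = crlf, name = basename(path))
}

# assemble reconstructed record texts back into file bytes
.assembleFile <- function(recordTexts, crlf) {
  txt <- paste(recordTexts, collapse = "")
  if (crlf) txt <- gsub("\n", "\r\n", txt, fixed = TRUE)
  charToRaw(txt)
}

# ---------------------------------------------------------------------------
# auxiliary data byte coding (delta-encoded varints)
# ---------------------------------------------------------------------------

.encIntervals <- function(m) {
  n <- nrow(m)
  if (n == 0) return(encodeVarint(0))
  c(encodeVarint(n), encodeVarint(c(m[1, 1], diff(m[, 1]))), encodeVarint(m[, 2]))
}

.decIntervals <- function(bytes, offset) {
  r <- readVarints(bytes, offset, 1)
  n <- r$values
  if (n == 0)
    return(list(m = matrix(integer(), ncol = 2), offset = r$offset))
  s <- readVarints(bytes, r$offset, n)
  l <- readVarints(bytes, s$offset, n)
  list(m = cbind(as.integer(cumsum(s$values)), as.integer(l$values)),
       offset = l$offset)
}

#' Byte coding of auxiliary data
#'
#' Serializes an \linkS4class{AuxiliaryData} to a compact byte stream using
#' delta-encoded variable-length integers; \code{decodeAuxiliary} is the
#' exact inverse.
#'
#' @param aux an \linkS4class{AuxiliaryData}.
#' @return \code{encodeAuxiliary}: a raw vector. \code{decodeAuxiliary}: an
#'   \linkS4class{AuxiliaryData}.
#' @export
encodeAuxiliary <- function(aux) {
  idRaw <- charToRaw(aux@identifier)
  spRaw <- if (length(aux@specialChars))
    as.raw(vapply(aux@specialChars, function(ch) as.integer(charToRaw(ch)), 1L))
  else raw()
  c(encodeVarint(length(idRaw)), idRaw,
    as.raw(as.integer(aux@finalNewline)),
    encodeVarint(c(aux@totalLength, aux@nLines, aux@lineWidth)),
    .encIntervals(aux@lineExceptions),
    .encIntervals(aux@lowercase),
    .encIntervals(aux@nRuns),
    encodeVarint(length(aux@specialPos)),
    if (length(aux@specialPos))
      encodeVarint(c(aux@specialPos[1], diff(aux@specialPos)))
    else raw(),
    spRaw)
}

#' @rdname encodeAuxiliary
#' @param bytes raw vector produced by \code{encodeAuxiliary}.
#' @export
decodeAuxiliary <- function(bytes) {
  r <- readVarints(bytes, 0, 1)
  idLen <- r$values
  if (r$offset + idLen + 1 > length(bytes))
    sgcCorruptionError("truncated auxiliary stream")
  identifier <- if (idLen > 0) rawToChar(bytes[(r$offset + 1):(r$offset + idLen)]) else ""
  off <- r$offset + idLen
  finalNewline <- as.integer(bytes[off + 1]) != 0L
  off <- off + 1
  r <- readVarints(bytes, off, 3)
  totalLength <- as.integer(r$values[1]); nLines <- as.integer(r$values[2])
  lineWidth <- as.integer(r$values[3])
  exc <- .decIntervals(bytes, r$offset)
  low <- .decIntervals(bytes, exc$offset)
  nr <- .decIntervals(bytes, low$offset)
  r <- readVarints(bytes, nr$offset, 1)
  nSpec <- r$values
  specialPos <- integer(); specialChars <- character()
  off <- r$offset
  if (nSpec > 0) {
    s <- readVarints(bytes, off, nSpec)
    specialPos <- as.integer(cumsum(s$values))
    off <- s$offset
    if (off + nSpec > length(bytes)) sgcCorruptionError("truncated auxiliary stream")
    specialChars <- vapply(bytes[(off + 1):(off + nSpec)], rawToChar, character(1))
    off <- off + nSpec
  }
  new("AuxiliaryData", identifier = identifier, totalLength = totalLength,
      nLines = nLines, lineWidth = lineWidth, lineExceptions = exc$m,
      lowercase = low$m, nRuns = nr$m, specialPos = specialPos,
      specialChars = specialChars, finalNewline = finalNewline)
}
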