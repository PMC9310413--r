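# End-to-end compression and (selective) decompression of a collection.
#
# Stage order: (1) pre-process the reference and build its k-mer index;
# (2) first-order compress all targets — each an independent task sharing
# the read-only reference and index; (3) select, chain-compress and index
# the second-order references (serial), then second-order compress the
# remaining sequences concurrently; (4) serialize and entropy-code.
# Results are collected and serialized in seq_id order regardless of task
# completion order, so archive bytes are invariant under the worker count.

#' Compression configuration
#'
#' @param k k-mer length for first-order anchors (>= 4).
#' @param S number of second-order references (>= 0; clamped to the
#'   collection size; default 40).
#' @param minRun minimum second-order run length in tokens (default 2).
#' @param backend entropy backend identifier (see
#'   \code{\link{entropyBackends}}).
#' @param workers number of parallel workers for the per-sequence stages
#'   (forked processes; > 1 requires a unix-alike, otherwise tasks run
#'   serially).
#' @param maxOcc per-k-mer occurrence cap for the reference index.
#' @return a validated configuration list.
#' @export
sgcConfig <- function(k = 14L, S = 40L, minRun = 2L, backend = "bzip2",
                      workers = 1L, maxOcc = Inf) {
  k <- as.integer(k); S <- as.integer(S); minRun <- as.integer(minRun)
  workers <- as.integer(workers)
  if (is.na(k) || k < 4L || k > 31L) sgcConfigError("k must be in [4, 31]")
  if (is.na(S) || S < 0L) sgcConfigError("S must be >= 0")
  if (is.na(minRun) || minRun < 1L) sgcConfigError("minRun must be >= 1")
  if (is.na(workers) || workers < 1L) sgcConfigError("workers must be >= 1")
  if (!backend %in% entropyBackends())
    sgcConfigError(sprintf("unknown entropy backend '%s'", backend))
  list(k = k, S = S, minRun = minRun, backend = backend, workers = workers,
       maxOcc = maxOcc)
}

.applyWorkers <- function(X, FUN, workers) {
  if (workers > 1L && .Platform$OS.type == "unix" && length(X) > 1) {
    res <- parallel::mclapply(X, FUN, mc.cores = workers, mc.preschedule = TRUE)
    bad <- vapply(res, inherits, TRUE, "try-error")
    if (any(bad)) stop(attr(res[[which(bad)[1]]], "condition"))
    res
  } else {
    lapply(X, FUN)
  }
}

# reference base stream = concatenated base data of all records in the file
.referenceBaseStream <- function(referencePath) {
  parsed <- splitFastaFile(referencePath)
  paste(vapply(parsed$records, baseStream, character(1)), collapse = "")
}

#' Compress a collection of genome sequences
#'
#' Runs the full two-order pipeline against a reference genome and writes a
#' single indexed \code{.sgc} archive. Lossless: decompression reproduces
#' every input file byte for byte.
#'
#' @param reference path to the reference genome FASTA (multi-record
#'   references are concatenated into one base stream).
#' @param targets character vector of to-be-compressed FASTA paths; each
#'   file may hold several records, and every record becomes one sequence of
#'   the collection in file-then-record order.
#' @param output archive path to write.
#' @param config a configuration from \code{\link{sgcConfig}}.
#' @param force overwrite an existing \code{output}.
#' @param verbose print per-stage timings to stderr.
#' @return invisibly, a summary list: \code{inputBytes}, \code{outputBytes},
#'   \code{ratio}, \code{nSeq}, \code{S}, \code{preEntropyTokenBytes}, and
#'   \code{timings} (seconds per stage).
#' @export
compressCollection <- function(reference, targets, output,
                               config = sgcConfig(), force = FALSE,
                               verbose = FALSE) {
  if (length(targets) == 0) sgcUsageError("no target sequences given")
  if (file.exists(output) && !force)
    sgcUsageError(sprintf("output '%s' exists; use force = TRUE to overwrite", output))
  for (p in c(reference, targets))
    if (!file.exists(p)) sgcIOError(sprintf("cannot read input file '%s'", p))

  timings <- c(pre = 0, first = 0, second = 0, post = 0)
  tic <- function() proc.time()[["elapsed"]]

  # stage 1: pre-process reference, build index
  t0 <- tic()
  refBase <- .referenceBaseStream(reference)
  idx <- buildKmerIndex(refBase, k = config$k, maxOcc = config$maxOcc)
  timings["pre"] <- tic() - t0

  # stage 2: parse + split targets, first-order compress each record
  t0 <- tic()
  fileMeta <- list()
  records <- list()
  nextId <- 0L
  for (p in targets) {
    parsed <- splitFastaFile(p, firstSeqId = nextId)
    fileMeta[[length(fileMeta) + 1L]] <-
      data.frame(name = parsed$name, nRecords = length(parsed$records),
                 crlf = parsed$crlf, stringsAsFactors = FALSE)
    records <- c(records, parsed$records)
    nextId <- nextId + length(parsed$records)
  }
  files <- do.call(rbind, fileMeta)
  firstOrder <- .applyWorkers(records, function(rec) {
    compressFirstOrder(baseStream(rec), refBase, idx, seqId = rec@seqId)
  }, config$workers)
  timings["first"] <- tic() - t0

  # stage 3: second order — chain-compress references serially, then the rest
  t0 <- tic()
  sel <- selectSecondOrderReferences(firstOrder, config$S)
  Seff <- length(sel$references)
  chain <- chainCompressReferences(sel$references, minRun = config$minRun)
  nonRef <- .applyWorkers(sel$non_references, function(s) {
    compressSecondOrder(s, chain$index, minRun = config$minRun)
  }, config$workers)
  secondOrder <- c(chain$streams, nonRef)
  timings["second"] <- tic() - t0

  # stage 4: serialize + entropy-code
  t0 <- tic()
  auxBytes <- lapply(records, function(rec) encodeAuxiliary(auxData(rec)))
  res <- serializeStreams(secondOrder, auxBytes, output, k = config$k,
                          S = Seff, minRun = config$minRun,
                          backend = config$backend,
                          refFingerprint = idx@refFingerprint, files = files)
  timings["post"] <- tic() - t0

  inputBytes <- sum(file.size(targets))
  outputBytes <- file.size(output)
  if (verbose)
    message(sprintf(
      "compressed %d sequence(s): %s -> %s bytes (ratio %.1f:1) [pre %.2fs, first %.2fs, second %.2fs, post %.2fs]",
      length(records), format(inputBytes, big.mark = ","),
      format(outputBytes, big.mark = ","), inputBytes / outputBytes,
      timings["pre"], timings["first"], timings["second"], timings["post"]))
  invisible(list(inputBytes = inputBytes, outputBytes = outputBytes,
                 ratio = inputBytes / outputBytes, nSeq = length(records),
                 S = Seff, preEntropyTokenBytes = res$preEntropyTokenBytes,
                 timings = timings, path = output))
}

# which blocks must be read to reconstruct the requested ids
.blocksNeeded <- function(ids, S) {
  if (length(ids) == 0) return(integer())
  if (any(ids >= S)) refUpper <- S - 1L
  else refUpper <- max(ids)  # every requested id is a reference
  sort(unique(c(if (refUpper >= 0) 0:refUpper, ids)))
}

#' Decompress sequences from an archive
#'
#' Reconstructs sequences byte-exactly from an archive plus the same
#' reference genome used at compression (verified by content fingerprint).
#' With \code{ids = NULL} every sequence is restored and the original input
#' files are rewritten under \code{outdir}. With a seq_id vector only those
#' records are reconstructed — reading only the header, index, the needed
#' reference blocks and the requested blocks — and each is written as
#' \code{seq_<id>.fa}. Decompression is single-threaded by design: it is
#' I/O-bound and needs no index.
#'
#' @param archive path to a \code{.sgc} archive.
#' @param reference path to the reference genome FASTA.
#' @param outdir output directory (created if missing).
#' @param ids optional integer vector of 0-based sequence ids.
#' @param verbose print a summary to stderr.
#' @return invisibly, a list: \code{files} written, \code{bytesRead} from
#'   the archive, \code{blocksRead} (0-based ids, in read order).
#' @export
decompressCollection <- function(archive, reference, outdir, ids = NULL,
                                 verbose = FALSE) {
  arc <- openArchive(archive)
  counter <- new.env()
  counter$bytes <- arc@headerBytes

  refBase <- .referenceBaseStream(reference)
  if (!identical(fingerprintBytes(refBase), arc@refFingerprint))
    sgcWrongReferenceError(
      "reference fingerprint mismatch: this is not the reference the archive was compressed against")

  if (is.null(ids)) {
    wanted <- seq_len(arc@nSeq) - 1L
  } else {
    wanted <- as.integer(ids)
    if (any(is.na(wanted) | wanted < 0L | wanted >= arc@nSeq))
      sgcUsageError(sprintf("seq_id out of range [0, %d)", arc@nSeq))
  }
  needed <- .blocksNeeded(wanted, arc@S)

  con <- file(arc@path, "rb")
  on.exit(close(con))

  # expand the reference chain front to back; keep only what is needed
  expandedRefs <- list()
  decoded <- list()  # seqId -> list(stream, aux) for requested ids
  for (b in needed) {
    blk <- deserializeBlock(arc, b, con = con, counter = counter)
    if (b < arc@S) {
      fo <- decompressSecondOrder(blk$stream, expandedRefs)
      expandedRefs[[length(expandedRefs) + 1L]] <- fo
      if (b %in% wanted) decoded[[as.character(b)]] <- list(fo = fo, aux = blk$aux)
    } else {
      fo <- decompressSecondOrder(blk$stream, expandedRefs)
      decoded[[as.character(b)]] <- list(fo = fo, aux = blk$aux)
    }
  }

  rebuildRecord <- function(b) {
    d <- decoded[[as.character(b)]]
    aux <- decodeAuxiliary(d$aux)
    base <- decompressFirstOrder(d$fo, refBase)
    rec <- new("SequenceRecord", seqId = b, base = base, aux = aux)
    reconstructRecord(rec)
  }

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character()
  if (is.null(ids)) {
    # regroup records into the original files
    cursor <- 0L
    for (i in seq_len(nrow(arc@files))) {
      n <- arc@files$nRecords[i]
      recIds <- cursor + seq_len(n) - 1L
      texts <- vapply(recIds, rebuildRecord, character(1))
      out <- file.path(outdir, arc@files$name[i])
      writeBin(.assembleFile(texts, arc@files$crlf[i]), out)
      written <- c(written, out)
      cursor <- cursor + n
    }
  } else {
    fileOfSeq <- rep(seq_len(nrow(arc@files)), arc@files$nRecords)
    for (b in wanted) {
      txt <- rebuildRecord(b)
      out <- file.path(outdir, sprintf("seq_%d.fa", b))
      writeBin(.assembleFile(txt, arc@files$crlf[fileOfSeq[b + 1L]]), out)
      written <- c(written, out)
    }
  }
  if (verbose)
    message(sprintf("decompressed %d record(s), read %s of %s archive bytes (%d block(s))",
                    length(wanted), format(counter$bytes, big.mark = ","),
                    format(file.size(archive), big.mark = ","), length(needed)))
  invisible(list(files = written, bytesRead = counter$bytes,
                 blocksRead = needed))
}

#' List the contents of an archive
#'
#' Prints header fields and per-sequence compressed block sizes.
#'
#' @param archive path to a \code{.sgc} archive.
#' @return invisibly, a data.frame with one row per sequence.
#' @export
listArchive <- function(archive) {
  arc <- openArchive(archive)
  show(arc)
  df <- data.frame(seqId = seq_len(arc@nSeq) - 1L,
                   isReference = seq_len(arc@nSeq) - 1L < arc@S,
                   compressedBytes = arc@blockLengths)
  if (arc@nSeq > 0) {
    cat(sprintf("  %d reference block(s), %s total block bytes\n",
                min(arc@S, arc@nSeq), format(sum(arc@blockLengths), big.mark = ",")))
    print(head(df, 20), row.names = FALSE)
    if (arc@nSeq > 20) cat(sprintf("  ... %d more\n", arc@nSeq - 20))
  }
  invisible(df)
}
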