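# Synthetic reference genomes and mutated collections with the statistical
# structure the compressor exploits: high inter-sequence similarity (a star
# phylogeny of independent mutants), soft-masked runs, N runs, rare
# ambiguity symbols and fixed-width line wrapping. Every sequence carries a
# plain-text mutation log sufficient to rebuild it from the reference, and
# the generator replays the log as a self-check.

#' Mutation profile for the collection generator
#'
#' @param snpRate per-base substitution probability.
#' @param insRate,delRate per-base insertion/deletion event probabilities.
#' @param indelGeomP geometric parameter for indel lengths (length is
#'   1 + Geom(p), so mean 1/p).
#' @param softmaskFraction expected fraction of bases inside lowercase runs.
#' @param softmaskMeanRun mean soft-mask run length in bases.
#' @param nRunRate per-base probability of starting an N run.
#' @param nRunMeanLen mean N-run length in bases.
#' @param specialRate per-base probability of an ambiguity symbol.
#' @param lineWidth FASTA wrap width.
#' @param seed integer seed; together with the sequence ordinal it fully
#'   determines each output.
#' @return a validated profile list.
#' @export
mutationProfile <- function(snpRate = 1e-3, insRate = 1e-4, delRate = 1e-4,
                            indelGeomP = 0.5, softmaskFraction = 0.05,
                            softmaskMeanRun = 300, nRunRate = 1e-5,
                            nRunMeanLen = 50, specialRate = 1e-6,
                            lineWidth = 60L, seed = 42L) {
  rates <- c(snpRate, insRate, delRate, indelGeomP, softmaskFraction,
             specialRate, nRunRate)
  if (any(rates < 0 | rates > 1))
    sgcConfigError("all rates must lie in [0, 1]")
  if (lineWidth < 1) sgcConfigError("lineWidth must be >= 1")
  list(snpRate = snpRate, insRate = insRate, delRate = delRate,
       indelGeomP = indelGeomP, softmaskFraction = softmaskFraction,
       softmaskMeanRun = softmaskMeanRun, nRunRate = nRunRate,
       nRunMeanLen = nRunMeanLen, specialRate = specialRate,
       lineWidth = as.integer(lineWidth), seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")
.SPECIALS <- c("R", "Y", "K", "M", "S", "W", "B", "D", "H", "V")

.writeWrapped <- function(path, identifier, seqStr, width) {
  n <- nchar(seqStr)
  if (n == 0) {
    writeLines(paste0(">", identifier), path)
    return(invisible(path))
  }
  starts <- seq(1L, n, by = width)
  lines <- substring(seqStr, starts, pmin(starts + width - 1L, n))
  writeLines(c(paste0(">", identifier), lines), path)
  invisible(path)
}

#' Generate a random reference genome
#'
#' Uniform ACGT composition, fixed line width, fully determined by the
#' seed.
#'
#' @param path output FASTA path.
#' @param length sequence length in bases (0 gives a header-only record).
#' @param seed integer seed.
#' @param width FASTA wrap width.
#' @param identifier header text.
#' @return invisibly, \code{path}.
#' @export
generateReference <- function(path, length, seed = 42L, width = 60L,
                              identifier = "reference") {
  stopifnot(length >= 0)
  set.seed(as.integer(seed))
  seqStr <- if (length > 0)
    paste(sample(.BASES, length, replace = TRUE), collapse = "") else ""
  .writeWrapped(path, identifier, seqStr, width)
}

# thin overlapping (start, len) events, keeping earlier starts
.thinRuns <- function(starts, lens, maxLen) {
  keep <- logical(length(starts))
  prevEnd <- 0L
  o <- order(starts)
  for (i in o) {
    if (starts[i] > prevEnd && starts[i] + lens[i] - 1L <= maxLen) {
      keep[i] <- TRUE
      prevEnd <- starts[i] + lens[i] - 1L
    }
  }
  list(starts = starts[keep][order(starts[keep])],
       lens = lens[keep][order(starts[keep])])
}

# apply logged mutations to a reference character vector; shared by the
# generator and the replay self-check
.applyMutationLog <- function(refChars, log) {
  x <- refChars
  if (nrow(log$snp)) x[log$snp$pos + 1L] <- log$snp$new
  events <- rbind(
    if (nrow(log$ins)) data.frame(pos = log$ins$pos, type = "I",
                                  payload = log$ins$seq, len = NA_integer_)
    else NULL,
    if (nrow(log$del)) data.frame(pos = log$del$pos, type = "D",
                                  payload = NA_character_, len = log$del$len)
    else NULL)
  if (!is.null(events) && nrow(events)) {
    events <- events[order(events$pos, events$type), , drop = FALSE]
    pieces <- character(0)
    cur <- 1L
    for (i in seq_len(nrow(events))) {
      p <- events$pos[i] + 1L  # 1-based position the event acts at
      if (p > cur) pieces <- c(pieces, paste(x[cur:(p - 1L)], collapse = ""))
      if (events$type[i] == "I") {
        pieces <- c(pieces, events$payload[i])
        cur <- p
      } else {
        cur <- p + events$len[i]
      }
    }
    if (cur <= length(x)) pieces <- c(pieces, paste(x[cur:length(x)], collapse = ""))
    y <- strsplit(paste(pieces, collapse = ""), "")[[1]]
  } else {
    y <- x
  }
  # decorations, in the mutated coordinate frame: N runs, specials, then case
  if (nrow(log$nrun)) {
    idx <- unlist(mapply(function(s, l) s:(s + l - 1L), log$nrun$pos,
                         log$nrun$len, SIMPLIFY = FALSE)) + 1L
    y[idx] <- "N"
  }
  if (nrow(log$spc)) y[log$spc$pos + 1L] <- log$spc$char
  if (nrow(log$mask)) {
    idx <- unlist(mapply(function(s, l) s:(s + l - 1L), log$mask$pos,
                         log$mask$len, SIMPLIFY = FALSE)) + 1L
    y[idx] <- tolower(y[idx])
  }
  paste(y, collapse = "")
}

.writeMutationLog <- function(path, identifier, width, log) {
  lines <- c(paste("ID", identifier), paste("WIDTH", width))
  if (nrow(log$snp))
    lines <- c(lines, sprintf("SNP %d %s", log$snp$pos, log$snp$new))
  if (nrow(log$ins))
    lines <- c(lines, sprintf("INS %d %s", log$ins$pos, log$ins$seq))
  if (nrow(log$del))
    lines <- c(lines, sprintf("DEL %d %d", log$del$pos, log$del$len))
  if (nrow(log$nrun))
    lines <- c(lines, sprintf("NRUN %d %d", log$nrun$pos, log$nrun$len))
  if (nrow(log$spc))
    lines <- c(lines, sprintf("SPC %d %s", log$spc$pos, log$spc$char))
  if (nrow(log$mask))
    lines <- c(lines, sprintf("MASK %d %d", log$mask$pos, log$mask$len))
  writeLines(lines, path)
}

#' Replay a mutation log against the reference
#'
#' Rebuilds a derived sequence (decorations included) from the reference and
#' a mutation log written by \code{\link{generateCollection}}; used as the
#' generator's self-check oracle.
#'
#' @param refSeq reference sequence string (uppercase ACGT).
#' @param logPath path to the plain-text mutation log.
#' @return the derived sequence as a single string.
#' @export
replayMutationLog <- function(refSeq, logPath) {
  lines <- readLines(logPath)
  fields <- strsplit(lines, " ", fixed = TRUE)
  tag <- vapply(fields, `[[`, "", 1)
  get2 <- function(t) as.integer(vapply(fields[tag == t], `[[`, "", 2))
  get3 <- function(t) vapply(fields[tag == t], `[[`, "", 3)
  log <- list(
    snp = data.frame(pos = get2("SNP"), new = get3("SNP")),
    ins = data.frame(pos = get2("INS"), seq = get3("INS")),
    del = data.frame(pos = get2("DEL"), len = as.integer(get3("DEL"))),
    nrun = data.frame(pos = get2("NRUN"), len = as.integer(get3("NRUN"))),
    spc = data.frame(pos = get2("SPC"), char = get3("SPC")),
    mask = data.frame(pos = get2("MASK"), len = as.integer(get3("MASK"))))
  .applyMutationLog(strsplit(refSeq, "")[[1]], log)
}

#' Generate a collection of mutated genome sequences
#'
#' Derives \code{n} sequences independently from the reference (star
#' phylogeny: sampled substitutions and geometric-length indels), decorates
#' them with soft-masked runs, N runs and rare ambiguity symbols, wraps at
#' the profile's line width, and writes one FASTA plus one mutation log per
#' sequence. Each emitted FASTA is verified against its replayed log before
#' return.
#'
#' @param refPath reference FASTA path (as written by
#'   \code{\link{generateReference}}).
#' @param outDir output directory (created if missing).
#' @param n number of sequences.
#' @param profile a \code{\link{mutationProfile}}.
#' @return a data.frame with columns \code{seqId}, \code{fasta}, \code{log}.
#' @export
generateCollection <- function(refPath, outDir, n, profile = mutationProfile()) {
  parsed <- splitFastaFile(refPath)
  refSeq <- paste(vapply(parsed$records, baseStream, character(1)), collapse = "")
  refChars <- if (nchar(refSeq)) strsplit(refSeq, "")[[1]] else character()
  L <- length(refChars)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(profile$seed + i - 1L)
    # substitutions in the reference frame
    snpPos <- which(runif(L) < profile$snpRate)
    oldB <- refChars[snpPos]
    shift <- sample(1:3, length(snpPos), replace = TRUE)
    newB <- .BASES[(match(oldB, .BASES) - 1L + shift) %% 4L + 1L]
    # indel events in the reference frame
    insPos <- which(runif(L) < profile$insRate)
    insLen <- rgeom(length(insPos), profile$indelGeomP) + 1L
    insSeq <- vapply(insLen, function(l)
      paste(sample(.BASES, l, replace = TRUE), collapse = ""), character(1))
    delPos <- which(runif(L) < profile$delRate)
    delLen <- rgeom(length(delPos), profile$indelGeomP) + 1L
    dels <- .thinRuns(delPos, delLen, L)
    # drop insertions falling inside a deleted span
    if (length(insPos) && length(dels$starts)) {
      inDel <- vapply(insPos, function(p)
        any(p > dels$starts & p <= dels$starts + dels$lens - 1L), TRUE)
      insPos <- insPos[!inDel]; insSeq <- insSeq[!inDel]
    }

    log <- list(
      snp = data.frame(pos = snpPos - 1L, new = newB,
                       stringsAsFactors = FALSE)[seq_along(snpPos), , drop = FALSE],
      ins = data.frame(pos = insPos - 1L, seq = insSeq, stringsAsFactors = FALSE),
      del = data.frame(pos = dels$starts - 1L, len = dels$lens),
      nrun = data.frame(pos = integer(), len = integer()),
      spc = data.frame(pos = integer(), char = character(),
                       stringsAsFactors = FALSE),
      mask = data.frame(pos = integer(), len = integer()))

    mutated <- .applyMutationLog(refChars, log)
    L2 <- nchar(mutated)

    # decorations in the mutated frame
    if (L2 > 0) {
      nMaskRuns <- rpois(1, profile$softmaskFraction * L2 / profile$softmaskMeanRun)
      if (nMaskRuns > 0) {
        ms <- sample.int(L2, nMaskRuns, replace = TRUE)
        ml <- rgeom(nMaskRuns, 1 / profile$softmaskMeanRun) + 1L
        m <- .thinRuns(ms, ml, L2)
        log$mask <- data.frame(pos = m$starts - 1L, len = m$lens)
      }
      nrPos <- which(runif(L2) < profile$nRunRate)
      if (length(nrPos)) {
        nrLen <- rgeom(length(nrPos), 1 / profile$nRunMeanLen) + 1L
        nr <- .thinRuns(nrPos, nrLen, L2)
        log$nrun <- data.frame(pos = nr$starts - 1L, len = nr$lens)
      }
      spPos <- which(runif(L2) < profile$specialRate)
      if (length(spPos))
        log$spc <- data.frame(pos = spPos - 1L,
                              char = sample(.SPECIALS, length(spPos), replace = TRUE),
                              stringsAsFactors = FALSE)
    }

    final <- .applyMutationLog(refChars, log)
    identifier <- sprintf("seq_%03d", i - 1L)
    fa <- file.path(outDir, sprintf("seq_%03d.fa", i - 1L))
    lg <- file.path(outDir, sprintf("seq_%03d.log", i - 1L))
    .writeWrapped(fa, identifier, final, profile$lineWidth)
    .writeMutationLog(lg, identifier, profile$lineWidth, log)
    # self-check: replaying the log must reproduce the emitted sequence
    if (!identical(replayMutationLog(refSeq, lg), final))
      sgcCorruptionError(sprintf("mutation log replay mismatch for %s", identifier))
    out[[i]] <- data.frame(seqId = i - 1L, fasta = fa, log = lg,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' The frozen standard test fixture
#'
#' The collection used throughout the test suite: a 1 Mb random reference
#' and 50 derived sequences (SNP 1e-3, insertions/deletions 1e-4 with
#' geometric p = 0.5 lengths, 5\% soft-masked at mean run 300, N-run rate
#' 1e-5 at mean length 50, ambiguity-symbol rate 1e-6, width 60, seed 42).
#'
#' @param dir directory to generate into.
#' @param refLength reference length in bases.
#' @param n number of derived sequences.
#' @param seed integer seed.
#' @return list with \code{reference} (path) and \code{collection} (the
#'   data.frame from \code{\link{generateCollection}}).
#' @export
standardFixture <- function(dir, refLength = 1e6, n = 50L, seed = 42L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  refPath <- file.path(dir, "reference.fa")
  generateReference(refPath, refLength, seed = seed)
  coll <- generateCollection(refPath, file.path(dir, "collection"), n,
                             mutationProfile(seed = seed))
  list(reference = refPath, collection = coll)
}
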