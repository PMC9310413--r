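test_that("splitRecord decomposes simple records as expected", {
  rec <- splitRecord(">x\nACGT\n")
  expect_identical(baseStream(rec), "ACGT")
  aux <- auxData(rec)
  expect_identical(aux@identifier, "x")
  expect_identical(aux@lineWidth, 4L)
  expect_identical(nrow(aux@lowercase), 0L)
  expect_identical(nrow(aux@nRuns), 0L)
  expect_length(aux@specialPos, 0)

  rec <- splitRecord(">x\nACRT\n")
  expect_identical(baseStream(rec), "ACT")
  expect_identical(auxData(rec)@specialPos, 2L)
  expect_identical(auxData(rec)@specialChars, "R")
})

test_that("extraction order is lines, case, specials, then N removal", {
  rec <- splitRecord(">x\nacGTN\nNACG\n")
  aux <- auxData(rec)
  expect_identical(baseStream(rec), "ACGTACG")
  expect_identical(aux@lowercase, cbind(0L, 2L))
  expect_identical(aux@nRuns, cbind(4L, 2L))
  expect_identical(aux@lineWidth, 5L)
  expect_identical(aux@lineExceptions, cbind(1L, 4L))
  # the split must invert exactly
  expect_identical(reconstructRecord(rec), ">x\nacGTN\nNACG\n")
})

test_that("malformed records raise a parse error naming the offset", {
  expect_error(splitRecord("ACGT\n"), class = "sgc_parse_error")
  expect_error(splitRecord("ACGT\n"), "byte offset 0")
  tf <- withr::local_tempfile(lines = "no header here")
  expect_error(splitFastaFile(tf), class = "sgc_parse_error")
})

test_that("split/reconstruct round-trips randomized records byte-exactly", {
  set.seed(421)
  for (i in 1:500) {
    txt <- randomRecordText()
    expect_identical(reconstructRecord(splitRecord(txt)), txt)
  }
})

test_that("degenerate records survive the split", {
  for (txt in c(">empty\n", ">empty",
                paste0(">allN\n", strrep("N", 120), "\n"),
                paste0(">allN\n", strrep("n", 120), "\n"),
                paste0(">lower\n", strrep("acgt", 30), "\n"),
                ">x\n\nACGT\n")) {
    rec <- splitRecord(txt)
    expect_identical(reconstructRecord(rec), txt)
  }
  expect_identical(baseStream(splitRecord(paste0(">allN\n", strrep("N", 120), "\n"))), "")
})

test_that("multi-record files keep record order through seqId", {
  txt <- ">a\nACGT\nAC\n>b\nGGTT\n>c desc\nacgt\n"
  tf <- withr::local_tempfile()
  writeBin(charToRaw(txt), tf)
  parsed <- splitFastaFile(tf, firstSeqId = 10L)
  expect_identical(vapply(parsed$records, seqId, 1L), c(10L, 11L, 12L))
  expect_identical(vapply(parsed$records, function(r) auxData(r)@identifier,
                          ""), c("a", "b", "c desc"))
  rebuilt <- sgc:::.assembleFile(vapply(parsed$records, reconstructRecord, ""),
                                 parsed$crlf)
  expect_identical(rebuilt, charToRaw(txt))
})

test_that("CRLF files are detected and restored via the file-level flag", {
  txt <- ">a\r\nACGT\r\nAC\r\n>b\r\nGGTT\r\n"
  tf <- withr::local_tempfile()
  writeBin(charToRaw(txt), tf)
  parsed <- splitFastaFile(tf)
  expect_true(parsed$crlf)
  rebuilt <- sgc:::.assembleFile(vapply(parsed$records, reconstructRecord, ""),
                                 parsed$crlf)
  expect_identical(rebuilt, charToRaw(txt))
  # mixed endings are refused rather than silently corrupted
  tf2 <- withr::local_tempfile()
  writeBin(charToRaw(">a\r\nACGT\nAC\r\n"), tf2)
  expect_error(splitFastaFile(tf2), class = "sgc_parse_error")
})

test_that("auxiliary byte coding is the identity on AuxiliaryData", {
  roundtrip <- function(aux) decodeAuxiliary(encodeAuxiliary(aux))
  empty <- new("AuxiliaryData")
  expect_equal(roundtrip(empty), empty)

  # identifier with spaces and tabs survives verbatim
  rec <- splitRecord(">id with spaces\tand tab\nACGT\n")
  expect_equal(roundtrip(auxData(rec)), auxData(rec))

  # many random valid intervals
  set.seed(99)
  starts <- cumsum(sample(1:50, 1000, replace = TRUE) + 3L)
  lens <- sample(1:3, 1000, replace = TRUE)
  aux <- new("AuxiliaryData", identifier = "big", totalLength = 1000000L,
             nLines = 10L, lineWidth = 100000L,
             lowercase = cbind(as.integer(starts), as.integer(lens)),
             nRuns = cbind(as.integer(starts + 100000L), as.integer(lens)),
             specialPos = as.integer(starts + 500000L),
             specialChars = sample(c("R", "Y", "W"), 1000, replace = TRUE),
             finalNewline = FALSE)
  expect_equal(roundtrip(aux), aux)

  # truncation is detected
  enc <- encodeAuxiliary(auxData(rec))
  expect_error(decodeAuxiliary(enc[1:3]), class = "sgc_corruption_error")
})

test_that("split satisfies the symbol-count invariant", {
  set.seed(7)
  for (i in 1:25) {
    txt <- randomRecordText()
    rec <- splitRecord(txt)
    aux <- auxData(rec)
    expect_identical(nchar(baseStream(rec)) + sum(aux@nRuns[, 2]) +
                       length(aux@specialPos), aux@totalLength)
    expect_true(validObject(rec))
  }
})
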