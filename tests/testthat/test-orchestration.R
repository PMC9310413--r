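test_that("mixed input files round-trip byte-exactly through the archive", {
  dir <- withr::local_tempdir()
  ref <- file.path(dir, "ref.fa")
  generateReference(ref, 5000, seed = 71)
  refSeq <- baseStream(splitFastaFile(ref)$records[[1]])

  set.seed(72)
  # multi-record file, CRLF file, file without trailing newline
  f1 <- file.path(dir, "multi.fa")
  writeBin(charToRaw(paste0(">m1 first\n", mutateSnp(refSeq, 0.01), "\n",
                            ">m2 second\nacgtNNNacgt\n")), f1)
  f2 <- file.path(dir, "crlf.fa")
  writeBin(charToRaw(gsub("\n", "\r\n",
                          paste0(">w\n", substr(refSeq, 1, 333), "\n"))), f2)
  f3 <- file.path(dir, "nonl.fa")
  writeBin(charToRaw(paste0(">t\n", mutateSnp(substr(refSeq, 100, 2099), 0.005))),
           f3)
  targets <- c(f1, f2, f3)
  arc <- file.path(dir, "a.sgc")
  compressCollection(ref, targets, arc, config = sgcConfig(S = 2, k = 10))
  out <- file.path(dir, "out")
  res <- decompressCollection(arc, ref, out)
  for (f in targets)
    expect_true(filesIdentical(f, file.path(out, basename(f))))
  expect_identical(openArchive(arc)@nSeq, 4L)
})

test_that("archive bytes are invariant under the worker count", {
  dir <- withr::local_tempdir()
  fx <- makeSmallCollection(dir, n = 12, refLen = 6000)
  a1 <- file.path(dir, "w1.sgc"); a4 <- file.path(dir, "w4.sgc")
  compressCollection(fx$reference, fx$collection$fasta, a1,
                     config = sgcConfig(S = 4, k = 10, workers = 1))
  compressCollection(fx$reference, fx$collection$fasta, a4,
                     config = sgcConfig(S = 4, k = 10, workers = 4))
  expect_true(filesIdentical(a1, a4))
})

test_that("usage guards: empty targets, existing output, bad ids", {
  dir <- withr::local_tempdir()
  fx <- makeSmallCollection(dir, n = 2)
  arc <- file.path(dir, "a.sgc")
  expect_error(compressCollection(fx$reference, character(), arc),
               class = "sgc_usage_error")
  expect_false(file.exists(arc))
  compressCollection(fx$reference, fx$collection$fasta, arc,
                     config = sgcConfig(k = 10))
  expect_error(compressCollection(fx$reference, fx$collection$fasta, arc,
                                  config = sgcConfig(k = 10)),
               class = "sgc_usage_error")
  expect_silent(compressCollection(fx$reference, fx$collection$fasta, arc,
                                   config = sgcConfig(k = 10), force = TRUE))
  expect_error(decompressCollection(arc, fx$reference, file.path(dir, "o"),
                                    ids = 7), class = "sgc_usage_error")
  expect_error(compressCollection(file.path(dir, "missing.fa"),
                                  fx$collection$fasta, file.path(dir, "b.sgc")),
               class = "sgc_io_error")
})

test_that("selective extraction matches the corresponding full record", {
  dir <- withr::local_tempdir()
  fx <- makeSmallCollection(dir, n = 8, refLen = 5000)
  arc <- file.path(dir, "a.sgc")
  compressCollection(fx$reference, fx$collection$fasta, arc,
                     config = sgcConfig(S = 3, k = 10))
  full <- decompressCollection(arc, fx$reference, file.path(dir, "full"))
  sel <- decompressCollection(arc, fx$reference, file.path(dir, "sel"), ids = 6)
  expect_identical(sel$blocksRead, c(0L, 1L, 2L, 6L))
  expect_true(filesIdentical(sel$files[1], file.path(dir, "full", "seq_006.fa")))
  expect_lt(sel$bytesRead, file.size(arc))
})

test_that("a near-identical 1 Mb target compresses beyond 100:1", {
  dir <- withr::local_tempdir()
  ref <- file.path(dir, "ref.fa")
  generateReference(ref, 1e6, seed = 73)
  tgt <- file.path(dir, "t.fa")
  refSeq <- baseStream(splitFastaFile(ref)$records[[1]])
  sgc:::.writeWrapped(tgt, "t", refSeq, 60L)
  arc <- file.path(dir, "a.sgc")
  res <- compressCollection(ref, tgt, arc, config = sgcConfig(S = 1))
  expect_gte(res$ratio, 100)
  out <- decompressCollection(arc, ref, file.path(dir, "out"))
  expect_true(filesIdentical(tgt, out$files[1]))
})

test_that("the command-line wrapper reports usage errors with exit code 2", {
  cli <- system.file("cli", "sgc.R", package = "sgc")
  expect_true(nzchar(cli))
  status <- system2("Rscript", c(cli, "frobnicate"), stdout = FALSE,
                    stderr = FALSE)
  expect_identical(status, 2L)
})
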