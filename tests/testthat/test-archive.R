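test_that("varint coding follows the 7-bit continuation form", {
  expect_identical(encodeVarint(0), as.raw(0))
  expect_identical(length(encodeVarint(300)), 2L)
  expect_identical(decodeVarint(encodeVarint(300), 1), 300)
  expect_identical(decodeVarint(encodeVarint(127), 1), 127)
  expect_identical(length(encodeVarint(128)), 2L)
})

test_that("varint round-trips large random batches, zigzag included", {
  set.seed(61)
  u <- c(0, 1, 127, 128, 300, sample.int(2^30, 1e4), 2^40 + 7)
  expect_identical(decodeVarint(encodeVarint(u), length(u)), as.numeric(u))
  s <- c(0, -1, 1, -(2^20), sample(-1e6:1e6, 1e4))
  expect_identical(decodeVarint(encodeVarint(s, zigzag = TRUE), length(s),
                                zigzag = TRUE), as.numeric(s))
  expect_error(decodeVarint(encodeVarint(2^40)[1:2], 1),
               class = "sgc_corruption_error")
  expect_error(encodeVarint(-1), "negative")
})

test_that("entropy backends invert exactly and squeeze redundancy", {
  for (b in entropyBackends()) {
    expect_identical(entropyDecompress(entropyCompress(raw(0), b), b), raw(0))
    zeros <- raw(1e6)
    comp <- entropyCompress(zeros, b)
    expect_lt(length(comp), 1e4)  # < 1% of input
    expect_identical(entropyDecompress(comp, b), zeros)
    set.seed(62)
    payload <- as.raw(sample(0:255, 5000, replace = TRUE))
    expect_identical(entropyDecompress(entropyCompress(payload, b), b), payload)
  }
  expect_error(entropyCompress(raw(3), "snappy"), class = "sgc_config_error")
  expect_error(entropyDecompress(raw(3), "snappy"), class = "sgc_config_error")
})

test_that("second-order stream serialization is the identity", {
  set.seed(63)
  ref <- randBase(3000)
  idx <- buildKmerIndex(ref, k = 10)
  fo <- lapply(0:4, function(i)
    compressFirstOrder(mutateSnp(ref, 0.01), ref, idx, seqId = i))
  chain <- chainCompressReferences(fo[1:2])
  so <- c(chain$streams,
          lapply(fo[3:5], compressSecondOrder, idx = chain$index))
  for (s in so) {
    bytes <- sgc:::cpp_serialize_so(s@kind, s@refId, s@tokPos, s@tokCount,
                                    s@foType, s@foPos, s@foLen, s@foLit)
    back <- sgc:::cpp_deserialize_so(bytes)
    expect_identical(back$kind, s@kind)
    expect_identical(back$refId, s@refId)
    expect_identical(back$tokPos, s@tokPos)
    expect_identical(back$tokCount, s@tokCount)
    expect_identical(back$foType, s@foType)
    expect_identical(back$foPos, s@foPos)
    expect_identical(back$foLen, s@foLen)
    expect_identical(back$foLit, s@foLit)
  }
  # empty stream
  empty <- sgc:::cpp_deserialize_so(sgc:::cpp_serialize_so(
    integer(), integer(), integer(), integer(), integer(), integer(),
    integer(), character()))
  expect_length(empty$kind, 0)
})

test_that("archives round-trip header, index and every block", {
  dir <- withr::local_tempdir()
  fx <- makeSmallCollection(dir, n = 5)
  arc <- file.path(dir, "a.sgc")
  compressCollection(fx$reference, fx$collection$fasta, arc,
                     config = sgcConfig(S = 2, k = 10))
  a <- openArchive(arc)
  expect_identical(a@nSeq, 5L)
  expect_identical(a@S, 2L)
  expect_identical(a@k, 10L)
  expect_identical(nrow(a@files), 5L)
  expect_identical(sum(a@blockLengths) + a@headerBytes, file.size(arc))
  # block offsets tile the file without overlap
  expect_identical(a@blockOffsets,
                   a@headerBytes + cumsum(c(0, a@blockLengths[-5])))
  for (i in 0:4) {
    blk <- deserializeBlock(a, i)
    expect_s4_class(blk$stream, "SecondOrderStream")
    expect_identical(seqId(blk$stream), i)
    expect_identical(blk$stream@isReference, i < 2)
    aux <- decodeAuxiliary(blk$aux)
    expect_identical(aux@identifier, sprintf("seq_%03d", i))
  }
  expect_error(deserializeBlock(a, 5), class = "sgc_usage_error")
})

test_that("an empty collection still forms a valid archive", {
  dir <- withr::local_tempdir()
  arc <- file.path(dir, "empty.sgc")
  serializeStreams(list(), list(), arc, k = 14, S = 0, minRun = 2,
                   refFingerprint = raw(8))
  a <- openArchive(arc)
  expect_identical(a@nSeq, 0L)
  expect_length(a@blockLengths, 0)
})

test_that("a tampered block fails alone; other blocks still extract", {
  dir <- withr::local_tempdir()
  fx <- makeSmallCollection(dir, n = 4)
  arc <- file.path(dir, "a.sgc")
  compressCollection(fx$reference, fx$collection$fasta, arc,
                     config = sgcConfig(S = 1, k = 10))
  a <- openArchive(arc)
  bytes <- readFileBytes(arc)
  off <- a@blockOffsets[3] + 2   # inside block of seq_id 2
  bytes[off] <- xor(bytes[off], as.raw(0xFF))
  tampered <- file.path(dir, "t.sgc")
  writeBin(bytes, tampered)
  ta <- openArchive(tampered)
  expect_error(deserializeBlock(ta, 2), class = "sgc_corruption_error")
  for (i in c(0L, 1L, 3L))
    expect_s4_class(deserializeBlock(ta, i)$stream, "SecondOrderStream")
})

test_that("format and reference errors are classified", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.sgc")
  writeBin(charToRaw("NOTSGC----------"), bad)
  expect_error(openArchive(bad), class = "sgc_format_error")

  fx <- makeSmallCollection(dir, n = 3)
  arc <- file.path(dir, "a.sgc")
  compressCollection(fx$reference, fx$collection$fasta, arc,
                     config = sgcConfig(k = 10))
  otherRef <- file.path(dir, "other.fa")
  generateReference(otherRef, 4000, seed = 999)
  expect_error(decompressCollection(arc, otherRef, file.path(dir, "out")),
               class = "sgc_wrong_reference_error")
})
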