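# helper: first-order streams for a small mutant collection
makeStreams <- function(n, refLen = 2000, snpRate = 0.01, k = 10L, seed = 51) {
  set.seed(seed)
  ref <- randBase(refLen)
  idx <- buildKmerIndex(ref, k = k)
  streams <- lapply(seq_len(n) - 1L, function(i)
    compressFirstOrder(mutateSnp(ref, snpRate), ref, idx, seqId = i))
  list(ref = ref, idx = idx, streams = streams)
}

test_that("reference selection takes the first S streams, clamped", {
  ms <- makeStreams(10)
  sel <- selectSecondOrderReferences(ms$streams, S = 4)
  expect_identical(vapply(sel$references, seqId, 1L), 0:3)
  expect_identical(vapply(sel$non_references, seqId, 1L), 4:9)

  sel <- selectSecondOrderReferences(ms$streams, S = 40)
  expect_length(sel$references, 10)
  expect_length(sel$non_references, 0)

  sel <- selectSecondOrderReferences(ms$streams, S = 0)
  expect_length(sel$references, 0)
  expect_length(sel$non_references, 10)
})

test_that("token index holds every reference token exactly once", {
  ms <- makeStreams(3)
  idx <- buildTokenIndex(ms$streams)
  info <- tokenIndexInfo(idx)
  expect_identical(info$n_locations,
                   as.numeric(sum(vapply(ms$streams, nTokens, 1L))))
  expect_identical(info$seq_ids, 0:2)

  # two identical references: every fingerprint lists paired locations in order
  s <- ms$streams[[1]]
  s2 <- new("FirstOrderStream", seqId = 1L, type = s@type, pos = s@pos,
            len = s@len, lit = s@lit)
  idx2 <- buildTokenIndex(list(s, s2))
  tok <- tokens(s)
  for (i in head(seq_len(nrow(tok)), 20)) {
    hits <- tokenLookup(idx2, tok$type[i], tok$pos[i], tok$len[i], tok$lit[i])
    expect_identical(sort(unique(hits[, "refSeqId"])), 0:1)
    h0 <- hits[hits[, "refSeqId"] == 0L, "tokenPosition"]
    h1 <- hits[hits[, "refSeqId"] == 1L, "tokenPosition"]
    expect_identical(h0, h1)
    expect_true((i - 1L) %in% h0)
  }
})

test_that("every indexed location verifies token equality", {
  ms <- makeStreams(4, seed = 52)
  idx <- buildTokenIndex(ms$streams)
  for (s in ms$streams) {
    tok <- tokens(s)
    for (i in seq_len(nrow(tok))) {
      hits <- tokenLookup(idx, tok$type[i], tok$pos[i], tok$len[i], tok$lit[i])
      for (r in seq_len(nrow(hits))) {
        other <- tokens(ms$streams[[hits[r, "refSeqId"] + 1L]])
        j <- hits[r, "tokenPosition"] + 1L
        expect_identical(other$type[j], tok$type[i])
        if (tok$type[i] == 0L) {
          expect_identical(other$pos[j], tok$pos[i])
          expect_identical(other$len[j], tok$len[i])
        } else {
          expect_identical(other$lit[j], tok$lit[i])
        }
      }
    }
  }
})

test_that("a target identical to a reference collapses to one RefMatch", {
  ms <- makeStreams(2)
  ref0 <- ms$streams[[1]]
  expect_gte(nTokens(ref0), 2)
  idx <- buildTokenIndex(list(ref0))
  target <- new("FirstOrderStream", seqId = 5L, type = ref0@type,
                pos = ref0@pos, len = ref0@len, lit = ref0@lit)
  so <- compressSecondOrder(target, idx)
  expect_identical(nTokens(so), 1L)
  expect_identical(tokens(so)$kind, 0L)
  expect_identical(tokens(so)$refId, 0L)
  expect_identical(tokens(so)$tokPos, 0L)
  expect_identical(tokens(so)$tokCount, nTokens(ref0))
  back <- decompressSecondOrder(so, list(ref0))
  expect_identical(tokens(back), tokens(target))
})

test_that("targets sharing no token pass through unchanged", {
  ms <- makeStreams(1)
  idx <- buildTokenIndex(ms$streams)
  alien <- new("FirstOrderStream", seqId = 9L, type = c(1L, 0L, 1L),
               pos = c(NA, 999999L, NA), len = c(3L, 50L, 2L),
               lit = c("AAA", NA, "CC"))
  so <- compressSecondOrder(alien, idx)
  expect_true(all(tokens(so)$kind == 1L))
  back <- decompressSecondOrder(so, ms$streams)
  expect_identical(tokens(back), tokens(alien))
})

test_that("runs shorter than minRun stay passthrough", {
  one <- new("FirstOrderStream", seqId = 0L, type = 0L, pos = 0L, len = 20L,
             lit = NA_character_)
  idx <- buildTokenIndex(list(one))
  target <- new("FirstOrderStream", seqId = 1L, type = 0L, pos = 0L,
                len = 20L, lit = NA_character_)
  so <- compressSecondOrder(target, idx, minRun = 2L)
  expect_identical(tokens(so)$kind, 1L)
  so1 <- compressSecondOrder(target, idx, minRun = 1L)
  expect_identical(tokens(so1)$kind, 0L)
})

test_that("chain compression references only earlier streams and inverts", {
  ms <- makeStreams(1)
  chain <- chainCompressReferences(ms$streams)
  expect_true(all(tokens(chain$streams[[1]])$kind == 1L))

  s <- ms$streams[[1]]
  s2 <- new("FirstOrderStream", seqId = 1L, type = s@type, pos = s@pos,
            len = s@len, lit = s@lit)
  chain <- chainCompressReferences(list(s, s2))
  expect_identical(nTokens(chain$streams[[2]]), 1L)
  expect_identical(tokens(chain$streams[[2]])$refId, 0L)

  ms <- makeStreams(40, snpRate = 0.002, seed = 53)
  chain <- chainCompressReferences(ms$streams)
  for (i in seq_along(chain$streams)) {
    tok <- tokens(chain$streams[[i]])
    rm <- tok$kind == 0L
    if (any(rm)) expect_true(all(tok$refId[rm] < i - 1L))
  }
  expanded <- expandReferenceChain(chain$streams)
  for (i in seq_along(expanded))
    expect_identical(tokens(expanded[[i]]), tokens(ms$streams[[i]]))
})

test_that("the full two-order pipeline is the identity on streams", {
  ms <- makeStreams(20, snpRate = 0.001, seed = 54)
  sel <- selectSecondOrderReferences(ms$streams, S = 7)
  chain <- chainCompressReferences(sel$references)
  expanded <- expandReferenceChain(chain$streams)
  for (s in sel$non_references) {
    so <- compressSecondOrder(s, chain$index)
    back <- decompressSecondOrder(so, expanded)
    expect_identical(tokens(back), tokens(s))
    expect_identical(decompressFirstOrder(back, ms$ref),
                     decompressFirstOrder(s, ms$ref))
  }
})

test_that("dangling reference ids raise a corruption error naming the id", {
  so <- new("SecondOrderStream", seqId = 3L, kind = 0L, refId = 17L,
            tokPos = 0L, tokCount = 2L, foType = NA_integer_,
            foPos = NA_integer_, foLen = NA_integer_, foLit = NA_character_)
  expect_error(decompressSecondOrder(so, list()),
               class = "sgc_corruption_error")
  expect_error(decompressSecondOrder(so, list()), "17")
})
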