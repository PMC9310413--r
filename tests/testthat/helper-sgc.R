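# Shared helpers: small sequence generators and independent oracles.
# Everything here is plain R so it stays independent of the compiled paths
# it is used to check.

BASES <- c("A", "C", "G", "T")

randBase <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# simple SNP-only mutant, independent of the package's fixture generator
mutateSnp <- function(refStr, rate) {
  x <- strsplit(refStr, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    x[hit] <- BASES[(match(x[hit], BASES) - 1L + shift) %% 4L + 1L]
  }
  paste(x, collapse = "")
}

readFileBytes <- function(p) readBin(p, "raw", file.size(p))

filesIdentical <- function(a, b) identical(readFileBytes(a), readFileBytes(b))

# random FASTA record text exercising case, N runs, specials, ragged lines
# and trailing-newline state; uses the session RNG
randomRecordText <- function(maxLen = 300) {
  n <- sample(0:maxLen, 1)
  syms <- sample(c(BASES, tolower(BASES), "N", "n", "R", "y"), n,
                 replace = TRUE,
                 prob = c(rep(0.22, 4), rep(0.012, 4), 0.015, 0.01, 0.004, 0.003))
  id <- paste0("rec ", paste(sample(c(letters, " ", "\t", "|"), 8, replace = TRUE),
                             collapse = ""))
  width <- sample(1:80, 1)
  body <- paste(syms, collapse = "")
  lines <- if (n > 0) {
    starts <- seq(1, n, by = width)
    substring(body, starts, pmin(starts + width - 1, n))
  } else character()
  # occasionally make one line ragged
  if (length(lines) > 1 && runif(1) < 0.3) {
    i <- sample(seq_along(lines), 1)
    lines[i] <- substr(lines[i], 1, max(0, nchar(lines[i]) - 1))
  }
  txt <- paste(c(paste0(">", id), lines), collapse = "\n")
  if (runif(1) < 0.9) txt <- paste0(txt, "\n")
  txt
}

# Brute-force first-order oracle: every Match must be substring-equal and
# its length must equal the maximum extension over ALL occurrences of its
# anchor k-mer in the reference (occurrences found by naive scan).
checkFirstOrderOracle <- function(stream, target, refStr, k) {
  tok <- tokens(stream)
  nref <- nchar(refStr)
  refKmers <- if (nref >= k) substring(refStr, 1:(nref - k + 1), k:nref) else character()
  cursor <- 0L
  for (i in seq_len(nrow(tok))) {
    if (tok$type[i] == 0L) {
      span <- substr(target, cursor + 1L, cursor + tok$len[i])
      expect_identical(substr(refStr, tok$pos[i] + 1L, tok$pos[i] + tok$len[i]),
                       span)
      expect_gte(tok$len[i], k)
      anchor <- substr(target, cursor + 1L, cursor + k)
      occs <- which(refKmers == anchor) - 1L
      expect_true(length(occs) > 0)
      maxExt <- 0L
      tChars <- strsplit(substr(target, cursor + 1L, nchar(target)), "")[[1]]
      for (p in occs) {
        rChars <- strsplit(substr(refStr, p + 1L, nref), "")[[1]]
        m <- min(length(tChars), length(rChars))
        neq <- which(tChars[seq_len(m)] != rChars[seq_len(m)])
        ext <- if (length(neq)) neq[1] - 1L else m
        maxExt <- max(maxExt, ext)
      }
      expect_identical(tok$len[i], as.integer(maxExt))
    }
    cursor <- cursor + tok$len[i]
  }
  expect_identical(cursor, nchar(target))
}

# small compressed collection used by several archive/orchestration tests
makeSmallCollection <- function(dir, n = 6, refLen = 4000, seed = 11,
                                snpRate = 5e-3) {
  ref <- file.path(dir, "ref.fa")
  generateReference(ref, refLen, seed = seed)
  coll <- generateCollection(ref, file.path(dir, "coll"), n,
                             mutationProfile(seed = seed + 1, snpRate = snpRate))
  list(reference = ref, collection = coll)
}
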