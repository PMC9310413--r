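# Hash index of all reference k-mers, used for anchor discovery.

#' Build the k-mer index of a reference base stream
#'
#' Indexes every k-mer of \code{ref_base} (2-bit packed before hashing, so
#' bucketing is exact within the key) to the ordered list of its 0-based
#' start positions. Streams shorter than \code{k} yield a valid empty index
#' and matching degenerates to all-literal output. The index lives in native
#' memory and is never written to an archive: decompression does not need
#' it.
#'
#' @param ref_base reference base stream (uppercase ACGT character scalar).
#' @param k k-mer length in bases, between 1 and 31. Default 14: long enough
#'   for anchor specificity on genome-scale references, short enough to keep
#'   the index dense.
#' @param maxOcc cap on stored occurrences per k-mer (earliest kept);
#'   \code{Inf} stores all. Bounds extension work in repeat regions.
#' @return a \linkS4class{KmerIndex}.
#' @examples
#' idx <- buildKmerIndex("ACGTACGT", k = 4)
#' kmerLookup(idx, "ACGT")
#' @export
buildKmerIndex <- function(ref_base, k = 14L, maxOcc = Inf) {
  stopifnot(is.character(ref_base), length(ref_base) == 1)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L)
    sgcConfigError("k must be an integer between 1 and 31")
  ptr <- cpp_build_kmer_index(ref_base, k, maxOcc)
  new("KmerIndex", ptr = ptr, k = k, refLength = nchar(ref_base),
      refFingerprint = fingerprintBytes(ref_base))
}

#' Query a k-mer index
#'
#' Returns the ordered 0-based occurrence positions of \code{kmer} in the
#' indexed stream; an empty integer vector for absent k-mers.
#'
#' @param idx a \linkS4class{KmerIndex}.
#' @param kmer ACGT string of length \code{kmerSize(idx)}.
#' @export
kmerLookup <- function(idx, kmer) {
  stopifnot(is(idx, "KmerIndex"))
  if (nchar(kmer) != idx@k)
    sgcUsageError(sprintf("query length %d does not equal index k = %d",
                          nchar(kmer), idx@k))
  cpp_kmer_lookup(idx@ptr, kmer)
}

#' Summary counts of a k-mer index
#'
#' @param idx a \linkS4class{KmerIndex}.
#' @return list with \code{k}, \code{ref_length}, \code{n_positions} (total
#'   stored positions) and \code{n_kmers} (distinct k-mers).
#' @export
kmerIndexInfo <- function(idx) {
  stopifnot(is(idx, "KmerIndex"))
  cpp_kmer_index_info(idx@ptr)
}
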