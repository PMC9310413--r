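---
title: "Two-order reference-based compression of genome collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-order reference-based compression of genome collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Collections of genomes from the same species are enormously redundant: two
human individuals differ in roughly one base per thousand, and most of that
difference is shared across individuals. A general-purpose compressor cannot
exploit this structure well; a reference-based compressor can, by storing
each sequence as exact matches into a similar reference plus the few
diverging bases. `sgc` implements a two-order scheme: every sequence is
first matched against one external reference genome, and the resulting
token streams are then matched against each other, which captures the
redundancy *between* targets (shared variants) that the first stage cannot
see. The output is a single indexed archive from which any individual
sequence can be restored byte-exactly without expanding the whole
collection.

## The pipeline and its assumptions

```{r, eval = FALSE}
library(sgc)
compressCollection(reference, targets, "out.sgc", config = sgcConfig())
decompressCollection("out.sgc", reference, "restored/")
```

**Base/auxiliary split.** Losslessness is absolute: case, line wrapping, `N`
runs, ambiguity symbols, header text, CRLF convention and trailing-newline
state all survive. Each record is decomposed in a fixed order — record the
line lengths, fold lowercase to uppercase (recording intervals), remove
non-ACGTN symbols (recording position/symbol pairs), remove `N` runs
(recording intervals) — leaving a pure ACGT base stream. Any self-inverse
order would work; this one is frozen so that archives are portable between
package versions. Each auxiliary stream stores 0-based coordinates in the
frame that exists at its own extraction step, so reconstruction simply
applies the inverse steps in reverse order (insert `N` runs, insert
specials, restore case, re-wrap, prepend the identifier) without any
coordinate remapping. A lowercase `n` is recorded in both the lowercase and
the `N` streams, keeping each stream single-purpose. Line layout is stored
as a dominant width plus an exception list rather than per-line lengths,
because FASTA is overwhelmingly fixed-width; when several widths tie for
most frequent, the earliest line's width wins. Line endings are detected
once per file and stored as a single CRLF flag; files mixing conventions
are refused rather than silently normalised.

**First-order matching.** All k-mers of the reference base stream are
indexed (2-bit packed, so the key is exact for k ≤ 31; the hash table's own
collisions are resolved by chaining). Matching is plain greedy: at the
cursor, look up the anchor k-mer, extend every candidate occurrence as far
as the exact match runs, and emit the longest as a `Match(position,
length)`; otherwise the cursor advances one base into a pending literal.
Advancing by one (rather than k) after a failed anchor maximises match
recovery right after a mismatch. Matches shorter than k are undetectable by
the index and are deliberately not sought. Greedy matching is suboptimal in
principle — no lookahead, no match shortening — but is what makes the
method fast, and the second stage recovers much of the loss on collections.

**Second-order matching.** The first S first-order streams become
second-order references; they are chain-compressed (stream *i* may match
only streams 0..*i*−1), and all later streams are matched against the full
reference set. The match unit is a whole token: a `Match` token equals only
an identical (position, length) pair, a literal only an identical string.
This makes equality exact, the index a plain fingerprint map, and the
decoder trivial. Runs shorter than `minRun` tokens stay as passthrough
tokens, because a `RefMatch(ref id, token position, token count)` triple
costs more bytes than most single tokens. Ties between equally long runs go
to the lowest reference id, then the lowest token position — determinism
plus smaller encoded integers. Internally, candidate locations are found
through a token-*pair* fingerprint map whenever `minRun >= 2`: any
acceptable run must begin with two matching tokens, so the sparser map
yields bit-identical output while skipping the very frequent single-token
fingerprints (a lone `"A"` substitution literal occurs thousands of times).

**Archive.** One entropy-coded block per sequence (auxiliary bytes plus
serialized token stream), an index of block lengths and 8-byte FNV-1a
checksums in the header, and a content fingerprint of the reference genome
so decompression with the wrong reference fails fast instead of producing
garbage. Blocks are compressed independently — slightly worse than one
solid block, but it is what makes selective extraction possible. All
integers are varints; signed deltas (match positions are delta-coded
against the previous match's end) are zigzag-mapped; literal bases are
2-bit packed. The final entropy stage is pluggable with registered
backends `bzip2` (default), `gzip` and `xz`; the block-sorting `bzip2` is
the default because token payloads still carry long-range repetition that a
BWT-family coder exploits well. The backend identifier, k, S and `minRun`
are recorded in the header, so decompression needs no flags — and no k-mer
index at all, which is why decompression is much lighter than compression.

**Parallelism.** Per-sequence stages (first-order matching, second-order
matching of non-references) run as forked tasks sharing the read-only
reference and index; results are collected in sequence order regardless of
completion order, so archive bytes are invariant under the worker count.
Chain-compression of the references is inherently serial. Decompression is
single-threaded by design: it is I/O-bound.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 14 bases | anchor k-mer length. 4^14 ≈ 2.7·10^8 balances anchor specificity against index size for genome-scale references; smaller k finds more anchors in diverged sequences at more extension cost. |
| `S` | 40 sequences | number of second-order references. More references raise the chance of second-level matches (smaller output) and the indexing/matching cost (slower); S is clamped to the collection size and stored in the header. |
| `minRun` | 2 tokens | minimum accepted second-order run; a 1-token RefMatch almost always costs more than the token itself. |
| `backend` | `bzip2` | final entropy coder, per-block. |
| `workers` | 1 | forked tasks for the per-sequence stages; output-invariant. |
| `maxOcc` | unlimited | per-k-mer occurrence cap (earliest kept) to bound extension work in repeat regions. |

## The synthetic data generator

`generateReference()` draws a uniform ACGT sequence; `generateCollection()`
derives each target independently from it (a star phylogeny): substitutions
at `snpRate`, insertions/deletions at `insRate`/`delRate` with geometric
lengths, then decoration with soft-masked runs, `N` runs and rare ambiguity
symbols, and fixed-width wrapping. Every sequence ships with a plain-text
mutation log that deterministically rebuilds it from the reference, and the
generator replays the log as a self-check before returning. The standard
fixture frozen for the test suite is a 1 Mb reference with 50 sequences
(SNP 10^-3, indels 10^-4 with geometric p = 0.5, 5% soft-masked at mean run
300, N-run rate 10^-5 at mean 50, ambiguity rate 10^-6, width 60, seed 42)
— sized so the whole suite runs in minutes on one CPU while still
exercising every stream type.

What the generator does *not* emulate, and what passing tests therefore do
not show: real populations share variants (haplotype structure), so
first-order token streams of real genomes collide far more often than
streams of independent mutants, and the second-order stage is
correspondingly more valuable on real data than on this fixture — on
independent mutants it mostly finds nothing and the size trend across S is
flat rather than decreasing. There are no structural variants, no
translocations, no sequencing gaps beyond simple `N` runs, and base
composition is uniform rather than isochore-structured.

## Numerical and degenerate-input choices

* First-order ties (equally long candidate matches) go to the smallest
  absolute delta between the candidate start and the previous match's end,
  then the smallest position: the serializer delta-codes positions, so
  nearby candidates cost fewer bytes. The previous-end starts at 0.
* Targets shorter than k, references shorter than k, empty sequences,
  records that are 100% `N` or 100% lowercase, zero-line records and
  header-only files are all valid inputs; matching degenerates to literals
  and the split/reconstruct pair remains the identity.
* `S = 0` disables the second order (every token passes through); the
  serialization is unchanged, so first-order-only archives use the same
  format.
* Varints are unsigned 7-bit-continuation; anything signed is zigzag-mapped
  first. Truncated streams, out-of-range intervals, out-of-bounds matches
  and dangling reference ids raise classified corruption errors; a flipped
  byte in one block is caught by that block's checksum and leaves every
  other block extractable.

## Known limitations

* Greedy matching with no lookahead can fragment matches around clustered
  differences; methods that join matches across nearby substitutions or
  re-segment the target achieve better first-order ratios at higher cost.
* Second-order matching at whole-token granularity cannot exploit partial
  overlap between long literal tokens.
* An archive of N sequences with S references must always store reference 0
  verbatim (it opens the chain), so on a collection of identical sequences
  the archive can approach but never go below 1/N of the
  first-order-only size — the per-block entropy-coder overhead keeps it
  slightly above that floor.
* The reference index lives in memory (~16 bytes per reference position);
  chromosome-scale references are comfortable, full mammalian genomes as a
  single stream will want the `maxOcc` cap and patience.
* One reference per archive; no automatic reference selection or
  re-ordering of targets to improve the chain.
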