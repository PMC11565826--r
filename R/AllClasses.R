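#' @import methods
NULL

#' DocumentCollection: an ordered set of named DNA sequences
#'
#' One document corresponds to one genome/haplotype of the indexed collection.
#' Sequences are stored uppercase over the alphabet \{A,C,G,T,N\}. At least two
#' documents are required before any multi-MUM computation; a collection of one
#' document can still be concatenated and indexed (it simply has no multi-MUMs).
#'
#' @slot seqs character vector of DNA sequences.
#' @slot names character vector of unique document labels.
#' @export
setClass("DocumentCollection",
  representation(seqs = "character", names = "character"))

setValidity("DocumentCollection", function(object) {
  msgs <- character()
  if (length(object@seqs) != length(object@names))
    msgs <- c(msgs, "seqs and names must have equal length")
  if (any(!nzchar(object@seqs)))
    msgs <- c(msgs, "all documents must be non-empty")
  if (anyDuplicated(object@names))
    msgs <- c(msgs, "document names must be unique")
  bad <- grepl("[^ACGTN]", object@seqs)
  if (any(bad))
    msgs <- c(msgs, sprintf("document %d contains symbols outside {A,C,G,T,N}",
                            which(bad)[1]))
  if (length(msgs)) msgs else TRUE
})

#' ConcatText: separator-joined concatenation of a collection
#'
#' Documents are joined with d-1 distinct separator symbols (one per document
#' end, ranked by document index) followed by a single terminal sentinel. All
#' separators sort below the DNA alphabet and above the sentinel, so suffix
#' comparisons across documents are well defined and matches can never span a
#' document boundary. Integer codes: sentinel = 1, separator after document i
#' = i + 1, and DNA symbols A,C,G,T,N = d+1..d+5 where d is the document count.
#'
#' @slot codes integer vector of symbol codes, length n.
#' @slot n total length including separators and sentinel.
#' @slot d number of documents.
#' @slot docStart 1-based start offset of each document in the concatenation.
#' @slot docLen per-document sequence length (without separator).
#' @slot docNames document labels.
#' @export
setClass("ConcatText",
  representation(codes = "integer", n = "integer", d = "integer",
                 docStart = "integer", docLen = "integer",
                 docNames = "character"))

setValidity("ConcatText", function(object) {
  msgs <- character()
  n <- object@n
  if (length(object@codes) != n) msgs <- c(msgs, "codes length must equal n")
  if (sum(object@codes == 1L) != 1L || object@codes[n] != 1L)
    msgs <- c(msgs, "exactly one sentinel, at the last position")
  d <- object@d
  seps <- which(object@codes > 1L & object@codes <= d)
  expect <- object@docStart[-1L] - 1L
  if (!identical(seps, expect))
    msgs <- c(msgs, "separators must occur exactly at document ends")
  if (length(msgs)) msgs else TRUE
})

#' SuffixStructures: SA, LCP, DA and BWT of a concatenated text
#'
#' @slot sa suffix array, a 1-based permutation of 1..n.
#' @slot lcp longest common prefix with the lexicographically previous suffix
#'   (lcp[1] = 0).
#' @slot da document index of each rank's suffix start.
#' @slot bwt preceding symbol code of each rank (sentinel-wrapped).
#' @slot text the [ConcatText] these structures were built from.
#' @export
setClass("SuffixStructures",
  representation(sa = "integer", lcp = "integer", da = "integer",
                 bwt = "integer", text = "ConcatText"))

#' RLBWT: run-length encoded BWT
#'
#' @slot runChar symbol code of each maximal run.
#' @slot runLen run length.
#' @slot runStart 1-based BWT offset of each run start.
#' @slot r number of runs.
#' @slot n BWT length.
#' @export
setClass("RLBWT",
  representation(runChar = "integer", runLen = "integer",
                 runStart = "integer", r = "integer", n = "integer"))

setValidity("RLBWT", function(object) {
  msgs <- character()
  if (sum(object@runLen) != object@n) msgs <- c(msgs, "run lengths must sum to n")
  if (is.unsorted(object@runStart, strictly = TRUE))
    msgs <- c(msgs, "run starts must be strictly increasing")
  if (object@r > 1L && any(diff(object@runChar) == 0L))
    msgs <- c(msgs, "adjacent runs must differ in symbol (maximality)")
  if (length(msgs)) msgs else TRUE
})

#' MoveTables: run-indexed LF/FL permutation tables
#'
#' Both directions are answered from tables indexed by BWT run: \code{lfPos[j]}
#' is LF of run j's first position and \code{lfDestRun[j]} the run containing
#' it; stepping inside a run adds the offset and fast-forwards the destination
#' run pointer, the move-structure contract of constant amortized time per
#' step. FL is served from the same r intervals re-sorted by F-position.
#'
#' @slot runStart,runChar,runLen the underlying runs.
#' @slot lfPos LF image of each run start.
#' @slot lfDestRun run index containing \code{lfPos}.
#' @slot flFirst sorted F-interval starts (one interval per BWT run).
#' @slot flRun BWT run index of each F-interval.
#' @slot n BWT length.
#' @export
setClass("MoveTables",
  representation(runStart = "integer", runChar = "integer", runLen = "integer",
                 lfPos = "integer", lfDestRun = "integer",
                 flFirst = "integer", flRun = "integer", n = "integer"))

#' Thresholds: LCP-minimum positions between successive equal-character runs
#'
#' For each symbol c and each consecutive pair of c-runs, the stored position
#' is the smallest index attaining the minimum of the LCP array over the
#' boundaries strictly between the two runs; it directs the mismatch
#' repositioning during backward search.
#'
#' @slot charRunFirst,charRunLast per symbol code, first/last BWT position of
#'   every maximal run of that symbol (sorted).
#' @slot charThr per symbol code, threshold position between consecutive runs.
#' @slot pairs data.frame listing (char, prevRunEnd, nextRunStart, pos).
#' @export
setClass("Thresholds",
  representation(charRunFirst = "list", charRunLast = "list",
                 charThr = "list", pairs = "data.frame"))

#' MultiMUMSet: all multi-MUMs of a collection
#'
#' A multi-MUM is a match occurring exactly once in each of the d documents and
#' extendable in neither direction. Each is represented by the SA rank s of its
#' d-wide suffix-array window, its width w, and per-document 1-based start
#' positions.
#'
#' @slot s SA ranks of window starts, ascending.
#' @slot w match widths.
#' @slot positions u x d matrix of document-local start positions.
#' @slot ids positive integer labels (1..u in s order).
#' @slot d document count.
#' @slot u number of multi-MUMs.
#' @export
setClass("MultiMUMSet",
  representation(s = "integer", w = "integer", positions = "matrix",
                 ids = "integer", d = "integer", u = "integer"))

setValidity("MultiMUMSet", function(object) {
  msgs <- character()
  if (object@u >= 2L && any(diff(object@s) < object@d))
    msgs <- c(msgs, "consecutive SA window starts must differ by at least d")
  if (object@u > 0L && nrow(object@positions) != object@u)
    msgs <- c(msgs, "positions must have one row per multi-MUM")
  if (length(msgs)) msgs else TRUE
})

#' TunnelSet: non-overlapping multi-MUM tunnels
#'
#' Each tunnel is the realized suffix interval of one multi-MUM: an ordered
#' sequence of contiguous d-wide BWT ranges (columns) obtained by forward
#' stepping from the multi-MUM's SA window, truncated at the first
#' non-contiguous step, at width w, or (in mode "tunnels") at a collision with
#' a position already claimed by another tunnel.
#'
#' @slot mumId source multi-MUM id per tunnel.
#' @slot w source multi-MUM width.
#' @slot wPrime realized width (number of accepted columns).
#' @slot colStarts list of integer vectors; element t holds the 1-based BWT
#'   start of each column of tunnel t (columns x = 1..wPrime).
#' @slot d column height.
#' @slot n BWT length.
#' @slot mode "tunnels" (disjoint, collision-truncated) or "all".
#' @export
setClass("TunnelSet",
  representation(mumId = "integer", w = "integer", wPrime = "integer",
                 colStarts = "list", d = "integer", n = "integer",
                 mode = "character"))

#' ColBWT: the queryable co-linear BWT index
#'
#' The run-length BWT split into sub-runs at (sampled) tunnel column
#' boundaries; marked sub-runs carry a binned tunnel identifier (0 =
#' unmarked). Query-time structures are the sub-run arrays, the run-indexed LF
#' table over sub-runs, and per-character run navigation with thresholds; the
#' production query path touches nothing else. Full suffix structures may be
#' retained in the \code{oracle} slot for test/oracle modes and are never read
#' by [queryPmlCid()].
#'
#' @slot subStart,subChar,subLen,subId sub-run arrays (1-based starts; id 0 =
#'   unmarked).
#' @slot rPrime sub-run count.
#' @slot subLfPos,subLfDest LF move table over sub-runs.
#' @slot charRunFirst,charRunLast,charThr per-character maximal-run navigation
#'   and thresholds (see [Thresholds-class]).
#' @slot n,d,r,sigma text length, document count, BWT run count, alphabet size.
#' @slot docNames,docLen document metadata.
#' @slot params list(mode, sampleRate, idBits, minMumLen, revcomp).
#' @slot mumTable data.frame(id, binnedId, s, w, wPrime) per multi-MUM.
#' @slot nIdCollisions number of id pairs merged by byte-binning.
#' @slot coverage list(tunnel, marked): fraction of BWT positions inside any
#'   tunnel column, and inside a sampled (marked) sub-run.
#' @slot oracle list with full structures (ss, rl, mt, th, mums, tunnels,
#'   collection) or empty.
#' @slot version serialization format tag.
#' @export
setClass("ColBWT",
  representation(subStart = "integer", subChar = "integer", subLen = "integer",
                 subId = "integer", rPrime = "integer",
                 subLfPos = "integer", subLfDest = "integer",
                 charRunFirst = "list", charRunLast = "list", charThr = "list",
                 n = "integer", d = "integer", r = "integer", sigma = "integer",
                 docNames = "character", docLen = "integer",
                 params = "list", mumTable = "data.frame",
                 nIdCollisions = "integer", coverage = "list",
                 oracle = "list", version = "character"))

setValidity("ColBWT", function(object) {
  msgs <- character()
  if (sum(object@subLen) != object@n)
    msgs <- c(msgs, "sub-run lengths must sum to n")
  if (is.unsorted(object@subStart, strictly = TRUE))
    msgs <- c(msgs, "sub-run starts must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' NullModel: calibrated null distribution of pseudo-matching lengths
#'
#' Built from reversed reference substrings queried back against the index.
#' k is the largest PML occurring at least \code{minCount} times in the null
#' multiset; the significant-peak threshold defaults to ceiling((k+1)/2); and
#' \code{rhoNull} is the expected number of co-linear significant-peak pairs
#' per base under the null.
#'
#' @slot k threshold PML value.
#' @slot peakThreshold significant-peak height cutoff.
#' @slot rhoNull expected co-linear pair rate per base.
#' @slot minCount occurrence count defining k.
#' @slot window classification window length (bp).
#' @slot nNull,lenNull number and length of null substrings.
#' @slot seed RNG seed used for extraction.
#' @export
setClass("NullModel",
  representation(k = "integer", peakThreshold = "integer", rhoNull = "numeric",
                 minCount = "integer", window = "integer",
                 nNull = "integer", lenNull = "integer", seed = "integer"))

setValidity("NullModel", function(object) {
  if (object@rhoNull < 0) "rhoNull must be non-negative" else TRUE
})
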