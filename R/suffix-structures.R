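#' Build suffix array, LCP, document and BWT arrays
#'
#' The suffix array is computed by prefix doubling (counting-sort based,
#' O(n log n)); the LCP array by Kasai's algorithm; the document array by the
#' boundary map of the concatenation; and the BWT as the symbol preceding each
#' suffix (sentinel-wrapped).
#'
#' @param ct a [ConcatText-class].
#' @return a [SuffixStructures-class].
#' @export
buildSuffixStructures <- function(ct) {
  sa0 <- sa_build_cpp(ct@codes)         # 0-based
  lcp <- lcp_kasai_cpp(ct@codes, sa0)
  sa <- sa0 + 1L
  prev <- sa - 1L
  prev[prev == 0L] <- ct@n
  new("SuffixStructures", sa = sa, lcp = lcp, da = docOf(ct, sa),
      bwt = ct@codes[prev], text = ct)
}

#' Run-length encode the BWT
#'
#' @param ss a [SuffixStructures-class].
#' @return an [RLBWT-class] of maximal equal-symbol runs.
#' @export
runLengthEncode <- function(ss) {
  enc <- rle(ss@bwt)
  len <- as.integer(enc$lengths)
  new("RLBWT", runChar = as.integer(enc$values), runLen = len,
      runStart = as.integer(cumsum(c(1L, len[-length(len)]))),
      r = length(len), n = as.integer(length(ss@bwt)))
}

#' Build run-indexed LF/FL move tables
#'
#' @param rl an [RLBWT-class].
#' @return a [MoveTables-class].
#' @export
buildMoveTables <- function(rl) {
  lf <- runLfTable(rl@runChar, rl@runLen, rl@runStart)
  ord <- order(lf$lfPos)
  new("MoveTables", runStart = rl@runStart, runChar = rl@runChar,
      runLen = rl@runLen, lfPos = lf$lfPos,
      lfDestRun = findInterval(lf$lfPos, rl@runStart),
      flFirst = lf$lfPos[ord], flRun = as.integer(ord), n = rl@n)
}

# LF image of every run start: C[char] + occurrences of char before the run.
runLfTable <- function(runChar, runLen, runStart) {
  cnt <- tapply(runLen, runChar, sum)
  sigma <- max(runChar)
  counts <- integer(sigma)
  counts[as.integer(names(cnt))] <- as.integer(cnt)
  C <- c(0L, cumsum(counts))[seq_len(sigma)]   # symbols smaller than code c
  occBefore <- integer(length(runChar))
  for (c in unique(runChar)) {
    j <- which(runChar == c)
    occBefore[j] <- cumsum(c(0L, runLen[j][-length(j)]))
  }
  list(lfPos = as.integer(C[runChar] + occBefore + 1L), C = C)
}

#' LF mapping (one backward text step per BWT position)
#'
#' @param mt a [MoveTables-class].
#' @param i 1-based BWT positions (vectorized).
#' @return the LF images: SA[lfMap(mt, i)] = SA[i] - 1 (mod n).
#' @export
lfMap <- function(mt, i) {
  stopifnot(all(i >= 1L & i <= mt@n))
  j <- findInterval(i, mt@runStart)
  mt@lfPos[j] + (i - mt@runStart[j])
}

#' FL mapping (one forward text step; inverse of LF)
#'
#' @param mt a [MoveTables-class].
#' @param i 1-based BWT positions (vectorized).
#' @return the FL images: SA[flMap(mt, i)] = SA[i] + 1 (mod n).
#' @export
flMap <- function(mt, i) {
  stopifnot(all(i >= 1L & i <= mt@n))
  k <- findInterval(i, mt@flFirst)
  j <- mt@flRun[k]
  mt@runStart[j] + (i - mt@flFirst[k])
}

#' FL image of a range with contiguity flag
#'
#' Maps every position of [lo, hi] forward and reports whether the image is
#' the contiguous block [lo', hi'].
#'
#' @param mt a [MoveTables-class].
#' @param lo,hi 1-based range bounds, lo <= hi.
#' @return list(lo, hi, contiguous, image).
#' @export
flRange <- function(mt, lo, hi) {
  stopifnot(lo >= 1L, hi <= mt@n, lo <= hi)
  img <- flMap(mt, lo:hi)
  rng <- range(img)
  list(lo = rng[1], hi = rng[2],
       contiguous = (rng[2] - rng[1]) == (hi - lo), image = img)
}

#' Invert the BWT back to the text
#'
#' Repeated LF stepping from the sentinel's rank reconstructs the text right
#' to left; used as a build-time invariant.
#'
#' @param ss a [SuffixStructures-class].
#' @param mt a [MoveTables-class] over the same BWT.
#' @return integer vector equal to the original text codes.
#' @export
bwtInvert <- function(ss, mt) {
  n <- mt@n
  out <- integer(n)
  p <- which(ss@sa == 1L)  # rank of the full-text suffix; BWT there = T[n]
  for (i in n:1) {
    out[i] <- ss@bwt[p]
    p <- lfMap(mt, p)
  }
  out
}

#' Compute thresholds between successive equal-character runs
#'
#' For each symbol c and each consecutive pair of c-runs (prev run ending at
#' position e, next starting at b), the threshold is the smallest index in
#' [e+1, b] attaining the minimum of the LCP array there; those LCP entries
#' are exactly the suffix boundaries strictly between the two runs' interiors.
#'
#' @param ss a [SuffixStructures-class].
#' @param rl an [RLBWT-class].
#' @return a [Thresholds-class].
#' @export
computeThresholds <- function(ss, rl) {
  sigma <- max(rl@runChar)
  first <- vector("list", sigma); last <- vector("list", sigma)
  thr <- vector("list", sigma)
  rows <- list()
  for (c in seq_len(sigma)) {
    j <- which(rl@runChar == c)
    f <- rl@runStart[j]
    l <- rl@runStart[j] + rl@runLen[j] - 1L
    first[[c]] <- f; last[[c]] <- l
    if (length(j) >= 2L) {
      t <- integer(length(j) - 1L)
      for (k in seq_len(length(j) - 1L)) {
        span <- (l[k] + 1L):f[k + 1L]
        t[k] <- span[which.min(ss@lcp[span])]
      }
      thr[[c]] <- t
      rows[[length(rows) + 1L]] <-
        data.frame(char = c, prevRunEnd = l[-length(l)], nextRunStart = f[-1L],
                   pos = t)
    } else {
      thr[[c]] <- integer(0)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(char = integer(0), prevRunEnd = integer(0),
               nextRunStart = integer(0), pos = integer(0))
  new("Thresholds", charRunFirst = first, charRunLast = last,
      charThr = thr, pairs = pairs)
}
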