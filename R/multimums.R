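#' Find all multi-MUMs via suffix-array window criteria
#'
#' A d-wide SA window starting at rank i holds a multi-MUM of width
#' w = min(LCP[i+1..i+d-1]) iff w exceeds the LCP values flanking the window
#' (LCP beyond the array treated as 0), the window's d document indices are
#' all distinct, its d BWT symbols are not all equal (left-maximality), no
#' suffix in the window starts inside a separator/sentinel region, and
#' w >= max(minLen, 1).
#'
#' @param ss a [SuffixStructures-class].
#' @param d document count (>= 2).
#' @param minLen minimum multi-MUM width to report (default 1).
#' @return a [MultiMUMSet-class] sorted by SA window start.
#' @export
findMultiMUMs <- function(ss, d, minLen = 1L) {
  if (d < 2L) inputError("multi-MUMs require at least 2 documents (d = %d)", d)
  n <- length(ss@sa)
  nw <- n - d + 1L
  if (nw < 1L) return(emptyMUMSet(d))
  lcpExt <- c(ss@lcp, 0L)                       # LCP[n+1] := 0
  # w_i = min over LCP[i+1 .. i+d-1]
  w <- rollMin(ss@lcp[-1L], d - 1L)             # length n-d+1
  leftOk <- w > ss@lcp[seq_len(nw)]
  rightOk <- w > lcpExt[seq_len(nw) + d]
  # all d documents distinct: next-equal-document distance
  nxt <- rep.int(n + 1L, n)
  for (doc in unique(ss@da)) {
    idx <- which(ss@da == doc)
    if (length(idx) > 1L) nxt[idx[-length(idx)]] <- idx[-1L]
  }
  docOk <- rollMin(nxt, d) >= seq_len(nw) + d
  # not all BWT symbols equal
  if (d >= 2L) {
    neq <- as.integer(ss@bwt[-1L] != ss@bwt[-n])
    bwtOk <- rollMax(neq, d - 1L) > 0L
  } else bwtOk <- rep(FALSE, nw)
  # no suffix starting at a separator or the sentinel
  isSeq <- as.integer(ss@text@codes[ss@sa] > d)
  seqOk <- rollMin(isSeq, d) > 0L
  keep <- which(leftOk & rightOk & docOk & bwtOk & seqOk &
                w >= max(minLen, 1L))
  if (!length(keep)) return(emptyMUMSet(d))
  pos <- matrix(0L, nrow = length(keep), ncol = d)
  for (t in seq_along(keep)) {
    i <- keep[t]
    win <- i:(i + d - 1L)
    doc <- ss@da[win]
    pos[t, doc] <- ss@sa[win] - ss@text@docStart[doc] + 1L
  }
  colnames(pos) <- ss@text@docNames
  new("MultiMUMSet", s = as.integer(keep), w = as.integer(w[keep]),
      positions = pos, ids = seq_along(keep), d = as.integer(d),
      u = length(keep))
}

emptyMUMSet <- function(d) {
  new("MultiMUMSet", s = integer(0), w = integer(0),
      positions = matrix(0L, 0, d), ids = integer(0),
      d = as.integer(d), u = 0L)
}

#' Multi-MUM strings
#'
#' @param mums a [MultiMUMSet-class].
#' @param coll the [DocumentCollection-class] the set was computed from.
#' @return character vector of the matched strings.
#' @export
mumStrings <- function(mums, coll) {
  if (mums@u == 0L) return(character(0))
  p1 <- mums@positions[, 1L]
  substring(coll@seqs[1L], p1, p1 + mums@w - 1L)
}

#' Brute-force multi-MUM enumeration (test oracle)
#'
#' Enumerates substrings by width, keeps those occurring exactly once in every
#' document, and filters to the ones extendable in neither direction (a
#' document boundary blocks extension). Quadratic-ish; intended for small
#' collections only.
#'
#' @param coll a [DocumentCollection-class] with total length up to a few kb.
#' @param minLen minimum width to report.
#' @return data.frame(string, width, pos.<doc> columns) sorted by string.
#' @export
bruteForceMultiMUMs <- function(coll, minLen = 1L) {
  seqs <- coll@seqs
  d <- length(seqs)
  lens <- nchar(seqs)
  out <- list()
  w <- 1L
  while (w <= min(lens)) {
    kmers <- lapply(seq_len(d), function(i) {
      substring(seqs[i], 1:(lens[i] - w + 1L), w:lens[i])
    })
    tabs <- lapply(kmers, table)
    common <- Reduce(intersect, lapply(tabs, names))
    if (!length(common)) break
    uniq <- common
    for (i in seq_len(d)) uniq <- uniq[tabs[[i]][uniq] == 1L]
    if (length(uniq) && w >= max(minLen, 1L)) {
      # one occurrence per document by construction; match() finds it
      pmat <- vapply(seq_len(d), function(i) match(uniq, kmers[[i]]),
                     integer(length(uniq)))
      pmat <- matrix(pmat, ncol = d)
      # maximality: both extensions must be blocked (boundary or mismatch)
      extBlocked <- function(shifted, boundary) {
        ch <- vapply(seq_len(d), function(i) {
          ifelse(boundary[, i], NA_character_,
                 substring(seqs[i], shifted[, i], shifted[, i]))
        }, character(length(uniq)))
        ch <- matrix(ch, ncol = d)
        apply(ch, 1L, function(z) anyNA(z) || length(unique(z)) > 1L)
      }
      leftB <- extBlocked(pmat - 1L, pmat <= 1L)
      rightB <- extBlocked(pmat + w,
                           pmat + w - 1L >= matrix(lens, nrow(pmat), d,
                                                   byrow = TRUE))
      sel <- which(leftB & rightB)
      if (length(sel)) {
        df <- data.frame(string = uniq[sel], width = w)
        for (j in seq_len(d)) df[[paste0("pos.", coll@names[j])]] <- pmat[sel, j]
        out[[length(out) + 1L]] <- df
      }
    }
    w <- w + 1L
  }
  if (!length(out)) {
    res <- data.frame(string = character(0), width = integer(0))
    for (nm in coll@names) res[[paste0("pos.", nm)]] <- integer(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$string), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tabulate a multi-MUM set in the oracle's format
#'
#' @param mums a [MultiMUMSet-class].
#' @param coll the source [DocumentCollection-class].
#' @return data.frame comparable with [bruteForceMultiMUMs()] output.
#' @export
mumTableForComparison <- function(mums, coll) {
  res <- data.frame(string = mumStrings(mums, coll), width = mums@w)
  for (j in seq_len(mums@d))
    res[[paste0("pos.", coll@names[j])]] <- mums@positions[, j]
  res <- res[order(res$string), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export multi-MUM occurrences as a BED-like table
#'
#' @param mums a [MultiMUMSet-class].
#' @return data.frame(doc_name, start, end, mum_id, width) with 0-based
#'   half-open coordinates.
#' @export
mumBed <- function(mums) {
  if (mums@u == 0L)
    return(data.frame(doc_name = character(0), start = integer(0),
                      end = integer(0), mum_id = integer(0),
                      width = integer(0)))
  docs <- colnames(mums@positions)
  do.call(rbind, lapply(seq_len(mums@d), function(j) {
    data.frame(doc_name = docs[j], start = mums@positions[, j] - 1L,
               end = mums@positions[, j] - 1L + mums@w,
               mum_id = mums@ids, width = mums@w)
  }))
}
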