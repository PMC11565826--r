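#' Default significant-peak threshold for a calibrated threshold PML value
#'
#' The cutoff is ceiling((k+1)/2): two adjacent peaks both at the cutoff have
#' cumulative height exceeding k, the largest match length expected by
#' chance.
#'
#' @param k threshold PML value from null calibration.
#' @return integer peak-height cutoff.
#' @export
significantPeakThreshold <- function(k) as.integer(ceiling((k + 1) / 2))

#' Extract PML peaks from a query result
#'
#' A peak is a maximal run of positive pseudo-matching lengths decreasing by
#' exactly 1 left to right; it represents one exact-match region of the read.
#' Zero positions belong to no peak. Boundary ids are the first and last
#' nonzero chain id inside the span (0 if none).
#'
#' @param result a [queryPmlCid()] result (or any list with pml and cid).
#' @return data.frame(start, end, height, first_id, last_id), ordered and
#'   disjoint.
#' @export
extractPeaks <- function(result) {
  pml <- result$pml
  cid <- result$cid
  m <- length(pml)
  empty <- data.frame(start = integer(0), end = integer(0),
                      height = integer(0), first_id = integer(0),
                      last_id = integer(0))
  if (m == 0L || !any(pml > 0L)) return(empty)
  cont <- c(FALSE, pml[-1L] == pml[-m] - 1L & pml[-1L] > 0L)
  start <- which(pml > 0L & !cont)
  end <- c(start[-1L] - 1L, m)
  # trailing zeros after the last positive position
  end[length(end)] <- max(which(pml > 0L))
  # each segment may still hold zeros at its tail if pml dropped to 0 inside
  end <- vapply(seq_along(start), function(t) {
    span <- start[t]:end[t]
    span[max(which(pml[span] > 0L))]
  }, integer(1))
  ids <- lapply(seq_along(start), function(t) {
    z <- cid[start[t]:end[t]]
    z <- z[z > 0L]
    if (length(z)) c(z[1L], z[length(z)]) else c(0L, 0L)
  })
  data.frame(start = start, end = end, height = pml[start],
             first_id = vapply(ids, `[`, integer(1), 1L),
             last_id = vapply(ids, `[`, integer(1), 2L))
}

#' Count adjacent co-linear significant-peak pairs
#'
#' Peaks below the significance threshold are dropped first (small chance
#' matches are ignored); consecutive surviving peaks form a co-linear pair
#' when the last chain id of the first equals the first chain id of the
#' second and both are nonzero.
#'
#' @param peaks output of [extractPeaks()].
#' @param peakThreshold significant-peak height cutoff.
#' @return list(pairs, colinear): number of adjacent significant pairs and
#'   how many of them are co-linear.
#' @export
colinearPairs <- function(peaks, peakThreshold) {
  sig <- peaks[peaks$height >= peakThreshold, , drop = FALSE]
  k <- nrow(sig)
  if (k < 2L) return(list(pairs = 0L, colinear = 0L))
  a <- sig$last_id[-k]
  b <- sig$first_id[-1L]
  list(pairs = k - 1L, colinear = sum(a > 0L & a == b))
}

#' Calibrate the null model from reversed reference substrings
#'
#' Uniform substrings of the reference documents are extracted, reversed (not
#' complemented, so base composition is preserved while genuine homology is
#' destroyed), and queried back against the index. k is the largest PML value
#' occurring at least \code{minCount} times in the pooled null PMLs; the
#' significant-peak threshold defaults to ceiling((k+1)/2); and rhoNull is
#' the total count of adjacent co-linear significant-peak pairs over the null
#' sequences divided by the total null bases.
#'
#' @param index a [ColBWT-class].
#' @param coll the reference [DocumentCollection-class].
#' @param nNull number of null substrings (default 500).
#' @param lenNull substring length (default 2000).
#' @param minCount occurrence count defining k (default 5).
#' @param window classification window length in bp (default 150).
#' @param seed RNG seed for extraction.
#' @return a [NullModel-class].
#' @export
calibrateNull <- function(index, coll, nNull = 500L, lenNull = 2000L,
                          minCount = 5L, window = 150L, seed = 1L) {
  lens <- nchar(coll@seqs)
  ok <- which(lens >= lenNull)
  if (!length(ok))
    inputError("reference shorter than null substring length %d", lenNull)
  nulls <- withSeed(seed, {
    vapply(seq_len(nNull), function(i) {
      doc <- if (length(ok) == 1L) ok else sample(ok, 1L)
      at <- sample.int(lens[doc] - lenNull + 1L, 1L)
      sub <- substring(coll@seqs[doc], at, at + lenNull - 1L)
      paste(rev(splitChars(sub)), collapse = "")
    }, character(1))
  })
  res <- queryReads(index, nulls)
  allPml <- unlist(lapply(res, `[[`, "pml"), use.names = FALSE)
  tab <- table(allPml[allPml > 0L])
  eligible <- as.integer(names(tab))[tab >= minCount]
  k <- if (length(eligible)) max(eligible) else 0L
  thr <- significantPeakThreshold(k)
  pairsCo <- sum(vapply(res, function(x)
    colinearPairs(extractPeaks(x), thr)$colinear, integer(1)))
  new("NullModel", k = as.integer(k), peakThreshold = thr,
      rhoNull = pairsCo / (as.numeric(nNull) * lenNull),
      minCount = as.integer(minCount), window = as.integer(window),
      nNull = as.integer(nNull), lenNull = as.integer(lenNull),
      seed = as.integer(seed))
}

#' Merge co-linear adjacent significant peaks into augmented PMLs
#'
#' For each adjacent co-linear significant-peak pair, positions from the
#' first peak's start to the second peak's end receive the PML values of one
#' uninterrupted match ending at the second peak's end (the maximum with the
#' original value, so augmentation never decreases a PML).
#'
#' @param result a [queryPmlCid()] result.
#' @param null a [NullModel-class].
#' @return integer vector of augmented PMLs.
#' @export
augmentPml <- function(result, null) {
  pml <- result$pml
  peaks <- extractPeaks(result)
  sig <- peaks[peaks$height >= null@peakThreshold, , drop = FALSE]
  k <- nrow(sig)
  if (k >= 2L) {
    for (t in seq_len(k - 1L)) {
      a <- sig$last_id[t]; b <- sig$first_id[t + 1L]
      if (a > 0L && a == b) {
        span <- sig$start[t]:sig$end[t + 1L]
        pml[span] <- pmax(pml[span], sig$end[t + 1L] - span + 1L)
      }
    }
  }
  pml
}

windowsPass <- function(pml, k, window) {
  m <- length(pml)
  nw <- max(1L, ceiling(m / window))
  idx <- pmin(ceiling(seq_len(m) / window), nw)
  passed <- tapply(pml > k, idx, any)
  c(passed = sum(passed), windows = nw)
}

#' Classify one read against the index
#'
#' Four verdicts: \code{baseline} follows the windowed PML rule (a strict
#' majority of non-overlapping windows, the final partial window included,
#' contain some PML > k); \code{scheme_a} calls the read matching when its
#' per-base rate of adjacent co-linear significant-peak pairs exceeds the
#' null expectation; \code{scheme_b} applies the windowed rule to PMLs
#' augmented by merging co-linear peak pairs; \code{scheme_c} is
#' \code{baseline OR scheme_a}.
#'
#' @param result a [queryPmlCid()] result.
#' @param null a [NullModel-class].
#' @return one-row data.frame with verdicts and supporting counts.
#' @export
classifyRead <- function(result, null) {
  m <- length(result$pml)
  if (m == 0L)
    return(data.frame(baseline = FALSE, scheme_a = FALSE, scheme_b = FALSE,
                      scheme_c = FALSE, windows = 0L, windows_passed = 0L,
                      colinear_pairs = 0L, read_len = 0L))
  wp <- windowsPass(result$pml, null@k, null@window)
  baseline <- wp["passed"] > wp["windows"] / 2
  peaks <- extractPeaks(result)
  co <- colinearPairs(peaks, null@peakThreshold)
  schemeA <- (co$colinear / m) > null@rhoNull
  wpB <- windowsPass(augmentPml(result, null), null@k, null@window)
  schemeB <- wpB["passed"] > wpB["windows"] / 2
  data.frame(baseline = unname(baseline), scheme_a = unname(schemeA),
             scheme_b = unname(schemeB),
             scheme_c = unname(baseline | schemeA),
             windows = unname(wp["windows"]),
             windows_passed = unname(wp["passed"]),
             colinear_pairs = co$colinear, read_len = m)
}

#' Classify a batch of reads
#'
#' @param index a [ColBWT-class].
#' @param reads named character vector of reads.
#' @param null a [NullModel-class].
#' @return data.frame, one row per read, with verdicts and counts.
#' @export
classifyReads <- function(index, reads, null) {
  res <- queryReads(index, reads)
  out <- do.call(rbind, lapply(res, classifyRead, null = null))
  out <- cbind(read_id = names(res), out)
  rownames(out) <- NULL
  out
}

#' Sensitivity/specificity summary against truth labels
#'
#' @param calls data.frame from [classifyReads()].
#' @param truth logical vector (TRUE = read originates from the reference),
#'   aligned with calls.
#' @param scheme column name of the verdict to summarize.
#' @return named numeric vector (sensitivity, specificity, accuracy).
#' @export
classificationMetrics <- function(calls, truth, scheme = "scheme_c") {
  pred <- calls[[scheme]]
  sens <- if (any(truth)) mean(pred[truth]) else NA_real_
  spec <- if (any(!truth)) mean(!pred[!truth]) else NA_real_
  c(sensitivity = sens, specificity = spec,
    accuracy = mean(pred == truth))
}
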