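#' Simulate a pangenome: one base genome plus mutated haplotypes
#'
#' A uniform random base sequence is drawn once; each haplotype is an
#' independent copy carrying SNVs (uniform alternative base) at rate
#' \code{snvRate} and, optionally, indels at rate \code{indelRate} with
#' geometric lengths. Deterministic under \code{seed}.
#'
#' @param baseLen base genome length (>= 1).
#' @param d number of haplotypes (>= 2).
#' @param snvRate per-base substitution probability per haplotype.
#' @param indelRate per-base indel initiation probability (default 0).
#' @param indelGeomP geometric length parameter for indels.
#' @param seed RNG seed.
#' @return a [DocumentCollection-class] named hap1..hapD.
#' @export
simulatePangenome <- function(baseLen, d, snvRate, indelRate = 0,
                              indelGeomP = 0.25, seed = 1L) {
  stopifnot(baseLen >= 1, d >= 2, snvRate >= 0, snvRate <= 1,
            indelRate >= 0, indelRate <= 1)
  withSeed(seed, {
    base <- sample(DNA_BASES[1:4], baseLen, replace = TRUE)
    seqs <- vapply(seq_len(d), function(h) {
      hap <- base
      mut <- which(stats::runif(baseLen) < snvRate)
      if (length(mut))
        hap[mut] <- vapply(hap[mut], function(b)
          sample(setdiff(DNA_BASES[1:4], b), 1L), character(1))
      if (indelRate > 0) {
        sites <- which(stats::runif(length(hap)) < indelRate)
        for (at in rev(sites)) {       # right-to-left keeps coordinates valid
          len <- stats::rgeom(1L, indelGeomP) + 1L
          if (stats::runif(1L) < 0.5) {
            hap <- hap[-(at:min(at + len - 1L, length(hap)))]
          } else {
            ins <- sample(DNA_BASES[1:4], len, replace = TRUE)
            hap <- append(hap, ins, after = at)
          }
        }
        if (!length(hap)) hap <- sample(DNA_BASES[1:4], 1L)
      }
      paste(hap, collapse = "")
    }, character(1))
    documentCollection(seqs, paste0("hap", seq_len(d)))
  })
}

#' Simulate labeled reads from a pangenome plus an unrelated negative source
#'
#' Positive reads are substrings of the indexed haplotypes with per-base SNV
#' errors (uniform alternative base); negative reads are error-free
#' substrings of an independently generated random genome unrelated to the
#' collection. Truth labels record origin document and offset.
#'
#' @param coll the indexed [DocumentCollection-class].
#' @param nReads total number of reads.
#' @param readLen read length (must not exceed the shortest donor).
#' @param snvRate per-base read error rate (positives only).
#' @param positiveFraction fraction of reads drawn from the collection.
#' @param seed RNG seed.
#' @return list(reads = named character vector, truth = data.frame(read_id,
#'   positive, doc, pos)).
#' @export
simulateReads <- function(coll, nReads, readLen, snvRate, seed = 1L,
                          positiveFraction = 1) {
  lens <- nchar(coll@seqs)
  if (readLen > max(lens)) inputError("readLen exceeds every donor length")
  nPos <- round(nReads * positiveFraction)
  withSeed(seed, {
    okDocs <- which(lens >= readLen)
    reads <- character(nReads)
    doc <- integer(nReads); pos <- integer(nReads)
    for (i in seq_len(nPos)) {
      doc[i] <- if (length(okDocs) == 1L) okDocs else sample(okDocs, 1L)
      pos[i] <- sample.int(lens[doc[i]] - readLen + 1L, 1L)
      rd <- splitChars(substring(coll@seqs[doc[i]], pos[i],
                                 pos[i] + readLen - 1L))
      err <- which(stats::runif(readLen) < snvRate)
      if (length(err))
        rd[err] <- vapply(rd[err], function(b)
          sample(setdiff(DNA_BASES[1:4], b), 1L), character(1))
      reads[i] <- paste(rd, collapse = "")
    }
    if (nPos < nReads) {
      negLen <- max(10L * readLen, 10000L)
      neg <- paste(sample(DNA_BASES[1:4], negLen, replace = TRUE),
                   collapse = "")
      for (i in (nPos + 1L):nReads) {
        at <- sample.int(negLen - readLen + 1L, 1L)
        reads[i] <- substring(neg, at, at + readLen - 1L)
        doc[i] <- NA_integer_; pos[i] <- at
      }
    }
    ids <- sprintf("read%04d", seq_len(nReads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids,
                            positive = seq_len(nReads) <= nPos,
                            doc = doc, pos = pos))
  })
}

#' Co-linear peak-calling accuracy on reads of known origin
#'
#' Simulates positive reads only (known loci), queries them, extracts peaks,
#' and treats every adjacent significant-peak pair as truth-positive
#' (same read, hence same locus): accuracy is the fraction of those pairs the
#' chain statistics classify as co-linear. Degenerate reads producing a
#' single peak contribute no pairs and are reported as such.
#'
#' @param coll pangenome collection to index.
#' @param nReads,readLen,snvRate read simulation parameters.
#' @param minMumLen,mode,sampleRate,idBits index configuration.
#' @param nNull,lenNull null calibration sizes.
#' @param seed RNG seed for the whole experiment.
#' @return list(accuracy, pairs, colinear, k, peakThreshold, coverage,
#'   degenerateReads, index).
#' @export
runPeakExperiment <- function(coll, nReads = 500L, readLen = 5000L,
                              snvRate = 0.01, minMumLen = 1L,
                              mode = "tunnels", sampleRate = 10L,
                              idBits = 8L, nNull = 500L, lenNull = 2000L,
                              seed = 1L) {
  index <- colbwtBuild(coll, minMumLen = minMumLen, mode = mode,
                       sampleRate = sampleRate, idBits = idBits)
  null <- calibrateNull(index, coll, nNull = nNull, lenNull = lenNull,
                        seed = seed + 1L)
  sim <- simulateReads(coll, nReads, readLen, snvRate, seed = seed + 2L,
                       positiveFraction = 1)
  res <- queryReads(index, sim$reads)
  pairs <- 0L; colinear <- 0L; degenerate <- 0L
  for (x in res) {
    co <- colinearPairs(extractPeaks(x), null@peakThreshold)
    if (co$pairs == 0L) degenerate <- degenerate + 1L
    pairs <- pairs + co$pairs
    colinear <- colinear + co$colinear
  }
  list(accuracy = if (pairs > 0L) colinear / pairs else NA_real_,
       pairs = pairs, colinear = colinear, k = null@k,
       peakThreshold = null@peakThreshold, coverage = index@coverage,
       degenerateReads = degenerate, index = index, null = null)
}

#' Host-depletion style classification experiment on synthetic data
#'
#' Builds an index over the collection, calibrates the null, simulates a
#' labeled mixture of positive (pangenome-derived, error-bearing) and
#' negative (unrelated random genome) reads, classifies every read under all
#' schemes, and summarizes per-scheme accuracy, sensitivity and specificity.
#'
#' @param coll pangenome collection to index.
#' @param nPos,nNeg numbers of positive and negative reads.
#' @param readLen,snvRate read simulation parameters.
#' @param minMumLen,mode,sampleRate,idBits index configuration.
#' @param nNull,lenNull null calibration sizes.
#' @param seed RNG seed.
#' @return list(calls, truth, metrics) where metrics is a matrix with one row
#'   per scheme.
#' @export
runDepletionExperiment <- function(coll, nPos = 2000L, nNeg = 2000L,
                                   readLen = 1000L, snvRate = 0.01,
                                   minMumLen = 1L, mode = "tunnels",
                                   sampleRate = 10L, idBits = 8L,
                                   nNull = 500L, lenNull = 2000L,
                                   seed = 1L) {
  index <- colbwtBuild(coll, minMumLen = minMumLen, mode = mode,
                       sampleRate = sampleRate, idBits = idBits)
  null <- calibrateNull(index, coll, nNull = nNull, lenNull = lenNull,
                        seed = seed + 1L)
  sim <- simulateReads(coll, nPos + nNeg, readLen, snvRate, seed = seed + 2L,
                       positiveFraction = nPos / (nPos + nNeg))
  calls <- classifyReads(index, sim$reads, null)
  schemes <- c("baseline", "scheme_a", "scheme_b", "scheme_c")
  metrics <- t(vapply(schemes, function(s)
    classificationMetrics(calls, sim$truth$positive, s), numeric(3)))
  list(calls = calls, truth = sim$truth, metrics = metrics, null = null,
       index = index)
}
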