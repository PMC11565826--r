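# Shared fixtures and independent oracles, all generated in code.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(len, alphabet = BASES) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Unrelated random documents
randomCollection <- function(d, maxLen = 100L, minLen = 15L) {
  documentCollection(
    vapply(seq_len(d), function(i) randomSeq(sample(minLen:maxLen, 1L)),
           character(1)),
    paste0("doc", seq_len(d)))
}

# Related documents: one base sequence, independent SNVs per document
relatedCollection <- function(d, len, snvRate = 0.03) {
  base <- sample(BASES, len, replace = TRUE)
  documentCollection(
    vapply(seq_len(d), function(i) {
      x <- base
      m <- which(stats::runif(len) < snvRate)
      if (length(m))
        x[m] <- vapply(x[m], function(b) sample(setdiff(BASES, b), 1L),
                       character(1))
      paste(x, collapse = "")
    }, character(1)),
    paste0("doc", seq_len(d)))
}

# Collection built so that exact-substring reads never reset: documents are d
# copies of a random {A,C,G}-sequence terminated by the only T in the index,
# so every suffix of a read ending at the terminal has all its occurrences
# preceded by one and the same character.
noResetCollection <- function(d = 3L, len = 120L) {
  doc <- paste0(randomSeq(len - 1L, c("A", "C", "G")), "T")
  documentCollection(rep(doc, d), paste0("copy", seq_len(d)))
}

# Independent reverse complement (chartr-based; no Biostrings)
naiveRevcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Naive O(n^2 log n) suffix structures from integer codes
naiveSuffixStructures <- function(codes) {
  n <- length(codes)
  sufs <- vapply(seq_len(n), function(i)
    paste(sprintf("%03d", codes[i:n]), collapse = "."), character(1))
  sa <- order(sufs, method = "radix")
  lcp <- integer(n)
  for (i in 2:n) {
    a <- codes[sa[i - 1]:n]; b <- codes[sa[i]:n]
    k <- 0L
    while (k < length(a) && k < length(b) && a[k + 1L] == b[k + 1L]) k <- k + 1L
    lcp[i] <- k
  }
  prev <- sa - 1L; prev[prev == 0L] <- n
  list(sa = sa, lcp = lcp, bwt = codes[prev])
}

# Mutate an exact read with SNV errors
mutateRead <- function(read, rate) {
  x <- strsplit(read, "")[[1]]
  e <- which(stats::runif(length(x)) < rate)
  if (length(e))
    x[e] <- vapply(x[e], function(b) sample(setdiff(BASES, b), 1L),
                   character(1))
  paste(x, collapse = "")
}

# Random substring read from a collection document
sampleRead <- function(coll, len) {
  lens <- nchar(coll@seqs)
  doc <- sample(which(lens >= len), 1L)
  at <- sample.int(lens[doc] - len + 1L, 1L)
  substring(coll@seqs[doc], at, at + len - 1L)
}

expect_same_mums <- function(coll, minLen = 1L) {
  ct <- concatText(coll)
  ss <- buildSuffixStructures(ct)
  a <- mumTableForComparison(findMultiMUMs(ss, ct@d, minLen), coll)
  b <- bruteForceMultiMUMs(coll, minLen)
  expect_equal(a, b, ignore_attr = TRUE)
}
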