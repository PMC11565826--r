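test_that("suffix structures match a naive suffix-sort oracle", {
  set.seed(7)
  cases <- c(list(documentCollection(c("ACAC", "ACAC"))),
             lapply(1:6, function(i) randomCollection(sample(2:4, 1L),
                                                      maxLen = 60L)))
  for (coll in cases) {
    ct <- concatText(coll)
    ss <- buildSuffixStructures(ct)
    ref <- naiveSuffixStructures(ct@codes)
    expect_identical(ss@sa, ref$sa)
    expect_identical(ss@lcp, ref$lcp)
    expect_identical(ss@bwt, ref$bwt)
    expect_identical(ss@da, docOf(ct, ss@sa))
  }
})

test_that("degenerate one-symbol texts are handled", {
  expect_equal(colbwt:::sa_build_cpp(1L), 0L)
  expect_equal(colbwt:::lcp_kasai_cpp(1L, 0L), 0L)
  ct <- concatText(documentCollection("A"))
  ss <- buildSuffixStructures(ct)
  expect_equal(ss@sa, c(2L, 1L))               # sentinel suffix sorts first
})

test_that("run-length encoding is maximal and matches a one-pass scan", {
  set.seed(11)
  for (rep in 1:5) {
    ct <- concatText(randomCollection(3L, maxLen = 80L))
    ss <- buildSuffixStructures(ct)
    rl <- runLengthEncode(ss)
    expect_equal(rl@r, sum(diff(ss@bwt) != 0L) + 1L)   # scan oracle
    expect_identical(rep(rl@runChar, rl@runLen), ss@bwt)
    expect_true(validObject(rl))
  }
})

test_that("LF and FL are mutually inverse permutations and the BWT inverts", {
  set.seed(13)
  coll <- documentCollection(c(randomSeq(100L), randomSeq(96L)))
  ct <- concatText(coll)
  ss <- buildSuffixStructures(ct)
  mt <- buildMoveTables(runLengthEncode(ss))
  n <- ct@n
  expect_identical(lfMap(mt, flMap(mt, 1:n)), 1:n)
  expect_identical(flMap(mt, lfMap(mt, 1:n)), 1:n)
  # LF direct definition: SA[LF(i)] = SA[i] - 1 (mod n)
  lf <- lfMap(mt, 1:n)
  expect_identical(ss@sa[lf], ifelse(ss@sa == 1L, n, ss@sa - 1L))
  # the LF orbit from any position visits every BWT position exactly once
  seen <- integer(n); p <- 5L
  for (k in 1:n) { seen[p] <- seen[p] + 1L; p <- lfMap(mt, p) }
  expect_true(all(seen == 1L))
  expect_identical(bwtInvert(ss, mt), ct@codes)
})

test_that("flRange flags non-contiguous images found by brute force", {
  set.seed(17)
  found <- FALSE
  agree <- TRUE
  for (rep in 1:8) {
    ct <- concatText(randomCollection(2L, maxLen = 40L))
    ss <- buildSuffixStructures(ct)
    mt <- buildMoveTables(runLengthEncode(ss))
    n <- ct@n
    # brute-force FL from the SA definition
    rankOf <- order(ss@sa)
    for (lo in 1:(n - 2L)) {
      hi <- lo + 2L
      img <- rankOf[ifelse(ss@sa[lo:hi] == n, 1L, ss@sa[lo:hi] + 1L)]
      st <- flRange(mt, lo, hi)
      agree <- agree && setequal(st$image, img) &&
        st$contiguous == (max(img) - min(img) == hi - lo)
      if (!st$contiguous) found <- TRUE
    }
  }
  expect_true(agree)   # image and flag match brute-force FL everywhere
  expect_true(found)   # non-contiguous ranges do arise and are flagged
})

test_that("thresholds are LCP argmins strictly between successive equal-character runs", {
  set.seed(19)
  for (rep in 1:6) {
    coll <- relatedCollection(2L, sample(100:250, 1L))
    ct <- concatText(coll)
    ss <- buildSuffixStructures(ct)
    rl <- runLengthEncode(ss)
    th <- computeThresholds(ss, rl)
    # exhaustive re-scan oracle over every consecutive same-symbol run pair
    ok <- TRUE
    for (c in unique(rl@runChar)) {
      j <- which(rl@runChar == c)
      if (length(j) < 2L) {
        ok <- ok && length(th@charThr[[c]]) == 0L
        next
      }
      f <- rl@runStart[j]; l <- f + rl@runLen[j] - 1L
      for (k in seq_len(length(j) - 1L)) {
        span <- (l[k] + 1L):f[k + 1L]
        t <- th@charThr[[c]][k]
        ok <- ok && t > l[k] && t <= f[k + 1L] &&     # strictly between runs
          t == span[which.min(ss@lcp[span])]          # argmin, smallest tie
      }
    }
    expect_true(ok)
  }
})
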