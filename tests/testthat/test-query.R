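test_that("exact reads over a reset-free fixture give full PML ramps", {
  set.seed(73)
  coll <- noResetCollection(d = 3L, len = 100L)
  idx <- colbwtBuild(coll)
  doc <- unname(docSeqs(coll))[1L]
  for (m in c(10L, 40L, 100L)) {
    read <- substring(doc, nchar(doc) - m + 1L, nchar(doc))
    r <- queryPmlCid(idx, read)
    expect_identical(r$pml, m:1)      # uninterrupted extension
  }
})

test_that("reads with no indexable symbol give all-zero PML and CID", {
  coll <- documentCollection(c("ACGTAC", "ACGTCC"))
  idx <- colbwtBuild(coll)
  r <- queryPmlCid(idx, "NNNNN")
  expect_identical(r$pml, rep(0L, 5L))
  expect_identical(r$cid, rep(0L, 5L))
  expect_identical(queryPmlCid(idx, "")$pml, integer(0))
})

test_that("ambiguous read symbols force a reset mid-read", {
  set.seed(79)
  coll <- noResetCollection(d = 2L, len = 60L)
  idx <- colbwtBuild(coll)
  doc <- unname(docSeqs(coll))[1L]
  read <- substring(doc, 31L, 60L)
  broken <- paste0(substring(read, 1L, 9L), "N", substring(read, 11L, 30L))
  r <- queryPmlCid(idx, broken)
  expect_equal(r$pml[10L], 0L)
  expect_true(is.na(r$trace[10L]))
})

test_that("PML never exceeds the exact matching statistic and is genuine", {
  set.seed(83)
  coll <- relatedCollection(3L, 600L)
  idx <- colbwtBuild(coll, idBits = 16L)
  docs <- unname(docSeqs(coll))
  for (q in 1:25) {
    rd <- mutateRead(sampleRead(coll, 80L), 0.03)
    r <- queryPmlCid(idx, rd)
    ms <- queryMsOracle(idx, rd)
    expect_true(all(r$pml <= ms$len))
    # every nonzero PML names a substring present in some document
    for (i in which(r$pml > 0L & seq_along(r$pml) %% 7L == 0L)) {
      frag <- substring(rd, i, i + r$pml[i] - 1L)
      expect_true(any(vapply(docs, grepl, logical(1), pattern = frag,
                             fixed = TRUE)))
    }
  }
})

test_that("the exact matching-statistics oracle is itself verified", {
  set.seed(89)
  coll <- relatedCollection(2L, 200L)
  idx <- colbwtBuild(coll)
  doc <- unname(docSeqs(coll))[1L]
  # full-match read: len must ramp
  read <- substring(doc, 51L, 110L)
  ms <- queryMsOracle(idx, read)
  expect_identical(ms$len, 60:1)
  # absent symbol
  expect_identical(queryMsOracle(idx, "NNN")$len, rep(0L, 3L))
  # agreement with a direct double-loop longest-prefix search
  rd <- mutateRead(sampleRead(coll, 25L), 0.1)
  ms <- queryMsOracle(idx, rd)
  txt <- paste(unlist(strsplit(docs <- unname(docSeqs(coll)), "")),
               collapse = "")   # per-document scan below avoids separators
  naiveLen <- vapply(seq_len(nchar(rd)), function(i) {
    best <- 0L
    for (s in docs) for (j in seq_len(nchar(s))) {
      k <- 0L
      while (i + k <= nchar(rd) && j + k <= nchar(s) &&
             substring(rd, i + k, i + k) == substring(s, j + k, j + k))
        k <- k + 1L
      best <- max(best, k)
    }
    best
  }, integer(1))
  expect_identical(ms$len, naiveLen)
  # reported occurrence positions are genuine
  ct <- idx@oracle$ss@text
  for (i in which(ms$len > 0L)) {
    at <- ms$pos[i]
    got <- paste(c("A", "C", "G", "T", "N")[ct@codes[at:(at + ms$len[i] - 1L)]
                                            - ct@d], collapse = "")
    expect_identical(got, substring(rd, i, i + ms$len[i] - 1L))
  }
})

test_that("per-read work is linear: at most two index steps per position", {
  set.seed(97)
  coll <- relatedCollection(4L, 500L)
  idx <- colbwtBuild(coll)
  for (q in 1:10) {
    m <- sample(20:200, 1L)
    r <- queryPmlCid(idx, mutateRead(sampleRead(coll, m), 0.05))
    expect_lte(r$steps, 2 * m)
  }
})

test_that("chain ids are sound against the tunnel position oracle", {
  set.seed(101)
  coll <- relatedCollection(3L, 500L)
  idx <- colbwtBuild(coll, sampleRate = 1L, idBits = 32L)
  o <- idx@oracle
  idmap <- tunnelIdMap(o$tunnels)
  ct <- o$ss@text
  for (q in 1:15) {
    rd <- mutateRead(sampleRead(coll, 120L), 0.02)
    r <- queryPmlCid(idx, rd)
    for (i in which(r$cid > 0L)) {
      g <- r$cid[i]
      expect_equal(idmap[r$trace[i]], g)   # tracked position inside tunnel g
      tp <- o$ss@sa[r$trace[i]]
      dd <- docOf(ct, tp)
      lp <- tp - ct@docStart[dd] + 1L
      j <- match(g, o$mums@ids)
      pj <- o$mums@positions[j, dd]
      # text position within the occurrence swept by columns 1..w'
      expect_gte(lp, pj + 1L)
      expect_lte(lp, pj + o$mums@w[j])
    }
  }
})

test_that("queries are deterministic and independent of oracle structures", {
  set.seed(103)
  coll <- relatedCollection(3L, 300L)
  idx <- colbwtBuild(coll)
  rd <- mutateRead(sampleRead(coll, 100L), 0.02)
  r1 <- queryPmlCid(idx, rd)
  r2 <- queryPmlCid(idx, rd)
  r3 <- queryPmlCid(stripOracle(idx), rd)
  expect_identical(r1, r2)
  expect_identical(r1, r3)
  expect_error(queryMsOracle(stripOracle(idx), rd),
               class = "colbwt_input_error")
})
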