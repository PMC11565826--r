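nullModel <- function(k, thr = significantPeakThreshold(k), rho = 0,
                      window = 150L) {
  new("NullModel", k = as.integer(k), peakThreshold = as.integer(thr),
      rhoNull = rho, minCount = 5L, window = as.integer(window),
      nNull = 0L, lenNull = 0L, seed = 0L)
}

test_that("the significant-peak threshold follows the ceiling formula", {
  expect_equal(significantPeakThreshold(5L), 3L)
  expect_equal(significantPeakThreshold(0L), 1L)
  expect_equal(significantPeakThreshold(20L), 11L)
})

test_that("peak extraction segments decreasing-by-one PML ramps", {
  pk <- extractPeaks(list(pml = c(4L, 3L, 2L, 1L), cid = rep(0L, 4L)))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$height, 4L)
  expect_equal(c(pk$start, pk$end), c(1L, 4L))

  pk <- extractPeaks(list(pml = c(3L, 2L, 1L, 0L, 5L, 4L, 3L, 2L, 1L),
                          cid = rep(0L, 9L)))
  expect_equal(pk$height, c(3L, 5L))
  expect_equal(pk$start, c(1L, 5L))
  expect_equal(pk$end, c(3L, 9L))

  expect_equal(nrow(extractPeaks(list(pml = rep(0L, 6L),
                                      cid = rep(0L, 6L)))), 0L)
  # a rise inside positive values starts a new peak
  pk <- extractPeaks(list(pml = c(1L, 3L, 2L), cid = c(0L, 0L, 0L)))
  expect_equal(pk$height, c(1L, 3L))
  # boundary ids are first/last nonzero chain ids in the span
  pk <- extractPeaks(list(pml = c(5L, 4L, 3L, 2L, 1L),
                          cid = c(0L, 7L, 0L, 9L, 0L)))
  expect_equal(c(pk$first_id, pk$last_id), c(7L, 9L))
})

test_that("co-linear pairing compares boundary ids of significant peaks", {
  peaks <- data.frame(start = c(1L, 10L), end = c(5L, 14L),
                      height = c(5L, 5L), first_id = c(7L, 7L),
                      last_id = c(7L, 7L))
  expect_equal(colinearPairs(peaks, 3L)$colinear, 1L)
  peaks$first_id <- c(7L, 9L); peaks$last_id <- c(7L, 9L)
  expect_equal(colinearPairs(peaks, 3L)$colinear, 0L)
  # zero ids never pair
  peaks$first_id <- peaks$last_id <- c(0L, 0L)
  expect_equal(colinearPairs(peaks, 3L)$colinear, 0L)
  # an insignificant peak between two significant ones is ignored
  peaks <- data.frame(start = c(1L, 7L, 12L), end = c(5L, 8L, 16L),
                      height = c(5L, 2L, 5L), first_id = c(4L, 9L, 4L),
                      last_id = c(4L, 9L, 4L))
  co <- colinearPairs(peaks, 3L)
  expect_equal(co$pairs, 1L)
  expect_equal(co$colinear, 1L)
})

test_that("merging co-linear peaks never decreases a PML", {
  set.seed(107)
  null <- nullModel(5L)
  for (rep in 1:20) {
    m <- 40L
    pml <- integer(m); i <- 1L
    while (i <= m) {
      h <- sample(0:8, 1L)
      seg <- if (h == 0L) 0L else h:1
      take <- seq_len(min(length(seg), m - i + 1L))
      pml[i + take - 1L] <- seg[take]
      i <- i + length(take)
    }
    cid <- sample(0:2, m, replace = TRUE)
    aug <- augmentPml(list(pml = pml, cid = cid), null)
    expect_true(all(aug >= pml))
  }
})

test_that("scheme c is exactly baseline OR scheme a and windows majority is strict", {
  null <- nullModel(3L, rho = 0, window = 10L)
  mk <- function(pml, cid = rep(0L, length(pml))) list(pml = pml, cid = cid)
  # one window (short read): any PML > k passes
  short <- classifyRead(mk(c(0L, 4L, 3L)), null)
  expect_true(short$baseline)
  expect_equal(short$windows, 1L)
  # exactly half the windows passing is not a majority
  pml <- c(rep(5L, 10L), rep(0L, 10L))
  expect_false(classifyRead(mk(pml), null)$baseline)
  # identity on random inputs
  set.seed(109)
  for (rep in 1:25) {
    res <- mk(sample(0:6, 35L, replace = TRUE),
              sample(0:3, 35L, replace = TRUE))
    row <- classifyRead(res, nullModel(3L, rho = 1e-3, window = 10L))
    expect_identical(row$scheme_c, row$baseline || row$scheme_a)
  }
})

test_that("calibration recovers k, the peak threshold and the null rate", {
  set.seed(113)
  coll <- relatedCollection(3L, 3000L, snvRate = 0.01)
  idx <- colbwtBuild(coll)
  null <- calibrateNull(idx, coll, nNull = 40L, lenNull = 500L, seed = 5L)
  null2 <- calibrateNull(idx, coll, nNull = 40L, lenNull = 500L, seed = 5L)
  expect_identical(null@k, null2@k)            # reproducible under the seed
  expect_identical(null@rhoNull, null2@rhoNull)
  expect_gt(null@k, 0L)
  # reversed substrings should look like chance: k far below a genuine match
  expect_lt(null@k, 40L)
  expect_equal(null@peakThreshold, significantPeakThreshold(null@k))
  expect_gte(null@rhoNull, 0)
})

test_that("end-to-end verdicts separate genuine reads from foreign reads", {
  set.seed(127)
  coll <- relatedCollection(4L, 4000L, snvRate = 0.005)
  idx <- colbwtBuild(coll, sampleRate = 2L)
  null <- calibrateNull(idx, coll, nNull = 50L, lenNull = 600L, seed = 9L)
  pos <- vapply(1:8, function(i) mutateRead(sampleRead(coll, 600L), 0.01),
                character(1))
  neg <- vapply(1:8, function(i) randomSeq(600L), character(1))
  calls <- classifyReads(idx, stats::setNames(c(pos, neg), paste0("r", 1:16)),
                         null)
  truth <- rep(c(TRUE, FALSE), each = 8L)
  expect_true(all(calls$baseline[truth]))
  expect_true(all(!calls$baseline[!truth]))
  expect_identical(calls$scheme_c, calls$baseline | calls$scheme_a)
  # positive calls of the combined scheme include the baseline's
  expect_true(all(calls$scheme_c[calls$baseline]))
  m <- classificationMetrics(calls, truth, "scheme_c")
  mb <- classificationMetrics(calls, truth, "baseline")
  expect_gte(m["sensitivity"], mb["sensitivity"])
  expect_lte(m["specificity"], mb["specificity"])
})
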