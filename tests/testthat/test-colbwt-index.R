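test_that("sub-runs reproduce the BWT and respect the sub-run count bound", {
  set.seed(53)
  for (rep in 1:4) {
    coll <- relatedCollection(sample(2:5, 1L), sample(200:500, 1L))
    idx <- colbwtBuild(coll, sampleRate = 1L)
    ss <- idx@oracle$ss
    expect_identical(rep(idx@subChar, idx@subLen), ss@bwt)
    uCols <- length(unique(unlist(idx@oracle$tunnels@colStarts)))
    expect_lte(idx@rPrime, idx@r + 2L * uCols)
    expect_lte(uCols, idx@n / idx@d)
    # every marked sub-run is one full tunnel column of height d
    marked <- which(idx@subId > 0L)
    expect_true(all(idx@subLen[marked] == idx@d))
  }
})

test_that("sub-sampling marks offset 0, s, 2s, ... from each tunnel start", {
  set.seed(59)
  coll <- relatedCollection(3L, 400L)
  full <- colbwtBuild(coll, sampleRate = 1L)
  ts <- full@oracle$tunnels
  sparse <- colbwtBuild(coll, sampleRate = 3L)
  expectMarked <- sort(unique(unlist(lapply(seq_along(ts@mumId), function(t) {
    st <- ts@colStarts[[t]]
    if (!length(st)) return(integer(0))
    as.integer(outer(st[seq(1L, length(st), by = 3L)], 0:(ts@d - 1L), "+"))
  }))))
  got <- which(rep(sparse@subId, sparse@subLen) > 0L)
  expect_identical(got, expectMarked)
  # s larger than every realized width marks exactly the first column
  one <- colbwtBuild(coll, sampleRate = max(ts@wPrime) + 1L)
  nMarked <- sum(one@subId > 0L)
  expect_equal(nMarked, sum(ts@wPrime > 0L))
})

test_that("id binning wraps with 0 reserved and equal ids stay equal", {
  expect_equal(colbwt:::binId(1L, 8L), 1L)
  expect_equal(colbwt:::binId(255L, 8L), 255L)
  expect_equal(colbwt:::binId(256L, 8L), 1L)     # wraps past 2^8 - 1
  expect_equal(colbwt:::binId(300L, 8L), 45L)
  expect_equal(colbwt:::binId(300L, 16L), 300L)
  ids <- 1:1000
  expect_true(all(colbwt:::binId(ids, 8L) >= 1L &
                  colbwt:::binId(ids, 8L) <= 255L))
  # equality of true ids implies equality of stored ids (no false negatives)
  expect_true(all(colbwt:::binId(ids, 8L) == colbwt:::binId(ids, 8L)))
})

test_that("id collisions at 8 bits are permitted and logged", {
  set.seed(61)
  coll <- relatedCollection(2L, 12000L, snvRate = 0.02)   # several hundred MUMs
  expect_message(idx <- colbwtBuild(coll, idBits = 8L), "binning merged")
  expect_gt(idx@nIdCollisions, 0L)
  expect_gt(nrow(idx@mumTable), 255L)
  wide <- suppressMessages(colbwtBuild(coll, idBits = 16L))
  expect_equal(wide@nIdCollisions, 0L)
})

test_that("idAt reports the sub-run id at any BWT position", {
  set.seed(67)
  coll <- relatedCollection(3L, 300L)
  idx <- colbwtBuild(coll, sampleRate = 1L, idBits = 16L)
  ts <- idx@oracle$tunnels
  idmap <- tunnelIdMap(ts)
  expect_identical(idAt(idx, seq_len(idx@n)), as.integer(idmap))
  # all positions of one marked column share the id
  t <- which(ts@wPrime > 0L)[1L]
  q <- ts@colStarts[[t]][1L]
  expect_equal(length(unique(idAt(idx, q:(q + idx@d - 1L)))), 1L)
  expect_error(idAt(idx, 0L), class = "colbwt_input_error")
  expect_error(idAt(idx, idx@n + 1L), class = "colbwt_input_error")
})

test_that("serialization round-trips and rejects corrupt containers", {
  set.seed(71)
  coll <- relatedCollection(2L, 150L)
  idx <- colbwtBuild(coll)
  path <- tempfile(fileext = ".colbwt")
  colbwtSave(idx, path)
  back <- colbwtLoad(path)
  expect_identical(back@subStart, idx@subStart)
  expect_identical(back@subId, idx@subId)
  expect_length(back@oracle, 0L)               # production index by default
  expect_identical(idAt(back, seq_len(idx@n)), idAt(idx, seq_len(idx@n)))
  # queries agree before and after the round trip
  rd <- sampleRead(coll, 40L)
  expect_identical(queryPmlCid(back, rd), queryPmlCid(idx, rd))
  # corrupted magic bytes
  raw <- readBin(path, "raw", file.size(path))
  raw[2L] <- as.raw(88L)
  writeBin(raw, path)
  expect_error(colbwtLoad(path), class = "colbwt_input_error")
})
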