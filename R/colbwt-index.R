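#' Split the RLBWT into id-carrying sub-runs (col-BWT)
#'
#' Tunnel columns at step offsets 0, s, 2s, ... within each tunnel (offset
#' measured from the tunnel's first column, so the first column is always
#' marked) are marked with the tunnel's binned multi-MUM id; BWT runs are
#' split only where a marked range boundary falls inside a run. Id binning
#' stores 1 + ((id - 1) mod (2^idBits - 1)), keeping 0 reserved for unmarked
#' sub-runs; collisions produce false-positive id equality, never false
#' negatives, and are counted.
#'
#' @param rl an [RLBWT-class].
#' @param ts a [TunnelSet-class] over the same BWT.
#' @param sampleRate mark every sampleRate-th column of each tunnel (s >= 1).
#' @param idBits stored id width, one of 8, 16, 32.
#' @return list with the sub-run arrays (subStart, subChar, subLen, subId),
#'   rPrime, idvec diagnostics (nIdCollisions, markedFraction).
#' @export
buildColBWTSubruns <- function(rl, ts, sampleRate = 1L, idBits = 8L) {
  stopifnot(sampleRate >= 1L, idBits %in% c(8L, 16L, 32L))
  n <- rl@n
  idvec <- integer(n)
  colBnd <- logical(n + 1L)   # forced sub-run boundaries at column edges
  used <- integer(0)
  for (t in seq_along(ts@mumId)) {
    starts <- ts@colStarts[[t]]
    if (!length(starts)) next
    samp <- starts[seq(1L, length(starts), by = sampleRate)]
    pos <- as.integer(outer(samp, 0:(ts@d - 1L), "+"))
    idvec[pos] <- binId(ts@mumId[t], idBits)
    colBnd[samp] <- TRUE
    colBnd[samp + ts@d] <- TRUE
    used <- c(used, ts@mumId[t])
  }
  nColl <- length(unique(used)) - length(unique(binId(unique(used), idBits)))
  if (nColl > 0L)
    message(sprintf("col-BWT id binning merged %d id(s) (idBits=%d)", nColl,
                    idBits))
  runIdx <- rep.int(seq_len(rl@r), rl@runLen)
  newSub <- c(TRUE, runIdx[-1L] != runIdx[-n] | idvec[-1L] != idvec[-n]) |
    colBnd[seq_len(n)]
  subStart <- which(newSub)
  list(subStart = as.integer(subStart),
       subChar = rl@runChar[runIdx[subStart]],
       subLen = as.integer(diff(c(subStart, n + 1L))),
       subId = idvec[subStart],
       rPrime = length(subStart),
       nIdCollisions = as.integer(nColl),
       markedFraction = mean(idvec > 0L))
}

#' Build a complete col-BWT index from a document collection
#'
#' Runs the whole pipeline: concatenation with separators, suffix structures,
#' run-length BWT, move tables, thresholds, multi-MUM finding, tunnel
#' construction, and sub-run splitting with id marking. The returned index
#' answers [queryPmlCid()] from the sub-run arrays, LF move table, thresholds
#' and ids alone; the full structures are kept in the \code{oracle} slot
#' (unless \code{keepOracle = FALSE}) for test oracles and are not consulted
#' by the production query path.
#'
#' @param coll a [DocumentCollection-class] with d >= 2 documents.
#' @param minMumLen minimum multi-MUM width (default 1).
#' @param mode tunnel mode, "tunnels" (non-overlapping, default) or "all".
#' @param sampleRate id sub-sampling parameter s (default 1: mark every
#'   column).
#' @param idBits stored id width in bits (8, 16 or 32; default 8).
#' @param revcomp append each document's reverse complement before indexing.
#' @param keepOracle retain full suffix structures for oracle/test modes.
#' @param verbose log build statistics (u, r, r', coverage).
#' @return a [ColBWT-class] index.
#' @export
colbwtBuild <- function(coll, minMumLen = 1L, mode = c("tunnels", "all"),
                        sampleRate = 1L, idBits = 8L, revcomp = FALSE,
                        keepOracle = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  if (length(coll@seqs) < 2L)
    inputError("col-BWT indexing requires at least 2 documents")
  if (revcomp) coll <- augmentRevcomp(coll)
  ct <- concatText(coll)
  ss <- buildSuffixStructures(ct)
  rl <- runLengthEncode(ss)
  mt <- buildMoveTables(rl)
  th <- computeThresholds(ss, rl)
  mums <- findMultiMUMs(ss, ct@d, minMumLen)
  ts <- buildTunnels(mums, mt, mode)
  sub <- buildColBWTSubruns(rl, ts, sampleRate, idBits)
  lf <- runLfTable(sub$subChar, sub$subLen, sub$subStart)
  tunnelCov <- length(unique(claimedPositions(ts))) / ct@n
  if (verbose)
    message(sprintf(
      "col-BWT build: n=%d d=%d u=%d r=%d r'=%d coverage tunnel=%.1f%% marked=%.1f%%",
      ct@n, ct@d, mums@u, rl@r, sub$rPrime, 100 * tunnelCov,
      100 * sub$markedFraction))
  idx <- new("ColBWT",
    subStart = sub$subStart, subChar = sub$subChar, subLen = sub$subLen,
    subId = sub$subId, rPrime = as.integer(sub$rPrime),
    subLfPos = lf$lfPos,
    subLfDest = findInterval(lf$lfPos, sub$subStart),
    charRunFirst = th@charRunFirst, charRunLast = th@charRunLast,
    charThr = th@charThr,
    n = ct@n, d = ct@d, r = rl@r, sigma = as.integer(ct@d + 5L),
    docNames = ct@docNames, docLen = ct@docLen,
    params = list(mode = mode, sampleRate = as.integer(sampleRate),
                  idBits = as.integer(idBits),
                  minMumLen = as.integer(minMumLen), revcomp = revcomp),
    mumTable = data.frame(id = mums@ids, binnedId = binId(mums@ids, idBits),
                          s = mums@s, w = mums@w,
                          wPrime = ts@wPrime[order(ts@mumId)])[
                            seq_len(mums@u), , drop = FALSE],
    nIdCollisions = sub$nIdCollisions,
    coverage = list(tunnel = tunnelCov, marked = sub$markedFraction),
    oracle = if (keepOracle)
      list(ss = ss, rl = rl, mt = mt, th = th, mums = mums, tunnels = ts,
           collection = coll)
    else list(),
    version = "colbwt-1")
  validObject(idx)
  idx
}

#' Drop the oracle structures from an index
#'
#' Returns a production-only index: the query path is unchanged, asserting
#' the interface boundary between the compressed index and the full arrays.
#' @param index a [ColBWT-class].
#' @return the index without oracle structures.
#' @export
stripOracle <- function(index) {
  index@oracle <- list()
  index
}

#' Sub-run id at a BWT position
#'
#' @param index a [ColBWT-class].
#' @param p 1-based BWT positions (vectorized).
#' @return stored (binned) ids; 0 where unmarked.
#' @export
idAt <- function(index, p) {
  if (any(p < 1L | p > index@n)) inputError("BWT position out of range")
  index@subId[findInterval(p, index@subStart)]
}

#' Serialize a col-BWT index to a versioned container
#'
#' A magic tag and format version precede the payload so truncation or a
#' foreign file is reported clearly.
#'
#' @param index a [ColBWT-class].
#' @param path output file path.
#' @param includeOracle also store the full structures (larger file).
#' @return the path, invisibly.
#' @export
colbwtSave <- function(index, path, includeOracle = FALSE) {
  if (!includeOracle) index <- stripOracle(index)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("COLBWTIDX1\n"), con)
  writeBin(serialize(index, NULL, version = 3L), con)
  invisible(path)
}

#' Load a serialized col-BWT index
#'
#' @param path file written by [colbwtSave()].
#' @return a [ColBWT-class].
#' @export
colbwtLoad <- function(path) {
  if (!file.exists(path)) inputError("index file not found: %s", path)
  raw <- readBin(path, what = "raw", n = file.size(path))
  magic <- charToRaw("COLBWTIDX1\n")
  if (length(raw) < length(magic) ||
      !identical(raw[seq_along(magic)], magic))
    inputError("not a col-BWT index (bad magic/version): %s", path)
  idx <- tryCatch(unserialize(raw[-seq_along(magic)]),
                  error = function(e)
                    inputError("corrupt or truncated index: %s", path))
  if (!is(idx, "ColBWT") || !identical(idx@version, "colbwt-1"))
    inputError("index format version mismatch: %s", path)
  idx
}
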