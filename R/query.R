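# Encode a read against an index alphabet. A, C, G, T map to index codes;
# N and any foreign character map to 0, which the query kernel treats as an
# always-mismatching symbol that forces a reset.
encodeRead <- function(index, read) {
  b <- baseCode(splitChars(toupper(read)))
  code <- index@d + b
  code[is.na(b) | b == 5L] <- 0L
  code
}

# 0-based navigation tables handed to the C++ kernel, built once per batch.
queryTables <- function(index) {
  list(subStart = index@subStart - 1L,
       subChar = index@subChar,
       subId = index@subId,
       subLfPos = index@subLfPos - 1L,
       subLfDest = index@subLfDest - 1L,
       charRunFirst = lapply(index@charRunFirst, function(x) x - 1L),
       charRunLast = lapply(index@charRunLast, function(x) x - 1L),
       charThr = lapply(index@charThr, function(x) x - 1L))
}

#' Pseudo-matching lengths and chain statistics for one read
#'
#' One right-to-left pass over the read keeps a tracked BWT position and a
#' current match length. A position whose BWT symbol equals the next read
#' symbol extends the match by one LF step; on mismatch the thresholds direct
#' a jump to the nearest run of the wanted symbol (to the run above when the
#' tracked position is at or above the threshold separating the flanking
#' runs, below otherwise), the length resets, and one LF step restarts the
#' match at length 1. The chain id CID[i] is the sub-run id at the tracked
#' position after the step for read position i (0 when unmarked). Work is
#' linear in the read length: at most one jump and one LF step per position.
#'
#' @param index a [ColBWT-class].
#' @param read a DNA string; N (or any foreign character) always mismatches
#'   and forces a reset.
#' @param tables precomputed [queryTables()] output (internal, for batching).
#' @return list(pml, cid, trace, steps): per-position pseudo-matching lengths
#'   and chain ids, the tracked BWT position per step (1-based; NA on reset
#'   positions), and the number of index steps taken.
#' @export
queryPmlCid <- function(index, read, tables = NULL) {
  if (is.null(tables)) tables <- queryTables(index)
  pat <- encodeRead(index, read)
  if (!length(pat))
    return(list(pml = integer(0), cid = integer(0), trace = integer(0),
                steps = 0))
  res <- pml_query_cpp(pat, tables$subStart, tables$subChar, tables$subId,
                       tables$subLfPos, tables$subLfDest,
                       tables$charRunFirst, tables$charRunLast,
                       tables$charThr, 0L)
  res$trace <- res$trace + 1L
  res
}

#' Batch query: PML and CID arrays for many reads
#'
#' @param index a [ColBWT-class].
#' @param reads named character vector of reads.
#' @return named list of [queryPmlCid()] results.
#' @export
queryReads <- function(index, reads) {
  tables <- queryTables(index)
  lapply(reads, function(r) queryPmlCid(index, r, tables = tables))
}

#' Exact matching statistics (oracle mode)
#'
#' Computes, for every read position, the length of the longest prefix of
#' P[i..m] occurring anywhere in the indexed text plus one occurrence, by
#' per-suffix binary search over the retained suffix array. Requires an index
#' built with \code{keepOracle = TRUE}; this path is a test oracle and an
#' upper bound for pseudo-matching lengths, not the production query.
#'
#' @param index a [ColBWT-class] with oracle structures.
#' @param read a DNA string.
#' @return list(len, pos): per-position lengths and 1-based text occurrence
#'   positions (NA where length 0).
#' @export
queryMsOracle <- function(index, read) {
  if (!length(index@oracle))
    inputError("matching-statistics oracle requires an index built with keepOracle = TRUE")
  ss <- index@oracle$ss
  pat <- encodeRead(index, read)
  res <- ms_oracle_cpp(ss@text@codes, ss@sa - 1L, pat)
  pos <- res$pos + 1L
  pos[res$len == 0L] <- NA_integer_
  list(len = res$len, pos = pos)
}

#' Write query results as a SPUMONI-style TSV
#'
#' One row per read: read id, space-separated PML array, space-separated CID
#' array. Header lines (prefixed with #) echo the index configuration.
#'
#' @param results output of [queryReads()].
#' @param index the [ColBWT-class] queried.
#' @param path output file.
#' @export
writeQueryTsv <- function(results, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# colbwt query: n=%d d=%d mode=%s s=%d idBits=%d",
                     index@n, index@d, index@params$mode,
                     index@params$sampleRate, index@params$idBits), con)
  writeLines("# read_id\tpml\tcid", con)
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("read", seq_along(results))
  for (i in seq_along(results)) {
    writeLines(paste(nm[i], paste(results[[i]]$pml, collapse = " "),
                     paste(results[[i]]$cid, collapse = " "), sep = "\t"), con)
  }
  invisible(path)
}
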