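#' Convert multi-MUM SA windows into non-overlapping BWT tunnels
#'
#' Multi-MUMs are processed in descending width order (ties by ascending SA
#' rank). Starting from each multi-MUM's d-wide SA window, the FL map is
#' applied repeatedly; a forward step is accepted only if (a) the image is a
#' contiguous block, (b) the step count does not exceed the multi-MUM's width,
#' and (c), in mode "tunnels", no image position has been claimed by an
#' earlier tunnel. The first violation stops the tunnel (a collision truncates
#' it). In mode "all", every contiguous forward-step column is recorded
#' without the claim check; overlapping positions later carry the id written
#' last in processing order.
#'
#' @param mums a [MultiMUMSet-class].
#' @param mt a [MoveTables-class] over the same BWT.
#' @param mode "tunnels" (disjoint) or "all".
#' @return a [TunnelSet-class]; tunnels appear in processing order.
#' @export
buildTunnels <- function(mums, mt, mode = c("tunnels", "all")) {
  mode <- match.arg(mode)
  d <- mums@d
  n <- mt@n
  ord <- order(-mums@w, mums@s)
  claimed <- logical(n)
  ids <- integer(0); ws <- integer(0); wps <- integer(0)
  cols <- list()
  for (t in ord) {
    lo <- mums@s[t]; hi <- lo + d - 1L
    starts <- integer(0)
    for (x in seq_len(mums@w[t])) {
      st <- flRange(mt, lo, hi)
      if (!st$contiguous) break
      if (mode == "tunnels" && any(claimed[st$lo:st$hi])) break
      starts[x] <- st$lo
      if (mode == "tunnels") claimed[st$lo:st$hi] <- TRUE
      lo <- st$lo; hi <- st$hi
    }
    ids <- c(ids, mums@ids[t])
    ws <- c(ws, mums@w[t])
    wps <- c(wps, length(starts))
    cols[[length(cols) + 1L]] <- starts
  }
  new("TunnelSet", mumId = ids, w = ws, wPrime = wps, colStarts = cols,
      d = as.integer(d), n = as.integer(n), mode = mode)
}

#' All BWT positions claimed by a tunnel set
#'
#' @param ts a [TunnelSet-class].
#' @return integer vector of claimed positions (with duplicates in mode
#'   "all" if tunnels overlap).
#' @export
claimedPositions <- function(ts) {
  starts <- unlist(ts@colStarts, use.names = FALSE)
  if (!length(starts)) return(integer(0))
  as.integer(outer(starts, 0:(ts@d - 1L), "+"))
}

#' Per-position tunnel id map
#'
#' Expands a tunnel set into an n-length vector of multi-MUM ids (0 where no
#' tunnel column covers the position), writing tunnels in processing order so
#' overlapped positions in mode "all" keep the last writer.
#'
#' @param ts a [TunnelSet-class].
#' @return integer vector of length n.
#' @export
tunnelIdMap <- function(ts) {
  idvec <- integer(ts@n)
  for (t in seq_along(ts@mumId)) {
    starts <- ts@colStarts[[t]]
    if (!length(starts)) next
    pos <- as.integer(outer(starts, 0:(ts@d - 1L), "+"))
    idvec[pos] <- ts@mumId[t]
  }
  idvec
}

#' Exhaustively verify a tunnel set against full suffix structures
#'
#' Checks, with direct array lookups: pairwise disjointness of claimed
#' positions (as the cardinality identity sum(d * wPrime) == |claimed|, in
#' mode "tunnels"); that every column is a contiguous single-symbol block of
#' height d; that LF applied to each tunnel's first column start lands in its
#' source multi-MUM's SA window; and that the number of distinct column starts
#' is at most n/d.
#'
#' @param ts a [TunnelSet-class].
#' @param ss a [SuffixStructures-class].
#' @param mt a [MoveTables-class].
#' @param mums the source [MultiMUMSet-class].
#' @return list(ok, violations): `violations` is a character vector, empty on
#'   success.
#' @export
verifyTunnelSet <- function(ts, ss, mt, mums) {
  v <- character(0)
  d <- ts@d
  pos <- claimedPositions(ts)
  if (ts@mode == "tunnels") {
    if (length(pos) != length(unique(pos)))
      v <- c(v, "claimed positions are not pairwise disjoint")
    if (sum(ts@wPrime) * d != length(unique(pos)))
      v <- c(v, "cardinality identity sum(d*wPrime) == |claimed| fails")
  }
  starts <- unlist(ts@colStarts, use.names = FALSE)
  if (length(unique(starts)) > floor(ts@n / d))
    v <- c(v, "distinct column starts exceed n/d")
  for (t in seq_along(ts@mumId)) {
    st <- ts@colStarts[[t]]
    if (!length(st)) next
    for (q in st) {
      if (length(unique(ss@bwt[q:(q + d - 1L)])) != 1L) {
        v <- c(v, sprintf("tunnel %d: column at %d is not single-symbol",
                          ts@mumId[t], q))
        break
      }
    }
    s0 <- mums@s[match(ts@mumId[t], mums@ids)]
    back <- lfMap(mt, st[1L])
    if (back < s0 || back > s0 + d - 1L)
      v <- c(v, sprintf("tunnel %d: LF of first column start not in source SA window",
                        ts@mumId[t]))
  }
  list(ok = length(v) == 0L, violations = v)
}
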