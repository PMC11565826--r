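#' @rdname DocumentCollection-class
#' @param x a \code{DocumentCollection}.
#' @export
setGeneric("numDocs", function(x) standardGeneric("numDocs"))

#' @rdname DocumentCollection-class
#' @export
setGeneric("docNames", function(x) standardGeneric("docNames"))

#' @rdname DocumentCollection-class
#' @export
setGeneric("docSeqs", function(x) standardGeneric("docSeqs"))

setMethod("numDocs", "DocumentCollection", function(x) length(x@seqs))
setMethod("docNames", "DocumentCollection", function(x) x@names)
setMethod("docSeqs", "DocumentCollection", function(x) {
  stats::setNames(x@seqs, x@names)
})
setMethod("numDocs", "ConcatText", function(x) x@d)
setMethod("docNames", "ConcatText", function(x) x@docNames)
setMethod("numDocs", "ColBWT", function(x) x@d)
setMethod("docNames", "ColBWT", function(x) x@docNames)

#' @rdname MultiMUMSet-class
#' @param x a \code{MultiMUMSet}.
#' @export
setGeneric("numMUMs", function(x) standardGeneric("numMUMs"))
setMethod("numMUMs", "MultiMUMSet", function(x) x@u)

#' @rdname MultiMUMSet-class
#' @export
setGeneric("mumWidths", function(x) standardGeneric("mumWidths"))
setMethod("mumWidths", "MultiMUMSet", function(x) x@w)

#' @rdname MultiMUMSet-class
#' @export
setGeneric("mumStarts", function(x) standardGeneric("mumStarts"))
setMethod("mumStarts", "MultiMUMSet", function(x) x@s)

setMethod("show", "DocumentCollection", function(object) {
  cat(sprintf("DocumentCollection with %d document(s), total %d bp\n",
              length(object@seqs), sum(nchar(object@seqs))))
  k <- min(length(object@seqs), 5L)
  for (i in seq_len(k))
    cat(sprintf("  %s: %d bp\n", object@names[i], nchar(object@seqs[i])))
  if (length(object@seqs) > k) cat(sprintf("  ... and %d more\n",
                                           length(object@seqs) - k))
})

setMethod("show", "ConcatText", function(object) {
  cat(sprintf("ConcatText: n = %d (%d document(s), %d separator(s) + sentinel)\n",
              object@n, object@d, object@d - 1L))
})

setMethod("show", "SuffixStructures", function(object) {
  cat(sprintf("SuffixStructures over n = %d positions (%d document(s))\n",
              length(object@sa), object@text@d))
})

setMethod("show", "RLBWT", function(object) {
  cat(sprintf("RLBWT: n = %d, r = %d runs (mean run length %.2f)\n",
              object@n, object@r, object@n / object@r))
})

setMethod("show", "MultiMUMSet", function(object) {
  cat(sprintf("MultiMUMSet: u = %d multi-MUM(s) over d = %d documents\n",
              object@u, object@d))
  if (object@u > 0L)
    cat(sprintf("  widths: min %d, median %.0f, max %d\n",
                min(object@w), stats::median(object@w), max(object@w)))
})

setMethod("show", "TunnelSet", function(object) {
  claimed <- sum(object@wPrime) * object@d
  cat(sprintf("TunnelSet (mode=%s): %d tunnel(s), %d column(s), %d claimed position(s) of n = %d\n",
              object@mode, length(object@mumId), sum(object@wPrime),
              claimed, object@n))
})

setMethod("show", "ColBWT", function(object) {
  cat(sprintf("ColBWT index: n = %d, d = %d, r = %d, r' = %d sub-runs\n",
              object@n, object@d, object@r, object@rPrime))
  cat(sprintf("  mode=%s, sample rate s=%d, id bits=%d, min multi-MUM length=%d\n",
              object@params$mode, object@params$sampleRate,
              object@params$idBits, object@params$minMumLen))
  cat(sprintf("  %d multi-MUM(s); coverage: %.1f%% tunnel, %.1f%% marked\n",
              nrow(object@mumTable), 100 * object@coverage$tunnel,
              100 * object@coverage$marked))
  cat(sprintf("  oracle structures retained: %s\n",
              if (length(object@oracle)) "yes" else "no"))
})

setMethod("show", "NullModel", function(object) {
  cat(sprintf("NullModel: k = %d (min count %d), significant peak threshold = %d\n",
              object@k, object@minCount, object@peakThreshold))
  cat(sprintf("  expected co-linear pairs per base under null: %.3g\n",
              object@rhoNull))
})
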