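#' Create a document collection from character sequences
#'
#' @param seqs character vector of DNA sequences (one document each).
#' @param names optional document labels; defaults to doc1..docD.
#' @param ambiguous how to treat symbols outside \{A,C,G,T,N\}: "error"
#'   rejects them, "N" maps them (and lowercase input is always uppercased).
#' @return a [DocumentCollection-class].
#' @export
documentCollection <- function(seqs, names = NULL,
                               ambiguous = c("error", "N")) {
  ambiguous <- match.arg(ambiguous)
  seqs <- toupper(as.character(seqs))
  if (is.null(names)) names <- paste0("doc", seq_along(seqs))
  if (any(!nzchar(seqs))) inputError("empty sequence in collection")
  if (anyDuplicated(names)) inputError("duplicate document names")
  if (ambiguous == "N") {
    seqs <- gsub("[^ACGTN]", "N", seqs)
  } else if (any(grepl("[^ACGTN]", seqs))) {
    inputError("sequence contains symbols outside {A,C,G,T,N}")
  }
  new("DocumentCollection", seqs = seqs, names = as.character(names))
}

#' Read a multi-FASTA file into a document collection
#'
#' One FASTA record becomes one document, in file order; sequences are
#' uppercased. Gzip-compressed input is handled transparently.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @inheritParams documentCollection
#' @return a [DocumentCollection-class].
#' @export
readFasta <- function(path, ambiguous = c("error", "N")) {
  if (!file.exists(path)) inputError("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) inputError("not FASTA-formatted: %s", path))
  if (length(set) == 0L) inputError("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(set))
  documentCollection(as.character(set), nm, ambiguous = ambiguous)
}

#' Write a collection to a FASTA file
#'
#' @param coll a [DocumentCollection-class].
#' @param path output path.
#' @param width line width.
#' @export
writeFasta <- function(coll, path, width = 70L) {
  set <- Biostrings::DNAStringSet(coll@seqs)
  names(set) <- coll@names
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Append each document's reverse complement to itself
#'
#' Each document becomes forward strand followed directly by its reverse
#' complement, forming a single document, so that both strands of a genome are
#' indexed under one document identity. By default no separator is inserted at
#' the strand junction; set \code{junction = "N"} to insert an N there.
#'
#' @param coll a [DocumentCollection-class].
#' @param junction "none" (direct join) or "N".
#' @return a [DocumentCollection-class] with doubled documents.
#' @export
augmentRevcomp <- function(coll, junction = c("none", "N")) {
  junction <- match.arg(junction)
  sep <- if (junction == "N") "N" else ""
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(coll@seqs)))
  new("DocumentCollection",
      seqs = paste0(coll@seqs, sep, rc), names = coll@names)
}

#' Concatenate a collection with per-document separators and a sentinel
#'
#' Documents are joined in order; document i < d is terminated by its own
#' separator symbol (rank increasing with i, all below the DNA alphabet) and
#' the final document by the single sentinel, the least symbol. The result has
#' length sum(|Ti|) + d.
#'
#' @param coll a [DocumentCollection-class].
#' @return a [ConcatText-class].
#' @export
concatText <- function(coll) {
  d <- length(coll@seqs)
  stopifnot(d >= 1L)
  lens <- nchar(coll@seqs)
  docStart <- cumsum(c(1L, lens[-d] + 1L))
  n <- sum(lens) + d
  codes <- integer(n)
  for (i in seq_len(d)) {
    b <- baseCode(splitChars(coll@seqs[i]))
    codes[docStart[i]:(docStart[i] + lens[i] - 1L)] <- d + b
    term <- docStart[i] + lens[i]
    codes[term] <- if (i < d) i + 1L else 1L
  }
  new("ConcatText", codes = codes, n = as.integer(n), d = as.integer(d),
      docStart = as.integer(docStart), docLen = as.integer(lens),
      docNames = coll@names)
}

#' Document index of a text position
#'
#' A document's separator (and the sentinel, for the last document) is
#' attributed to the document it terminates, making the map total.
#'
#' @param ct a [ConcatText-class].
#' @param pos 1-based text positions.
#' @return integer document indices.
#' @export
docOf <- function(ct, pos) {
  stopifnot(all(pos >= 1L & pos <= ct@n))
  findInterval(pos, ct@docStart)
}

#' Recover the original documents from a concatenation
#'
#' Strips separators and the sentinel; used by the round-trip invariant.
#' @param ct a [ConcatText-class].
#' @return character vector of document sequences.
#' @export
splitConcat <- function(ct) {
  vapply(seq_len(ct@d), function(i) {
    span <- ct@docStart[i]:(ct@docStart[i] + ct@docLen[i] - 1L)
    paste(DNA_BASES[ct@codes[span] - ct@d], collapse = "")
  }, character(1))
}

# Decode integer codes back to display characters (separators as digits-ish)
decodeCodes <- function(codes, d) {
  out <- character(length(codes))
  dna <- codes > d
  out[dna] <- DNA_BASES[codes[dna] - d]
  out[codes == 1L] <- "$"
  sep <- codes > 1L & codes <= d
  out[sep] <- "#"
  out
}
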