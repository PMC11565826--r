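DNA_BASES <- c("A", "C", "G", "T", "N")

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Map base letters to 1..5 (A,C,G,T,N); anything else -> NA
baseCode <- function(chars) match(chars, DNA_BASES)

splitChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' N is its own complement. Thin wrapper kept separate from the test oracle.
#' @param s a single DNA string over \{A,C,G,T,N\}.
#' @return the reverse complement string.
#' @export
revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Binned identifier stored in sub-runs: keeps 0 reserved for "unmarked" while
# folding ids into 2^bits - 1 classes. Equal stored ids are necessary but not
# sufficient for equal multi-MUM ids.
binId <- function(id, bits) {
  stopifnot(bits %in% c(8L, 16L, 32L))
  m <- 2^bits - 1
  as.integer(1 + ((as.numeric(id) - 1) %% m))
}

# Rolling minimum of x over windows of length k (result length n-k+1)
rollMin <- function(x, k) {
  n <- length(x)
  if (k == 1L) return(x)
  out <- x[seq_len(n - k + 1L)]
  for (j in seq_len(k - 1L)) out <- pmin(out, x[(1L + j):(n - k + 1L + j)])
  out
}

rollMax <- function(x, k) {
  n <- length(x)
  if (k == 1L) return(x)
  out <- x[seq_len(n - k + 1L)]
  for (j in seq_len(k - 1L)) out <- pmax(out, x[(1L + j):(n - k + 1L + j)])
  out
}

inputError <- function(fmt, ...) {
  stop(structure(class = c("colbwt_input_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
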