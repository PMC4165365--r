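# Internal low-level helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Vectorized over `x`; `N` is preserved.  Everything in the package scans in
#' DNA space, so miRNA input (RNA alphabet) is converted with [rna_to_dna()]
#' before reaching here.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp_dna(c("ACGT", "GGTAA"))
revcomp_dna <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' U/T normalization at the RNA input boundary
#' @param x character vector of RNA sequences.
#' @return DNA-alphabet uppercase sequences.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# Length of the longest common prefix of two strings (byte-wise).
common_prefix_len <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

# Random DNA string(s) of the given lengths.
random_dna <- function(len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# 0-based half-open substring of a chromosome string.
substr0 <- function(seq, start, end) substr(seq, start + 1L, end)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
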