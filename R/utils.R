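#' @importFrom stats rbinom runif rnorm setNames median quantile dnorm pnorm
#' @importFrom utils read.table write.table head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# SAM/GFF/VCF 1-based conversions happen only at the io boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random DNA string
#'
#' Uniform i.i.d. bases; uses the current RNG state (callers seed).
#'
#' @param n Length in bp.
#' @return A single uppercase character string.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  rawToChar(charToRaw(paste(DNA_BASES, collapse = ""))[sample.int(4L, n, replace = TRUE)])
}

#' Reverse complement of a DNA string
#' @param x Character string over A/C/G/T/N.
#' @return Reverse-complemented string.
#' @keywords internal
revcomp <- function(x) {
  r <- rev(charToRaw(x))
  rawToChar(charToRaw(chartr("ACGTN", "TGCAN", rawToChar(r))))
}

# substring of a chromosome in internal [start, end) coordinates
seq_slice <- function(seqs, chrom, start, end) {
  substr(seqs[[chrom]], start + 1L, end)
}

# mutate a base to a different one, uniformly
other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
}

#' Left-align an insertion against the reference
#'
#' Shifts an insertion breakpoint leftwards while the last inserted base
#' equals the reference base immediately left of the breakpoint, rotating
#' the inserted sequence. This canonical placement makes support
#' aggregation stable in homopolymers and tandem contexts.
#'
#' @param refseq Reference chromosome sequence (character).
#' @param pos 0-based insertion breakpoint (number of reference bases
#'   before the insertion point).
#' @param seq Inserted sequence.
#' @return list(pos=, seq=) with the left-aligned placement.
#' @export
left_align_insertion <- function(refseq, pos, seq) {
  s <- charToRaw(seq)
  n <- length(s)
  if (n == 0L) return(list(pos = pos, seq = seq))
  ref <- charToRaw(refseq)
  while (pos > 0L && ref[pos] == s[n]) {
    s <- c(s[n], s[-n])
    pos <- pos - 1L
  }
  list(pos = pos, seq = rawToChar(s))
}

#' Left-align a deletion against the reference
#'
#' @param refseq Reference chromosome sequence.
#' @param start 0-based start of the deleted reference interval.
#' @param len Deletion length in bp.
#' @return list(start=, seq=) left-aligned deleted interval and its sequence.
#' @export
left_align_deletion <- function(refseq, start, len) {
  ref <- charToRaw(refseq)
  # deleted interval [start, start+len); shift left while base entering on the
  # right equals base leaving on the left
  while (start > 0L && ref[start] == ref[start + len]) {
    start <- start - 1L
  }
  list(start = start, seq = rawToChar(ref[(start + 1L):(start + len)]))
}

# IRanges from internal 0-based half-open intervals (may be empty)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# total bases of the union of internal intervals clipped to [0, len)
union_bases <- function(start, end, len = NULL) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::reduce(as_iranges0(start, end))
  if (!is.null(len)) {
    ir <- IRanges::restrict(ir, start = 1L, end = as.integer(len))
  }
  sum(IRanges::width(ir))
}

# hamming identity between two equal-length raw vectors
raw_identity <- function(a, b) {
  if (length(a) != length(b)) stop("raw_identity: length mismatch")
  if (length(a) == 0L) return(1)
  mean(a == b)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
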