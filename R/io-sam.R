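# Plain-text SAM reader/writer. BAM/CRAM are out of scope at desk scale;
# convert with samtools upstream if needed.

FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

#' Read a SAM file into a record table
#'
#' SAM POS (1-based) is converted to the internal 0-based \code{ref_start}.
#' Unmapped records are skipped and counted; records whose read-consuming
#' CIGAR length disagrees with the stored sequence are rejected and counted.
#'
#' @param path Path to a SAM text file.
#' @param keep_secondary Keep secondary alignments (default FALSE).
#' @param keep_supplementary Keep supplementary alignments (default TRUE;
#'   depth and variant stages filter on \code{is_primary} themselves).
#' @return data.frame with columns read_id, flag, chrom, ref_start, mapq,
#'   cigar, seq, md, strand, is_primary, is_supplementary. Attributes
#'   \code{header} (character vector of header lines), \code{n_unmapped},
#'   \code{n_rejected}.
#' @export
read_sam <- function(path, keep_secondary = FALSE, keep_supplementary = TRUE) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  n_unmapped <- 0L
  n_rejected <- 0L
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) { n_rejected <- n_rejected + 1L; next }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, FLAG_UNMAPPED) != 0L || f[3] == "*") {
      n_unmapped <- n_unmapped + 1L
      next
    }
    md <- NA_character_
    if (length(f) > 11L) {
      tags <- f[-(1:11)]
      mdtag <- tags[startsWith(tags, "MD:Z:")]
      if (length(mdtag)) md <- substring(mdtag[1L], 6L)
    }
    seq <- toupper(f[10])
    cig <- f[6]
    if (seq != "*") {
      rl <- cigar_read_length(parse_cigar(cig))
      if (rl != nchar(seq)) {
        warning(sprintf("SAM record %s: CIGAR read length %d != SEQ length %d; skipped",
                        f[1], rl, nchar(seq)), call. = FALSE)
        n_rejected <- n_rejected + 1L
        next
      }
    }
    recs[[i]] <- list(read_id = f[1], flag = flag, chrom = f[3],
                      ref_start = as.integer(f[4]) - 1L, mapq = as.integer(f[5]),
                      cigar = cig, seq = seq, md = md)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) {
    data.frame(read_id = vapply(recs, `[[`, character(1), "read_id"),
               flag = vapply(recs, `[[`, integer(1), "flag"),
               chrom = vapply(recs, `[[`, character(1), "chrom"),
               ref_start = vapply(recs, `[[`, integer(1), "ref_start"),
               mapq = vapply(recs, `[[`, integer(1), "mapq"),
               cigar = vapply(recs, `[[`, character(1), "cigar"),
               seq = vapply(recs, `[[`, character(1), "seq"),
               md = vapply(recs, `[[`, character(1), "md"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = character(0), flag = integer(0), chrom = character(0),
               ref_start = integer(0), mapq = integer(0), cigar = character(0),
               seq = character(0), md = character(0))
  }
  out$strand <- ifelse(bitwAnd(out$flag, FLAG_REVERSE) != 0L, "-", "+")
  out$is_supplementary <- bitwAnd(out$flag, FLAG_SUPPLEMENTARY) != 0L
  is_secondary <- bitwAnd(out$flag, FLAG_SECONDARY) != 0L
  out$is_primary <- !is_secondary & !out$is_supplementary
  if (!keep_secondary) out <- out[!is_secondary, , drop = FALSE]
  if (!keep_supplementary) out <- out[!out$is_supplementary, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "header") <- hdr
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a record table as SAM
#'
#' @param records Record data.frame (see \code{\link{read_sam}}).
#' @param path Output path.
#' @param refseqs Named character vector of reference sequences used for the
#'   \code{@SQ} header lines; ignored if \code{header} is given.
#' @param header Optional character vector of full header lines.
#' @export
write_sam <- function(records, path, refseqs = NULL, header = NULL) {
  if (is.null(header)) {
    if (is.null(refseqs)) stopf("write_sam: need refseqs or header")
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(refseqs), nchar(refseqs)))
  }
  md <- records$md
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                   records$read_id, records$flag, records$chrom,
                   records$ref_start + 1L, records$mapq, records$cigar,
                   records$seq,
                   ifelse(is.na(md), "", paste0("\tMD:Z:", md)))
  writeLines(c(header, lines), path)
  invisible(path)
}
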