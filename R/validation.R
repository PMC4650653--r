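# Independent confirmation of recovered insertions with short-read and
# RNA-seq alignments: 2.5 kb flanked validation contigs, 10x junction
# coverage rule, 2x coverage-defined exonic runs.

#' Build validation reference contigs around insertion calls
#'
#' One contig per call: left reference flank + inserted sequence + right
#' reference flank. Gapped (close-breakpoint) calls yield two junction
#' contigs, one per side. Flanks truncated at chromosome ends are flagged.
#'
#' @param calls Merged insertion call data.frame.
#' @param refseqs Named character vector of reference sequences.
#' @param flank Flank size (bp) on each side.
#' @return list(seqs = named character vector of contigs, info = data.frame
#'   contig, call_index, junction_left, junction_right (0-based contig
#'   coordinates of the two reference/insert junctions), ins_len,
#'   truncated, gapped).
#' @export
build_validation_reference <- function(calls, refseqs, flank = 2500L) {
  seqs <- character(0)
  info <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    ref <- refseqs[[cl$chrom]]
    n <- nchar(ref)
    lf0 <- max(0L, cl$breakpoint - flank)
    rf1 <- min(n, cl$breakpoint + flank)
    lflank <- substr(ref, lf0 + 1L, cl$breakpoint)
    rflank <- substr(ref, cl$breakpoint + 1L, rf1)
    truncated <- nchar(lflank) < flank || nchar(rflank) < flank
    frags <- strsplit(cl$seq, "-", fixed = TRUE)[[1]]
    gapped <- length(frags) > 1L
    if (!gapped) {
      id <- sprintf("insctg%03d", i)
      seqs[[id]] <- paste0(lflank, cl$seq, rflank)
      info[[length(info) + 1L]] <- data.frame(
        contig = id, call_index = i, junction_left = nchar(lflank),
        junction_right = nchar(lflank) + nchar(cl$seq), ins_len = nchar(cl$seq),
        truncated = truncated, gapped = FALSE, stringsAsFactors = FALSE)
    } else {
      idL <- sprintf("insctg%03dL", i); idR <- sprintf("insctg%03dR", i)
      seqs[[idL]] <- paste0(lflank, frags[1])
      seqs[[idR]] <- paste0(frags[2], rflank)
      info[[length(info) + 1L]] <- data.frame(
        contig = idL, call_index = i, junction_left = nchar(lflank),
        junction_right = NA_integer_, ins_len = nchar(frags[1]),
        truncated = truncated, gapped = TRUE, stringsAsFactors = FALSE)
      info[[length(info) + 1L]] <- data.frame(
        contig = idR, call_index = i, junction_left = NA_integer_,
        junction_right = nchar(frags[2]), ins_len = nchar(frags[2]),
        truncated = truncated, gapped = TRUE, stringsAsFactors = FALSE)
    }
  }
  list(seqs = seqs,
       info = if (length(info)) do.call(rbind, info) else
         data.frame(contig = character(0), call_index = integer(0),
                    junction_left = integer(0), junction_right = integer(0),
                    ins_len = integer(0), truncated = logical(0), gapped = logical(0)))
}

#' Confirm insertions with genomic short-read coverage
#'
#' An insertion is confirmed when every base of both junction windows
#' (one read length on each side of each reference/insert junction) and of
#' the insertion body reaches \code{min_depth}; partially confirmed when
#' exactly one junction passes; unconfirmed otherwise.
#'
#' @param vref Output of \code{\link{build_validation_reference}}.
#' @param records Short-read SAM records aligned to the validation contigs.
#' @param min_depth Required per-base depth (default 10).
#' @param read_len Junction window half-width; defaults to the modal
#'   aligned read length in \code{records}.
#' @return data.frame call_index, status (confirmed | partially_confirmed |
#'   unconfirmed).
#' @export
confirm_genomic <- function(vref, records, min_depth = 10L, read_len = NULL) {
  if (nrow(records)) {
    missing_ctg <- setdiff(unique(records$chrom), names(vref$seqs))
    if (length(missing_ctg)) stopf("contig %s absent from validation reference",
                                   missing_ctg[1])
  }
  if (is.null(read_len)) {
    read_len <- if (nrow(records)) as.integer(median(nchar(records$seq))) else 100L
  }
  track <- depth_track(records, vref$seqs)
  info <- vref$info
  out <- list()
  for (ci in unique(info$call_index)) {
    rows <- info[info$call_index == ci, , drop = FALSE]
    passes <- logical(0)
    body_ok <- TRUE
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      v <- track$per_chrom[[r$contig]]
      n <- length(v)
      win_ok <- function(j) {
        if (is.na(j)) return(NA)
        lo <- max(1L, j - read_len + 1L); hi <- min(n, j + read_len)
        all(v[lo:hi] >= min_depth)
      }
      passes <- c(passes, win_ok(r$junction_left), win_ok(r$junction_right))
      body0 <- if (is.na(r$junction_left)) 0L else r$junction_left
      body1 <- if (is.na(r$junction_right)) n else r$junction_right
      if (body1 > body0) body_ok <- body_ok && all(v[(body0 + 1L):body1] >= min_depth)
    }
    passes <- passes[!is.na(passes)]
    status <- if (length(passes) && all(passes) && body_ok) "confirmed"
      else if (any(passes)) "partially_confirmed" else "unconfirmed"
    out[[length(out) + 1L]] <- data.frame(call_index = ci, status = status,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Exonic support of coding-region insertions from RNA-seq coverage
#'
#' Within the inserted segment of each validation contig, maximal runs
#' with depth >= \code{exon_depth} are coverage-defined exonic regions.
#' full = these runs cover the entire insertion; partial = some but not
#' all; none = no exonic base.
#'
#' @param vref Output of \code{\link{build_validation_reference}}.
#' @param records Spliced RNA-seq SAM records aligned to the contigs.
#' @param exon_depth Exonic coverage threshold (default 2).
#' @return data.frame call_index, exon_support (full | partial | none),
#'   exonic_bases.
#' @export
exon_support <- function(vref, records, exon_depth = 2L) {
  track <- depth_track(records, vref$seqs)
  info <- vref$info[!vref$info$gapped, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(info))) {
    r <- info[k, ]
    v <- track$per_chrom[[r$contig]]
    body <- v[(r$junction_left + 1L):r$junction_right]
    exonic <- sum(body >= exon_depth)
    status <- if (exonic == length(body)) "full" else if (exonic > 0L) "partial" else "none"
    out[[length(out) + 1L]] <- data.frame(call_index = r$call_index,
                                          exon_support = status,
                                          exonic_bases = exonic,
                                          stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(call_index = integer(0), exon_support = character(0),
               exonic_bases = integer(0))
}

#' Simulate short paired-end-style reads from a set of sequences
#'
#' Uniform error-free coverage emitter used to exercise the validation
#' rules; emits alignment records directly against the source sequences.
#'
#' @param seqs Named character vector of source sequences (e.g. validation
#'   contigs, or donor chromosomes).
#' @param depth Target mean depth.
#' @param read_len Read length (bp).
#' @param seed RNG seed.
#' @return SAM record data.frame.
#' @export
simulate_short_reads <- function(seqs, depth, read_len = 100L, seed = 1L) {
  set.seed(seed)
  out <- list()
  cnt <- 0L
  for (ch in names(seqs)) {
    n <- nchar(seqs[[ch]])
    rl <- min(read_len, n)
    n_reads <- max(1L, round(depth * n / rl))
    starts <- sample.int(n - rl + 1L + (rl - 1L), n_reads, replace = TRUE) - 1L - (rl - 1L)
    s0 <- pmax(0L, starts)
    s1 <- pmin(starts + rl, n)
    keep <- s1 - s0 >= min(30L, rl)
    s0 <- s0[keep]; s1 <- s1[keep]
    if (!length(s0)) next
    out[[length(out) + 1L]] <- data.frame(
      read_id = sprintf("sr%s_%06d", ch, cnt + seq_along(s0)),
      flag = 0L, chrom = ch, ref_start = s0, mapq = 60L,
      cigar = sprintf("%dM", s1 - s0),
      seq = substring(seqs[[ch]], s0 + 1L, s1),
      md = sprintf("%d", s1 - s0), stringsAsFactors = FALSE)
    cnt <- cnt + length(s0)
  }
  res <- do.call(rbind, out)
  res$strand <- "+"
  res$is_supplementary <- FALSE
  res$is_primary <- TRUE
  rownames(res) <- NULL
  res
}
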