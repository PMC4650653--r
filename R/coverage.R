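# Depth tracks, zero-coverage gaps, read-length statistics and
# accumulative shorter/longer-than-L coverage curves.

#' Per-base depth track from alignment records
#'
#' Depth counts reference bases consumed by M/=/X ops only; deletions span
#' but do not add depth. Primary alignments only by default.
#'
#' @param records SAM record data.frame.
#' @param refseqs Named character vector of reference sequences.
#' @param include_supplementary Also count supplementary alignments
#'   (needed when split reads carry real coverage, e.g. over a collapsed
#'   repeat).
#' @return list(per_chrom = named list of integer depth vectors,
#'   mean = genome mean depth), class \code{depth_track}.
#' @export
depth_track <- function(records, refseqs, include_supplementary = FALSE) {
  keep <- records$is_primary
  if (include_supplementary) keep <- keep | records$is_supplementary
  records <- records[keep, , drop = FALSE]
  per <- lapply(setNames(names(refseqs), names(refseqs)), function(ch) {
    n <- nchar(refseqs[[ch]])
    rc <- records[records$chrom == ch, , drop = FALSE]
    diffv <- integer(n + 1L)
    for (i in seq_len(nrow(rc))) {
      ops <- parse_cigar(rc$cigar[i])
      p <- rc$ref_start[i]
      for (j in seq_len(nrow(ops))) {
        op <- ops$op[j]; len <- ops$len[j]
        if (op %in% c("M", "=", "X")) {
          diffv[p + 1L] <- diffv[p + 1L] + 1L
          diffv[p + len + 1L] <- diffv[p + len + 1L] - 1L
          p <- p + len
        } else if (op %in% c("D", "N")) {
          p <- p + len
        }
      }
    }
    cumsum(diffv[seq_len(n)])
  })
  total <- sum(vapply(per, sum, numeric(1)))
  glen <- sum(nchar(refseqs))
  structure(list(per_chrom = per, mean = total / glen), class = "depth_track")
}

#' Extract zero-coverage gaps from a depth track
#'
#' @param track A \code{\link{depth_track}}.
#' @param min_len Minimum gap length to report.
#' @return data.frame chrom, start, end, length (0-based half-open),
#'   sorted by decreasing length.
#' @export
extract_gaps <- function(track, min_len = 1L) {
  out <- list()
  for (ch in names(track$per_chrom)) {
    v <- track$per_chrom[[ch]]
    r <- rle(v == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    zi <- which(r$values)
    if (length(zi)) {
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = starts[zi],
                                            end = ends[zi], stringsAsFactors = FALSE)
    }
  }
  g <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  g$length <- g$end - g$start
  g <- g[g$length >= min_len, , drop = FALSE]
  g <- g[order(-g$length), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Read-length statistics: median, N50 and 100 bp strata
#'
#' N50 is the length of the smallest read in the minimal set of longest
#' reads whose summed length reaches half the total yield. Strata run from
#' the minimum length in 100 bp increments, with lengths above
#' \code{open_from} merged into a final open stratum (139 closed bins plus
#' one open bin at the defaults).
#'
#' @param lengths Integer vector of read lengths (all >= \code{min_len}).
#' @param min_len Lower bound of the first stratum.
#' @param open_from Lengths >= this fall into the open final stratum.
#' @return list(median, n50, strata = data.frame(low, high, count, yield)).
#' @export
length_stats <- function(lengths, min_len = 1500L, open_from = 15400L) {
  if (length(lengths) == 0L) stopf("empty read set")
  s <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(as.numeric(s))
  n50 <- s[which(csum >= sum(as.numeric(s)) / 2)[1L]]
  lo <- if (open_from - 100L >= min_len) {
    seq(min_len, open_from - 100L, by = 100L)
  } else min_len
  bins <- findInterval(lengths, c(lo, open_from))
  bins[lengths >= open_from] <- length(lo) + 1L
  cnt <- tabulate(bins, nbins = length(lo) + 1L)
  yld <- vapply(seq_len(length(lo) + 1L), function(b)
    sum(as.numeric(lengths[bins == b])), numeric(1))
  strata <- data.frame(low = c(lo, open_from),
                       high = c(lo + 100L, Inf),
                       count = cnt, yield = yld)
  list(median = median(lengths), n50 = n50, strata = strata)
}

# reference intervals covered by each record's M ops (primary only)
aligned_intervals <- function(records) {
  prim <- records[records$is_primary, , drop = FALSE]
  out <- vector("list", nrow(prim))
  for (i in seq_len(nrow(prim))) {
    ops <- parse_cigar(prim$cigar[i])
    p <- prim$ref_start[i]
    iv <- list()
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        iv[[length(iv) + 1L]] <- c(p, p + len)
        p <- p + len
      } else if (op %in% c("D", "N")) p <- p + len
    }
    m <- do.call(rbind, iv)
    out[[i]] <- data.frame(chrom = prim$chrom[i], start = m[, 1], end = m[, 2],
                           read_id = prim$read_id[i], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               read_id = character(0))
  rownames(res) <- NULL
  res
}

# covered bases of a target interval set by a set of aligned intervals
covered_target_bases <- function(iv, targets) {
  total <- 0
  for (ch in unique(targets$chrom)) {
    t_ir <- IRanges::reduce(as_iranges0(targets$start[targets$chrom == ch],
                                        targets$end[targets$chrom == ch]))
    a <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0L) next
    a_ir <- IRanges::reduce(as_iranges0(a$start, a$end))
    total <- total + sum(IRanges::width(IRanges::intersect(t_ir, a_ir)))
  }
  total
}

#' Accumulative shorter/longer-than-L coverage curves
#'
#' For every 100 bp grid value L, computes the fraction of the target space
#' covered using only reads shorter than L and only reads of length >= L.
#'
#' @param records SAM record data.frame.
#' @param read_lengths Named integer vector (read_id -> full read length).
#' @param targets data.frame(chrom, start, end): genome, gene space or
#'   repeat space (interval union taken internally).
#' @param grid Candidate split lengths (default 1500-15500 by 100).
#' @return data.frame L, frac_shorter, frac_longer.
#' @export
accumulative_coverage <- function(records, read_lengths, targets,
                                  grid = seq(1500L, 15500L, by = 100L)) {
  target_total <- sum(vapply(unique(targets$chrom), function(ch)
    sum(IRanges::width(IRanges::reduce(as_iranges0(
      targets$start[targets$chrom == ch], targets$end[targets$chrom == ch])))),
    numeric(1)))
  if (target_total == 0) stopf("empty target space")
  iv <- aligned_intervals(records)
  iv$len <- unname(read_lengths[iv$read_id])
  out <- data.frame(L = grid, frac_shorter = NA_real_, frac_longer = NA_real_)
  for (k in seq_along(grid)) {
    L <- grid[k]
    out$frac_shorter[k] <- covered_target_bases(iv[iv$len < L, , drop = FALSE],
                                                targets) / target_total
    out$frac_longer[k] <- covered_target_bases(iv[iv$len >= L, , drop = FALSE],
                                               targets) / target_total
  }
  out
}

#' Intersection point of the shorter/longer coverage curves
#'
#' @param curves Output of \code{\link{accumulative_coverage}}.
#' @return list(L, frac_shorter, frac_longer, crossed): the smallest grid L
#'   minimizing |frac_shorter - frac_longer|; \code{crossed} is FALSE when
#'   the curves never change sign over the grid.
#' @export
intersection_point <- function(curves) {
  d <- curves$frac_shorter - curves$frac_longer
  i <- which(abs(d) <= min(abs(d)) + 1e-12)[1L]  # ties resolve to the smaller L
  list(L = curves$L[i], frac_shorter = curves$frac_shorter[i],
       frac_longer = curves$frac_longer[i],
       crossed = any(d <= 0) && any(d >= 0))
}

#' Coverage profile along chromosomes by read-length stratum
#'
#' @param records SAM record data.frame.
#' @param read_lengths Named integer vector of full read lengths.
#' @param refseqs Named character vector of reference sequences.
#' @param breaks Length-stratum breaks (right-open; last stratum open).
#' @param n_bins Position bins per chromosome.
#' @return data.frame chrom, bin (1-based), stratum label, covered_frac.
#' @export
per_chromosome_profile <- function(records, read_lengths, refseqs,
                                   breaks = c(1500L, 3000L, 6000L, 10000L),
                                   n_bins = 100L) {
  iv <- aligned_intervals(records)
  iv$len <- unname(read_lengths[iv$read_id])
  iv$stratum <- findInterval(iv$len, breaks)
  labels <- paste0("[", breaks, ",", c(breaks[-1L], Inf), ")")
  out <- list()
  for (ch in names(refseqs)) {
    n <- nchar(refseqs[[ch]])
    edges <- floor(seq(0, n, length.out = n_bins + 1L))
    for (s in seq_along(breaks)) {
      a <- iv[iv$chrom == ch & iv$stratum == s, , drop = FALSE]
      ir <- IRanges::reduce(as_iranges0(a$start, a$end))
      for (b in seq_len(n_bins)) {
        bin_ir <- as_iranges0(edges[b], edges[b + 1L])
        cov <- if (length(ir)) sum(IRanges::width(IRanges::intersect(ir, bin_ir))) else 0L
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, bin = b, stratum = labels[s],
          covered_frac = cov / max(1L, edges[b + 1L] - edges[b]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
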