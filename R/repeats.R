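# Repeat recovery under coverage subsampling, gap enrichment/composition,
# tandem-cluster detection with the preassembly blocker rule, and
# collapsed-repeat copy-number estimation.

#' Repeat and gene recovery rates under nested coverage subsampling
#'
#' Reads are permuted once (seeded) and nested prefixes are taken to reach
#' each target mean depth, so the 3x read set is a subset of the 6x set and
#' so on. An instance is recovered when its full annotated span has depth
#' >= 1 under the subsample.
#'
#' @param records SAM record data.frame.
#' @param refseqs Named character vector of reference sequences.
#' @param repeats Repeat interval data.frame (chrom, start, end,
#'   repeat_class).
#' @param genes List of gene models (recovery over the gene span).
#' @param coverage_levels Target mean depths, ascending.
#' @param seed Subsampling seed.
#' @return list(repeats = data.frame(repeat_class, coverage, n, recovered,
#'   rate), genes = data.frame(gene_id, coverage, recovered)).
#' @export
recovery_rates <- function(records, refseqs, repeats, genes,
                           coverage_levels = c(3, 6, 12, 24), seed = 1L) {
  prim <- records[records$is_primary, , drop = FALSE]
  iv <- aligned_intervals(prim)
  per_read <- split(iv, iv$read_id)
  ids <- names(per_read)
  read_ref_bases <- vapply(per_read, function(d) sum(d$end - d$start), numeric(1))
  glen <- sum(nchar(refseqs))
  avail <- sum(read_ref_bases) / glen
  # the top level names the full read set: a nominal 24x run aligns slightly
  # less than 24x once preassembly-blocked reads are withheld, so levels
  # within 5% of the available depth take every read
  if (max(coverage_levels) > avail * 1.05) {
    stopf("requested coverage %.1fx exceeds available %.2fx", max(coverage_levels), avail)
  }
  set.seed(seed)
  ord <- sample(ids)
  cum <- cumsum(read_ref_bases[ord]) / glen
  rep_out <- list()
  gene_out <- list()
  for (cv in sort(coverage_levels)) {
    n_take <- if (cv >= avail) length(ord) else which(cum >= cv)[1L]
    if (is.na(n_take)) n_take <- length(ord)
    sel <- iv[iv$read_id %in% ord[seq_len(n_take)], , drop = FALSE]
    cov_ir <- lapply(setNames(names(refseqs), names(refseqs)), function(ch) {
      a <- sel[sel$chrom == ch, , drop = FALSE]
      IRanges::reduce(as_iranges0(a$start, a$end))
    })
    fully <- function(ch, s, e) {
      ir <- cov_ir[[ch]]
      if (length(ir) == 0L) return(FALSE)
      q <- as_iranges0(s, e)
      any(IRanges::start(ir) <= IRanges::start(q) & IRanges::end(ir) >= IRanges::end(q))
    }
    rec <- vapply(seq_len(nrow(repeats)), function(i)
      fully(repeats$chrom[i], repeats$start[i], repeats$end[i]), logical(1))
    agg <- stats::aggregate(rec, by = list(repeat_class = repeats$repeat_class),
                            FUN = function(x) c(n = length(x), rec = sum(x)))
    rep_out[[length(rep_out) + 1L]] <- data.frame(
      repeat_class = agg$repeat_class, coverage = cv,
      n = agg$x[, "n"], recovered = agg$x[, "rec"],
      rate = agg$x[, "rec"] / agg$x[, "n"], stringsAsFactors = FALSE)
    if (length(genes)) {
      gene_out[[length(gene_out) + 1L]] <- data.frame(
        gene_id = vapply(genes, `[[`, character(1), "gene_id"), coverage = cv,
        recovered = vapply(genes, function(g) fully(g$chrom, g$start, g$end),
                           logical(1)), stringsAsFactors = FALSE)
    }
  }
  list(repeats = do.call(rbind, rep_out),
       genes = if (length(gene_out)) do.call(rbind, gene_out) else NULL)
}

#' Repeat-class enrichment and composition within coverage gaps
#'
#' fold(class) = (class bases in gaps / gap bases) /
#' (class bases in genome / genome length); composition(class) = class
#' bases in gaps / gap bases. Overlapping annotations of different classes
#' are each counted in full.
#'
#' @param gaps Gap data.frame from \code{\link{extract_gaps}}.
#' @param repeats Repeat interval data.frame.
#' @param refseqs Named character vector of reference sequences.
#' @return data.frame repeat_class, genome_bases, gap_bases, composition,
#'   fold; empty when there are no gap bases.
#' @export
gap_enrichment <- function(gaps, repeats, refseqs) {
  glen <- sum(nchar(refseqs))
  gap_total <- sum(gaps$end - gaps$start)
  classes <- sort(unique(repeats$repeat_class))
  if (gap_total == 0) {
    return(data.frame(repeat_class = character(0), genome_bases = numeric(0),
                      gap_bases = numeric(0), composition = numeric(0),
                      fold = numeric(0)))
  }
  out <- lapply(classes, function(cl) {
    r <- repeats[repeats$repeat_class == cl, , drop = FALSE]
    genome_bases <- 0; gap_bases <- 0
    for (ch in unique(r$chrom)) {
      r_ir <- IRanges::reduce(as_iranges0(r$start[r$chrom == ch], r$end[r$chrom == ch]))
      genome_bases <- genome_bases + sum(IRanges::width(r_ir))
      g <- gaps[gaps$chrom == ch, , drop = FALSE]
      if (nrow(g)) {
        g_ir <- IRanges::reduce(as_iranges0(g$start, g$end))
        gap_bases <- gap_bases + sum(IRanges::width(IRanges::intersect(r_ir, g_ir)))
      }
    }
    comp <- gap_bases / gap_total
    data.frame(repeat_class = cl, genome_bases = genome_bases, gap_bases = gap_bases,
               composition = comp,
               fold = if (genome_bases > 0) comp / (genome_bases / glen) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(-res$fold), ]
}

#' Detect tandem clusters of a short repeated unit
#'
#' Scans each chromosome for maximal runs with period 1-max_unit
#' (vectorized shifted-string comparison), keeps runs of at least
#' \code{min_cluster_len} spanning at least two unit copies, and reports
#' the minimal period. Runs of different periods overlapping the same locus
#' collapse to the smallest-period cluster.
#'
#' @param refseqs Named character vector of sequences.
#' @param min_cluster_len Minimum cluster length (bp).
#' @param max_unit Maximum unit length scanned.
#' @return data.frame chrom, start, end, unit, unit_len, copies, length.
#' @export
find_tandem_clusters <- function(refseqs, min_cluster_len = 100L, max_unit = 20L) {
  out <- list()
  for (ch in names(refseqs)) {
    s <- charToRaw(refseqs[[ch]])
    n <- length(s)
    found <- list()
    for (u in seq_len(min(max_unit, n - 1L))) {
      eq <- s[seq_len(n - u)] == s[(u + 1L):n]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      hit <- which(r$values & (r$lengths + u) >= max(min_cluster_len, 2L * u))
      for (h in hit) {
        cl_start <- starts[h]          # 0-based
        cl_end <- ends[h] + u          # tandem region spans run + one unit
        found[[length(found) + 1L]] <- c(cl_start, cl_end, u)
      }
    }
    if (!length(found)) next
    m <- do.call(rbind, found)
    m <- m[order(m[, 3], m[, 1]), , drop = FALSE]  # smallest period first
    taken <- as_iranges0(integer(0), integer(0))
    for (i in seq_len(nrow(m))) {
      q <- as_iranges0(m[i, 1], m[i, 2])
      if (length(taken) && sum(IRanges::width(IRanges::intersect(q, taken))) >
          0.5 * IRanges::width(q)) next
      taken <- c(taken, q)
      u <- m[i, 3]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = m[i, 1], end = m[i, 2],
        unit = substr(refseqs[[ch]], m[i, 1] + 1L, m[i, 1] + u),
        unit_len = u, copies = (m[i, 2] - m[i, 1]) / u,
        length = m[i, 2] - m[i, 1], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               unit = character(0), unit_len = integer(0), copies = numeric(0),
               length = integer(0))
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Flag preassembly-blocking clusters
#'
#' Tandem clusters longer than the threshold prevent preassembly of a long
#' read across the locus.
#'
#' @param clusters Output of \code{\link{find_tandem_clusters}}.
#' @param threshold Blocking length threshold (bp).
#' @return The clusters with a logical \code{blocker} column.
#' @export
flag_blockers <- function(clusters, threshold = 500L) {
  clusters$blocker <- clusters$length > threshold
  clusters
}

#' Collapsed-repeat copy number from relative read depth
#'
#' Estimates the copy number of a region that is collapsed to a single copy
#' in the reference as mean depth over the region divided by mean genome
#' depth. The genome mean excludes the queried region and zero-depth bases
#' (to avoid self-dilution); the naive genome-wide mean is reported too.
#'
#' @param track A \code{\link{depth_track}} (built including supplementary
#'   records when split reads carry the region's coverage).
#' @param chrom,start,end The region (0-based half-open).
#' @return list(copy_number, copy_number_naive, region_mean, genome_mean,
#'   genome_mean_naive).
#' @export
copy_number <- function(track, chrom, start, end) {
  v <- track$per_chrom[[chrom]]
  if (is.null(v) || end > length(v) || start < 0L) stopf("region outside genome")
  region <- v[(start + 1L):end]
  region_mean <- mean(region)
  allv <- unlist(track$per_chrom, use.names = FALSE)
  naive_mean <- mean(allv)
  outside <- c(v[-((start + 1L):end)],
               unlist(track$per_chrom[names(track$per_chrom) != chrom], use.names = FALSE))
  outside <- outside[outside > 0L]
  # a region spanning the whole genome leaves nothing outside; fall back to
  # the naive mean so the identity copy number of 1 is still reported
  if (length(outside) == 0L) outside <- region[region > 0L]
  if (length(outside) == 0L || mean(outside) == 0) stopf("zero genome mean depth")
  g_mean <- mean(outside)
  list(copy_number = region_mean / g_mean,
       copy_number_naive = if (naive_mean > 0) region_mean / naive_mean else NA_real_,
       region_mean = region_mean, genome_mean = g_mean,
       genome_mean_naive = naive_mean)
}
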