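# Per-read variant extraction from CIGAR/MD, site aggregation with the
# coverage >= 1 / count >= 1 / support-fraction > 0.5 calling rule, and
# error summaries with 100-window positional profiles.

#' Extract per-read variant events from alignment records
#'
#' Every CIGAR I/D op becomes an insertion/deletion event and every MD
#' substitution an SNV event, with reference (0-based) and read-relative
#' coordinates. Soft clips are not variants; they feed insertion recovery.
#' Records without an MD tag contribute indels only and are flagged.
#'
#' @param records SAM record data.frame (see \code{\link{read_sam}});
#'   only primary alignments are used.
#' @return data.frame: read_id, chrom, type (SNV|INS|DEL), pos (0-based
#'   breakpoint or interval start), size, ref, alt, read_frac (event
#'   position as a fraction of read length, in sequencing orientation).
#'   Attribute \code{n_no_md} counts records lacking MD.
#' @export
extract_read_variants <- function(records) {
  records <- records[records$is_primary, , drop = FALSE]
  out <- vector("list", nrow(records))
  n_no_md <- 0L
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    w <- cigar_walk(r)
    L <- nchar(r$seq)
    ev <- list()
    ins <- w[w$event == "insertion", , drop = FALSE]
    if (nrow(ins)) {
      ev[[length(ev) + 1L]] <- data.frame(
        read_id = r$read_id, chrom = r$chrom, type = "INS", pos = ins$ref_start,
        size = ins$read_end - ins$read_start, ref = "", alt = ins$seq,
        read_pos = ins$read_start, stringsAsFactors = FALSE)
    }
    del <- w[w$event == "deletion", , drop = FALSE]
    if (nrow(del)) {
      ev[[length(ev) + 1L]] <- data.frame(
        read_id = r$read_id, chrom = r$chrom, type = "DEL", pos = del$ref_start,
        size = del$ref_end - del$ref_start, ref = NA_character_, alt = "",
        read_pos = del$read_start, stringsAsFactors = FALSE)
    }
    if (!is.na(r$md)) {
      subs <- md_to_substitutions(r)
      if (nrow(subs)) {
        ev[[length(ev) + 1L]] <- data.frame(
          read_id = r$read_id, chrom = r$chrom, type = "SNV", pos = subs$ref_pos,
          size = 1L, ref = subs$ref_base, alt = subs$read_base,
          read_pos = subs$read_pos, stringsAsFactors = FALSE)
      }
    } else {
      n_no_md <- n_no_md + 1L
    }
    if (length(ev)) {
      e <- do.call(rbind, ev)
      # read-relative fraction in sequencing orientation
      rp <- if (r$strand == "-") L - e$read_pos - 1L else e$read_pos
      e$read_frac <- pmin(1 - 1e-9, pmax(0, rp / L))
      e$read_pos <- NULL
      out[[i]] <- e
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), chrom = character(0), type = character(0),
               pos = integer(0), size = integer(0), ref = character(0),
               alt = character(0), read_frac = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_no_md") <- n_no_md
  res
}

#' Aggregate per-read events into called variant sites
#'
#' Indels are first left-aligned against the reference so that equivalent
#' placements merge. Identical events (type, position, allele) are pooled;
#' a site is called when depth >= min_coverage, support >= min_count and
#' support/depth > min_frac -- an emulation of probabilistic variant
#' detection at minimum coverage 1, minimum count 1 and probability > 0.5.
#'
#' @param events Output of \code{\link{extract_read_variants}}.
#' @param depth DepthTrack from \code{\link{depth_track}}.
#' @param refseqs Named character vector of reference sequences (for
#'   left-alignment and deletion alleles).
#' @param min_coverage,min_count,min_frac Calling thresholds.
#' @return data.frame of sites: chrom, type, pos, size, ref, alt, support,
#'   depth, called, read_ids (comma-joined).
#' @export
aggregate_sites <- function(events, depth, refseqs, min_coverage = 1L,
                            min_count = 1L, min_frac = 0.5) {
  if (nrow(events) == 0L) {
    return(data.frame(chrom = character(0), type = character(0), pos = integer(0),
                      size = integer(0), ref = character(0), alt = character(0),
                      support = integer(0), depth = integer(0), called = logical(0),
                      read_ids = character(0)))
  }
  ev <- events
  chrom_len <- vapply(refseqs, nchar, integer(1))
  if (any(ev$pos < 0L | ev$pos + ifelse(ev$type == "DEL", ev$size, 0L) >
          chrom_len[ev$chrom])) {
    stopf("event beyond chromosome end")
  }
  # left-align indels to canonical placement
  for (i in which(ev$type == "INS")) {
    la <- left_align_insertion(refseqs[[ev$chrom[i]]], ev$pos[i], ev$alt[i])
    ev$pos[i] <- la$pos; ev$alt[i] <- la$seq
  }
  for (i in which(ev$type == "DEL")) {
    la <- left_align_deletion(refseqs[[ev$chrom[i]]], ev$pos[i], ev$size[i])
    ev$pos[i] <- la$start; ev$ref[i] <- la$seq
  }
  key <- paste(ev$chrom, ev$type, ev$pos, ev$size, ev$alt, sep = "\r")
  grp <- split(seq_len(nrow(ev)), key)
  sites <- lapply(grp, function(ix) {
    e <- ev[ix[1], ]
    d <- site_depth(depth, e$chrom, e$pos, e$type, e$size)
    support <- length(unique(ev$read_id[ix]))
    data.frame(chrom = e$chrom, type = e$type, pos = e$pos, size = e$size,
               ref = e$ref, alt = e$alt, support = support,
               depth = max(d, support), read_ids = paste(unique(ev$read_id[ix]),
                                                         collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sites)
  out <- out[order(out$chrom, out$pos, out$type), , drop = FALSE]
  out$called <- out$depth >= min_coverage & out$support >= min_count &
    out$support / out$depth > min_frac
  rownames(out) <- NULL
  out[, c("chrom", "type", "pos", "size", "ref", "alt", "support", "depth",
          "called", "read_ids")]
}

# local depth at a site: base depth at an SNV position, flanking-base depth
# at an insertion breakpoint, mean depth over a deleted interval
site_depth <- function(depth, chrom, pos, type, size) {
  v <- depth$per_chrom[[chrom]]
  n <- length(v)
  if (type == "SNV") return(v[min(n, pos + 1L)])
  if (type == "INS") {
    lo <- max(1L, pos); hi <- min(n, pos + 1L)
    return(max(v[lo:hi]))
  }
  as.integer(round(mean(v[(pos + 1L):min(n, pos + size)])))
}

#' Summarize error ratios, size classes and positional profiles
#'
#' Ratios are reported both as events and as event bases per aligned read
#' base (M/=/X); an 8 bp deletion contributes 8 event bases. Events are
#' split at the long-indel size cutoff (default 9 bp) and binned into 100
#' equal windows of normalized read length.
#'
#' @param events Output of \code{\link{extract_read_variants}}.
#' @param records The alignment records the events came from.
#' @param long_cutoff Size (bp) from which an indel counts as long.
#' @return list: aligned_bases; ratio (per-type events/aligned_bases);
#'   ratio_bases (event bases/aligned_bases); size_class counts; profile
#'   (100 x 3 matrix of window event counts); long_profile (same for
#'   long indels only).
#' @export
error_summary <- function(events, records, long_cutoff = 9L) {
  prim <- records[records$is_primary, , drop = FALSE]
  aligned <- sum(vapply(prim$cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$len[ops$op %in% c("M", "=", "X")])
  }, numeric(1)))
  if (aligned == 0) stopf("no aligned bases")
  types <- c("SNV", "INS", "DEL")
  ratio <- vapply(types, function(t) sum(events$type == t) / aligned, numeric(1))
  ratio_bases <- vapply(types, function(t)
    sum(events$size[events$type == t]) / aligned, numeric(1))
  size_class <- table(factor(ifelse(events$size >= long_cutoff, "long", "short"),
                             levels = c("short", "long")),
                      factor(events$type, levels = types))
  win <- pmin(99L, as.integer(floor(events$read_frac * 100)))
  profile <- vapply(types, function(t)
    tabulate(win[events$type == t] + 1L, nbins = 100L), integer(100))
  long <- events$size >= long_cutoff & events$type != "SNV"
  long_profile <- vapply(c("INS", "DEL"), function(t)
    tabulate(win[long & events$type == t] + 1L, nbins = 100L), integer(100))
  list(aligned_bases = aligned, ratio = ratio, ratio_bases = ratio_bases,
       size_class = size_class, profile = profile, long_profile = long_profile,
       long_cutoff = long_cutoff)
}
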