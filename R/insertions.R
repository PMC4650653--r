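# Recovery of sequences missing from the reference, in four modes:
#   within_read      - insertion present as a CIGAR I op in one alignment
#   self_mapped      - one read's unaligned end re-anchored locally at
#                      relaxed stringency; the un-anchored middle is the
#                      insertion
#   cross_mapped     - overlapping unaligned ends of two adjacent reads,
#                      merged into one gap-free sequence
#   close_breakpoint - non-overlapping unaligned ends joined across an
#                      unknown-length gap
# followed by breakpoint-clustered merging and genomic-context annotation.

insertion_call_row <- function(category, chrom, breakpoint, seq, size, read_ids) {
  data.frame(category = category, chrom = chrom, breakpoint = as.integer(breakpoint),
             seq = seq, size = as.integer(size),
             support = length(unique(read_ids)),
             read_ids = paste(unique(read_ids), collapse = ","),
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(category = character(0), chrom = character(0), breakpoint = integer(0),
             seq = character(0), size = integer(0), support = integer(0),
             read_ids = character(0))
}

#' Collect unaligned ends (soft-clipped read arms) from primary alignments
#'
#' @param records SAM record data.frame.
#' @param min_clip_len Ignore clips shorter than this (alignment jitter).
#' @return data.frame read_id, side (left|right of the primary alignment),
#'   chrom, breakpoint (0-based primary boundary on that side), clip_seq,
#'   primary_start, primary_end.
#' @export
unaligned_ends <- function(records, min_clip_len = 30L) {
  prim <- records[records$is_primary, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(prim))) {
    r <- prim[i, ]
    ops <- parse_cigar(r$cigar)
    if (any(ops$op == "H")) {
      stopf("record %s is hard-clipped; insertion recovery needs the clipped bases",
            r$read_id)
    }
    if (nrow(ops) == 0L || !any(ops$op == "S")) next
    ref_span <- cigar_ref_length(ops)
    L <- nchar(r$seq)
    if (ops$op[1] == "S" && ops$len[1] >= min_clip_len) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = r$read_id, side = "left", chrom = r$chrom,
        breakpoint = r$ref_start, clip_seq = substr(r$seq, 1L, ops$len[1]),
        primary_start = r$ref_start, primary_end = r$ref_start + ref_span,
        stringsAsFactors = FALSE)
    }
    nlast <- nrow(ops)
    if (ops$op[nlast] == "S" && ops$len[nlast] >= min_clip_len) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = r$read_id, side = "right", chrom = r$chrom,
        breakpoint = r$ref_start + ref_span,
        clip_seq = substr(r$seq, L - ops$len[nlast] + 1L, L),
        primary_start = r$ref_start, primary_end = r$ref_start + ref_span,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), side = character(0), chrom = character(0),
               breakpoint = integer(0), clip_seq = character(0),
               primary_start = integer(0), primary_end = integer(0))
  rownames(res) <- NULL
  res
}

#' Within-read insertions from called variant sites
#'
#' @param sites Called sites from \code{\link{aggregate_sites}}.
#' @param min_size Minimum insertion size (bp).
#' @return Insertion call data.frame.
#' @export
find_within_read <- function(sites, min_size = 9L) {
  s <- sites[sites$type == "INS" & sites$size >= min_size & sites$called, , drop = FALSE]
  if (nrow(s) == 0L) return(empty_calls())
  out <- do.call(rbind, lapply(seq_len(nrow(s)), function(i)
    insertion_call_row("within_read", s$chrom[i], s$pos[i], s$alt[i], s$size[i],
                       strsplit(s$read_ids[i], ",")[[1]])))
  rownames(out) <- NULL
  out
}

# split a clip into (insertion prefix, reference-anchored suffix) against a
# window W that starts at the breakpoint. Returns the number of leading
# non-reference bases, or NA when no anchor of at least min_anchor bases at
# min_identity is found. Seeded multi-anchor scan followed by a tolerant
# backward walk, so small indel errors inside the anchor do not detach it.
anchor_split <- function(clipraw, Wraw, min_anchor, min_identity,
                         seed_len = 48L, seed_step = 200L) {
  n <- length(clipraw)
  nw <- length(Wraw)
  if (n < min_anchor || nw < seed_len) return(NA_integer_)
  Wstr <- Biostrings::DNAString(rawToChar(Wraw))
  try_seed <- function(k, d_prev) {
    seed <- rawToChar(clipraw[(k + 1L):(k + seed_len)])
    hits <- Biostrings::matchPattern(seed, Wstr, max.mismatch = 2L)
    ps <- IRanges::start(hits)
    d_cand <- k + 1L - ps  # leading non-reference bases implied by each hit
    d_cand <- d_cand[d_cand >= -5L & d_cand <= n - min_anchor + 5L]
    if (length(d_cand) == 0L) return(NA_integer_)
    if (is.na(d_prev)) {
      nn <- d_cand[d_cand >= 0L]
      if (length(nn)) min(nn) else min(d_cand)
    } else d_cand[which.min(abs(d_cand - d_prev))]
  }
  # coarse scan over the whole clip (indel errors shift the offset d between
  # seeds; every seed re-anchors independently)
  starts <- seq(n - seed_len, 0L, by = -seed_step)  # 0-based, shallow first
  best_k <- NA_integer_; best_d <- NA_integer_
  d_prev <- NA_integer_
  for (k in starts) {
    d <- try_seed(k, d_prev)
    if (is.na(d)) next
    best_k <- k; best_d <- d
    d_prev <- d
  }
  if (is.na(best_k)) return(NA_integer_)
  # fine scan below the deepest coarse anchor to land close to the split
  k <- best_k - seed_len
  while (k >= max(0L, best_k - seed_step)) {
    d <- try_seed(k, best_d)
    if (is.na(d)) break
    best_k <- k; best_d <- d
    k <- k - seed_len
  }
  # tolerant backward walk from the deepest anchored seed toward the split;
  # starts at the seed's last base so the seed region is re-verified too
  d <- best_d
  j <- min(n, best_k + seed_len)  # 1-based clip index, walking down
  recent <- integer(0) # sliding mismatch window
  matched <- 0L; walked <- 0L
  while (j > max(0L, d)) {
    wi <- j - d        # 1-based W index for clip[j] is j - d
    if (wi < 1L) break
    ok <- clipraw[j] == Wraw[wi]
    walked <- walked + 1L
    matched <- matched + as.integer(ok)
    recent <- c(recent, as.integer(!ok))
    if (length(recent) > 8L) recent <- recent[-1L]
    if (sum(recent) >= 3L) { j <- j + sum(recent) ; break }  # error cluster: stop
    j <- j - 1L
  }
  split <- j
  anchor_len <- n - split
  if (anchor_len < min_anchor) return(NA_integer_)
  if (walked > 0L && matched / walked < min_identity) return(NA_integer_)
  as.integer(split)
}

#' Self-mapped insertions from single unaligned ends
#'
#' The clipped sequence's distal portion is re-anchored against the
#' reference window adjacent to the breakpoint at relaxed stringency; the
#' un-anchored middle of the read is the recovered insertion. Ends at the
#' same breakpoint share one detection: once a call is made, consistent
#' ends are added as support rather than re-anchored.
#'
#' @param ends \code{\link{unaligned_ends}} output.
#' @param refseqs Named character vector of reference sequences.
#' @param relax_min_anchor Minimum re-anchored bases.
#' @param relax_min_identity Minimum anchor identity.
#' @param min_size Minimum insertion size.
#' @param slack Extra reference window beyond the clip length.
#' @return list(calls = insertion call data.frame, used = indices of
#'   consumed ends).
#' @export
find_self_mapped <- function(ends, refseqs, relax_min_anchor = 200L,
                             relax_min_identity = 0.90, min_size = 9L,
                             slack = 2000L) {
  if (nrow(ends) == 0L) return(list(calls = empty_calls(), used = integer(0)))
  refraw <- lapply(setNames(names(refseqs), names(refseqs)),
                   function(ch) charToRaw(refseqs[[ch]]))
  grp_key <- paste(ends$chrom, ends$side, round(ends$breakpoint / 25))
  calls <- list()
  used <- integer(0)
  for (g in split(seq_len(nrow(ends)), grp_key)) {
    g <- g[order(-nchar(ends$clip_seq[g]))]
    call <- NULL
    attempts <- 0L
    supporters <- integer(0)
    for (i in g) {
      e <- ends[i, ]
      clipraw <- charToRaw(e$clip_seq)
      n <- length(clipraw)
      rr <- refraw[[e$chrom]]
      if (!is.null(call)) {
        # cheap consistency check against the existing call
        if (abs(e$breakpoint - call$breakpoint) <= 25L) supporters <- c(supporters, i)
        next
      }
      if (attempts >= 3L) next
      attempts <- attempts + 1L
      if (e$side == "right") {
        W <- rr[(e$breakpoint + 1L):min(length(rr), e$breakpoint + n + slack)]
        d <- anchor_split(clipraw, W, relax_min_anchor, relax_min_identity)
        if (is.na(d) || d < min_size) next
        ins_seq <- rawToChar(clipraw[seq_len(d)])
      } else {
        W <- rr[max(1L, e$breakpoint - n - slack):e$breakpoint]
        d <- anchor_split(rev(clipraw), rev(W), relax_min_anchor, relax_min_identity)
        if (is.na(d) || d < min_size) next
        ins_seq <- rawToChar(clipraw[(n - d + 1L):n])
      }
      call <- list(breakpoint = e$breakpoint, seq = ins_seq, chrom = e$chrom)
      supporters <- c(supporters, i)
    }
    if (!is.null(call)) {
      calls[[length(calls) + 1L]] <- insertion_call_row(
        "self_mapped", call$chrom, call$breakpoint, call$seq, nchar(call$seq),
        ends$read_id[supporters])
      used <- c(used, supporters)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  rownames(out) <- NULL
  list(calls = out, used = used)
}

# two recovered sequences describe the same event when the shorter aligns
# locally within the longer at high identity over most of its length
# (indel-aware: detector walks can pad or trim a few flank bases)
sequences_compatible <- function(a, b, min_identity) {
  if (identical(a, b)) return(TRUE)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = NULL,
                                       gapOpening = 4, gapExtension = 1)
  span <- Biostrings::nchar(Biostrings::pattern(aln))
  span >= 0.8 * nchar(a) && Biostrings::pid(aln) >= 100 * min_identity
}

# maximal suffix(A)/prefix(B) overlap at the identity threshold, or 0
best_overlap <- function(a, b, min_overlap, min_identity) {
  nmax <- min(length(a), length(b))
  for (o in seq(nmax, min_overlap)) {
    if (o < min_overlap) break
    ident <- mean(a[(length(a) - o + 1L):length(a)] == b[seq_len(o)])
    if (ident >= min_identity) return(o)
  }
  0L
}

#' Cross-mapped and close-breakpoint insertions from paired unaligned ends
#'
#' A right-side end (read arm anchored left of the insertion) is paired
#' with a left-side end (arm anchored right of it) when their breakpoints
#' lie within \code{pair_max_distance}. If the clips overlap by at least
#' \code{min_overlap} bases at \code{min_overlap_identity}, the merged
#' gap-free sequence is a cross-mapped call; otherwise the pair emits a
#' close-breakpoint call whose sequence carries a single unknown-length
#' gap marker ("-"). Ends are consumed best-overlap-first; an end is used
#' in at most one call.
#'
#' @param ends Unconsumed \code{\link{unaligned_ends}} rows.
#' @param pair_max_distance Maximum breakpoint distance between the ends.
#' @param min_overlap,min_overlap_identity Overlap acceptance thresholds.
#' @param min_size Minimum (lower-bound) insertion size.
#' @return list(cross = calls, close = calls).
#' @export
find_breakpoint_pairs <- function(ends, pair_max_distance = 50L,
                                  min_overlap = 30L, min_overlap_identity = 0.95,
                                  min_size = 9L) {
  rights <- which(ends$side == "right")
  lefts <- which(ends$side == "left")
  pairs <- list()
  for (i in rights) {
    for (j in lefts) {
      if (ends$chrom[i] != ends$chrom[j]) next
      if (ends$read_id[i] == ends$read_id[j]) next
      if (abs(ends$breakpoint[i] - ends$breakpoint[j]) > pair_max_distance) next
      a <- charToRaw(ends$clip_seq[i]); b <- charToRaw(ends$clip_seq[j])
      o <- best_overlap(a, b, min_overlap, min_overlap_identity)
      pairs[[length(pairs) + 1L]] <- list(i = i, j = j, overlap = o)
    }
  }
  if (length(pairs) == 0L) return(list(cross = empty_calls(), close = empty_calls()))
  ov <- vapply(pairs, `[[`, integer(1), "overlap")
  dist <- vapply(pairs, function(p)
    abs(as.numeric(ends$breakpoint[p$i]) - ends$breakpoint[p$j]), numeric(1))
  ordp <- order(-ov, dist)
  taken <- logical(nrow(ends))
  cross <- list(); close <- list()
  for (p in pairs[ordp]) {
    if (taken[p$i] || taken[p$j]) next
    taken[p$i] <- TRUE; taken[p$j] <- TRUE
    A <- ends$clip_seq[p$i]; B <- ends$clip_seq[p$j]
    bp <- ends$breakpoint[p$i]
    rid <- c(ends$read_id[p$i], ends$read_id[p$j])
    if (p$overlap >= min_overlap) {
      merged <- paste0(A, substr(B, p$overlap + 1L, nchar(B)))
      if (nchar(merged) >= min_size) {
        cross[[length(cross) + 1L]] <- insertion_call_row(
          "cross_mapped", ends$chrom[p$i], bp, merged, nchar(merged), rid)
      }
    } else {
      size <- nchar(A) + nchar(B)
      if (size >= min_size) {
        close[[length(close) + 1L]] <- insertion_call_row(
          "close_breakpoint", ends$chrom[p$i], bp, paste0(A, "-", B), size, rid)
      }
    }
  }
  list(cross = if (length(cross)) do.call(rbind, cross) else empty_calls(),
       close = if (length(close)) do.call(rbind, close) else empty_calls())
}

#' Merge insertion calls across detection modes and annotate context
#'
#' Gap-free calls are first left-aligned to their canonical placement.
#' Calls whose breakpoints fall within \code{merge_tolerance} of each other
#' describe the same missing-sequence event and collapse to one, keeping
#' the category of highest precedence (within_read > self_mapped >
#' cross_mapped > close_breakpoint) and the union of supporting reads.
#' Gap-free calls of equal precedence that disagree below
#' \code{merge_identity} stay separate. Context is coding_exon when the
#' breakpoint lies in a coding exon, intron when inside a gene span, else
#' intergenic.
#'
#' @param calls Insertion call data.frame (rbind of all modes).
#' @param genes List of gene models.
#' @param refseqs Named character vector of reference sequences.
#' @param merge_tolerance Breakpoint clustering distance (bp).
#' @param merge_identity Identity below which equal-precedence gap-free
#'   calls are kept apart.
#' @return Merged, annotated insertion call data.frame with context and
#'   validation_status columns.
#' @export
merge_and_annotate <- function(calls, genes, refseqs, merge_tolerance = 10L,
                               merge_identity = 0.95) {
  if (nrow(calls) == 0L) {
    out <- empty_calls()
    out$context <- character(0)
    out$validation_status <- character(0)
    return(out)
  }
  gapfree <- !grepl("-", calls$seq, fixed = TRUE)
  for (i in which(gapfree)) {
    la <- left_align_insertion(refseqs[[calls$chrom[i]]], calls$breakpoint[i],
                               calls$seq[i])
    calls$breakpoint[i] <- la$pos
    calls$seq[i] <- la$seq
  }
  prec <- c(within_read = 1L, self_mapped = 2L, cross_mapped = 3L,
            close_breakpoint = 4L)
  calls <- calls[order(calls$chrom, calls$breakpoint), , drop = FALSE]
  # single-linkage clustering on breakpoints
  cl <- integer(nrow(calls))
  cur <- 0L
  for (i in seq_len(nrow(calls))) {
    if (i == 1L || calls$chrom[i] != calls$chrom[i - 1L] ||
        calls$breakpoint[i] - calls$breakpoint[i - 1L] > merge_tolerance) {
      cur <- cur + 1L
    }
    cl[i] <- cur
  }
  merged <- list()
  for (g in split(seq_len(nrow(calls)), cl)) {
    sub <- calls[g, , drop = FALSE]
    sub <- sub[order(prec[sub$category], -sub$support), , drop = FALSE]
    keep <- rep(FALSE, nrow(sub))
    keep[1L] <- TRUE
    # equal-precedence gap-free conflicts stay separate
    for (i in seq_len(nrow(sub))[-1L]) {
      conflict <- FALSE
      if (prec[sub$category[i]] == prec[sub$category[1L]] &&
          !grepl("-", sub$seq[i], fixed = TRUE) &&
          !grepl("-", sub$seq[1L], fixed = TRUE)) {
        conflict <- !sequences_compatible(sub$seq[1L], sub$seq[i], merge_identity)
      }
      keep[i] <- conflict
    }
    rid_all <- unique(unlist(strsplit(sub$read_ids[!keep | seq_len(nrow(sub)) == 1L],
                                      ",")))
    for (i in which(keep)) {
      rid <- if (i == 1L) rid_all else strsplit(sub$read_ids[i], ",")[[1]]
      merged[[length(merged) + 1L]] <- insertion_call_row(
        sub$category[i], sub$chrom[i], sub$breakpoint[i], sub$seq[i], sub$size[i], rid)
    }
  }
  out <- do.call(rbind, merged)
  out$context <- vapply(seq_len(nrow(out)), function(i)
    breakpoint_context(genes, out$chrom[i], out$breakpoint[i]), character(1))
  out$validation_status <- "unconfirmed"
  out <- out[order(out$chrom, out$breakpoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full four-mode insertion recovery
#'
#' @param records SAM record data.frame.
#' @param sites Called sites from \code{\link{aggregate_sites}}.
#' @param refseqs Named character vector of reference sequences.
#' @param genes List of gene models.
#' @param min_size Minimum insertion size (bp).
#' @param ... Passed through to the mode detectors.
#' @return Merged, annotated insertion call data.frame.
#' @export
recover_insertions <- function(records, sites, refseqs, genes, min_size = 9L, ...) {
  within <- find_within_read(sites, min_size = min_size)
  ends <- unaligned_ends(records)
  sm <- find_self_mapped(ends, refseqs, min_size = min_size, ...)
  rest <- if (length(sm$used)) ends[-sm$used, , drop = FALSE] else ends
  pc <- find_breakpoint_pairs(rest, min_size = min_size)
  all_calls <- rbind(within, sm$calls, pc$cross, pc$close)
  merge_and_annotate(all_calls, genes, refseqs)
}
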