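# Aligner emulator: projects each read's known donor interval onto the
# reference through the donor block map, instead of aligning. Donor
# insertions small enough (and anchored well enough) become CIGAR I ops;
# larger ones soft-clip the shorter arm ("unaligned end"). Reads carrying
# more than blocker_threshold bases of a blocked tandem cluster are
# withheld, emulating preassembly failure. Extra collapsed-repeat copies
# are wrapped onto the single reference copy as split alignments.

#' Emulate read-to-reference alignment from simulation truth
#'
#' @param sim Output of \code{\link{simulate_reads}}.
#' @param donor The \code{lra_donor} the reads were simulated from.
#' @param config The \code{\link{simulation_config}}.
#' @return list(records = SAM record data.frame (as \code{\link{read_sam}}),
#'   n_withheld, withheld_ids, n_unmapped, header).
#' @export
emulate_alignment <- function(sim, donor, config) {
  reference <- donor$reference
  al <- config$aligner
  refraw <- lapply(setNames(names(reference$seqs), names(reference$seqs)),
                   function(ch) charToRaw(reference$seqs[[ch]]))
  # blocked tandem clusters, lifted to donor coordinates
  bc <- blocked_clusters(reference)
  blocked_donor <- lapply(setNames(names(donor$seqs), names(donor$seqs)), function(ch) {
    b <- bc[bc$chrom == ch, , drop = FALSE]
    btab <- donor$blocks[donor$blocks$chrom == ch, , drop = FALSE]
    iv <- lapply(seq_len(nrow(b)), function(i)
      lift_interval_to_donor(btab, b$start[i], b$end[i]))
    iv <- iv[!vapply(iv, is.null, logical(1))]
    if (length(iv)) do.call(rbind, iv) else matrix(numeric(0), ncol = 2L)
  })
  blocks_by_chrom <- split(donor$blocks, donor$blocks$chrom)
  collapsed <- reference$collapsed

  tr <- sim$truth_reads
  recs <- list()
  withheld <- character(0)
  n_unmapped <- 0L
  for (i in seq_len(nrow(tr))) {
    ch <- tr$chrom[i]
    ds <- tr$donor_start[i]; de <- tr$donor_end[i]
    biv <- blocked_donor[[ch]]
    if (nrow(biv)) {
      ov <- sum(pmax(0L, pmin(biv[, 2], de) - pmax(biv[, 1], ds)))
      if (ov > al$blocker_threshold) {
        withheld <- c(withheld, tr$read_id[i])
        next
      }
    }
    fwd <- if (tr$strand[i] == "-") revcomp(sim$reads$seq[i]) else sim$reads$seq[i]
    rr <- project_read(ch, ds, de, fwd, sim$errors[[tr$read_id[i]]],
                       blocks_by_chrom[[ch]], collapsed, al, refraw[[ch]],
                       tr$read_id[i], tr$strand[i])
    if (is.null(rr)) {
      n_unmapped <- n_unmapped + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = tr$read_id[i], flag = FLAG_UNMAPPED, chrom = "*", ref_start = -1L,
        mapq = 0L, cigar = "*", seq = fwd, md = NA_character_, stringsAsFactors = FALSE)
    } else {
      recs[[length(recs) + 1L]] <- rr
    }
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) {
    records <- data.frame(read_id = character(0), flag = integer(0), chrom = character(0),
                          ref_start = integer(0), mapq = integer(0), cigar = character(0),
                          seq = character(0), md = character(0))
  }
  rownames(records) <- NULL
  records$strand <- ifelse(bitwAnd(records$flag, FLAG_REVERSE) != 0L, "-", "+")
  records$is_supplementary <- bitwAnd(records$flag, FLAG_SUPPLEMENTARY) != 0L
  records$is_primary <- !records$is_supplementary & bitwAnd(records$flag, FLAG_UNMAPPED) == 0L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference$seqs), nchar(reference$seqs)))
  list(records = records, n_withheld = length(withheld), withheld_ids = withheld,
       n_unmapped = n_unmapped, header = header)
}

# project one read onto the reference; returns SAM record rows or NULL if
# the read has no alignable anchor
project_read <- function(ch, ds, de, fwd, errors, btab, collapsed, al, refr,
                         read_id, strand) {
  # 1. op chain from donor blocks overlapping [ds, de)
  ops <- list()  # each: list(op, ref_start, ref_end, dstart, dend, kind)
  ov <- btab[btab$donor_end > ds & btab$donor_start < de, , drop = FALSE]
  prev_match <- NULL
  for (j in seq_len(nrow(ov))) {
    b <- ov[j, ]
    a0 <- max(ds, b$donor_start); a1 <- min(de, b$donor_end)
    if (b$type == "match") {
      # implied deletion between consecutive match blocks the read spans
      if (!is.null(prev_match) && prev_match$ref_end < b$ref_start &&
          prev_match$dend == b$donor_start && a0 == b$donor_start) {
        ops[[length(ops) + 1L]] <- list(op = "D", ref_start = prev_match$ref_end,
                                        ref_end = b$ref_start, dstart = a0, dend = a0,
                                        kind = "donor")
      }
      off <- b$ref_start - b$donor_start
      ops[[length(ops) + 1L]] <- list(op = "M", ref_start = a0 + off, ref_end = a1 + off,
                                      dstart = a0, dend = a1, kind = "match")
      prev_match <- list(ref_end = b$ref_end, dend = b$donor_end)
    } else if (b$type == "ins") {
      ops[[length(ops) + 1L]] <- list(op = "I", ref_start = b$ref_start,
                                      ref_end = b$ref_start, dstart = a0, dend = a1,
                                      kind = "ins")
    } else { # collapsed_ins: wrap extra copies onto the reference unit
      unit <- nchar(collapsed$unit)
      us <- collapsed$start
      o0 <- a0 - b$donor_start  # offset within the expansion
      while (o0 < a1 - b$donor_start) {
        seg <- min(unit - (o0 %% unit), (a1 - b$donor_start) - o0)
        ops[[length(ops) + 1L]] <- list(op = "M", ref_start = us + (o0 %% unit),
                                        ref_end = us + (o0 %% unit) + seg,
                                        dstart = b$donor_start + o0,
                                        dend = b$donor_start + o0 + seg,
                                        kind = "collapsed")
        o0 <- o0 + seg
      }
    }
  }
  # 2. overlay read-level errors (donor coordinates)
  if (!is.null(errors) && nrow(errors)) {
    for (k in seq_len(nrow(errors))) {
      kind <- errors$kind[k]
      if (kind == "sub") next  # visible through MD only
      p <- errors$pos[k]; elen <- errors$len[k]
      idx <- which(vapply(ops, function(o)
        o$op == "M" && o$dstart < p && p + (if (kind == "del") elen else 0L) <= o$dend &&
          o$kind == "match", logical(1)))
      if (length(idx) == 0L) next
      o <- ops[[idx[1]]]
      off <- p - o$dstart
      left <- list(op = "M", ref_start = o$ref_start, ref_end = o$ref_start + off,
                   dstart = o$dstart, dend = p, kind = o$kind)
      if (kind == "ins") {
        mid <- list(op = "I", ref_start = o$ref_start + off, ref_end = o$ref_start + off,
                    dstart = p, dend = p, kind = "error", err_len = elen)
        right <- list(op = "M", ref_start = o$ref_start + off, ref_end = o$ref_end,
                      dstart = p, dend = o$dend, kind = o$kind)
      } else {
        mid <- list(op = "D", ref_start = o$ref_start + off,
                    ref_end = o$ref_start + off + elen, dstart = p, dend = p + elen,
                    kind = "error")
        right <- list(op = "M", ref_start = o$ref_start + off + elen, ref_end = o$ref_end,
                      dstart = p + elen, dend = o$dend, kind = o$kind)
      }
      ops <- append(ops[-idx[1]], list(left, mid, right), after = idx[1] - 1L)
    }
  }
  # 3. read-consumed length per op; running read offsets
  nops <- length(ops)
  if (nops == 0L) return(NULL)
  rlen <- vapply(ops, function(o) {
    if (o$op == "M") o$dend - o$dstart
    else if (o$op == "I") {
      if (identical(o$kind, "error")) o$err_len else o$dend - o$dstart
    } else {
      if (identical(o$kind, "error")) -(o$dend - o$dstart) else 0L
    }
  }, numeric(1))
  consume <- ifelse(vapply(ops, function(o) o$op, character(1)) == "D", 0L,
                    pmax(0L, rlen))
  # deletion errors shrink the read: read offsets skip nothing for D, but
  # donor offsets already account for removed bases via op construction
  qstart <- cumsum(c(0L, consume))[seq_len(nops)]
  qend <- qstart + consume
  # 4. break decisions
  m_read <- ifelse(vapply(ops, function(o) o$op, character(1)) == "M", consume, 0L)
  tot_m <- cumsum(m_read)
  brk <- logical(nops)  # op itself is a break (removed from chunks)
  for (j in seq_len(nops)) {
    o <- ops[[j]]
    if (o$op == "I" && o$kind == "ins") {
      s <- consume[j]
      fl <- tot_m[j] - m_read[j]
      fr <- tot_m[nops] - tot_m[j]
      if (s > al$max_cigar_insertion || fl < al$min_anchor || fr < al$min_anchor) brk[j] <- TRUE
    } else if (o$op == "D" && o$kind == "donor" &&
               (o$ref_end - o$ref_start) > al$max_cigar_deletion) {
      brk[j] <- TRUE
    }
  }
  # chunk boundaries also fall between adjacent collapsed segments and at
  # collapsed/match junctions (reference-coordinate discontinuity)
  kindv <- vapply(ops, function(o) o$kind, character(1))
  opv <- vapply(ops, function(o) o$op, character(1))
  newchunk <- c(FALSE, (kindv[-1L] == "collapsed" | kindv[-nops] == "collapsed") &
                  opv[-1L] == "M" & opv[-nops] == "M")
  chunk_id <- cumsum(c(1L, as.integer(brk[-nops] | brk[-1L] | newchunk[-1L])))
  chunk_id[brk] <- NA_integer_
  # 5. assemble chunks, pick the primary (most aligned read bases)
  chunks <- split(seq_len(nops), chunk_id)
  chunks <- lapply(chunks, function(ix) {
    # trim leading/trailing non-M ops
    while (length(ix) && opv[ix[1]] != "M") ix <- ix[-1L]
    while (length(ix) && opv[ix[length(ix)]] != "M") ix <- ix[-length(ix)]
    ix
  })
  chunks <- chunks[vapply(chunks, length, integer(1)) > 0L]
  if (length(chunks) == 0L) return(NULL)
  m_bases <- vapply(chunks, function(ix) sum(m_read[ix]), numeric(1))
  prim <- which.max(m_bases)
  total_read <- qend[nops]
  out <- list()
  for (cidx in seq_along(chunks)) {
    ix <- chunks[[cidx]]
    is_collapsed_chunk <- any(kindv[ix] == "collapsed")
    if (cidx != prim && !is_collapsed_chunk) next  # absorbed into primary's clips
    q0 <- qstart[ix[1]]; q1 <- qend[ix[length(ix)]]
    rec <- build_sam_record(ops[ix], q0, q1, total_read, fwd, refr, ch, read_id,
                            strand, supplementary = (cidx != prim))
    out[[length(out) + 1L]] <- rec
  }
  do.call(rbind, out)
}

# build one SAM record from an op run covering read interval [q0, q1)
build_sam_record <- function(oprun, q0, q1, total_read, fwd, refr, ch, read_id,
                             strand, supplementary = FALSE) {
  readraw <- charToRaw(fwd)
  # maximal extension of the terminal M ops into the clips (a real aligner
  # extends while bases keep matching; keeps recovered breakpoints canonical)
  first <- oprun[[1]]; last <- oprun[[length(oprun)]]
  while (q0 > 0L && first$ref_start > 0L &&
         readraw[q0] == refr[first$ref_start]) {
    q0 <- q0 - 1L
    first$ref_start <- first$ref_start - 1L
  }
  while (q1 < total_read && last$ref_end < length(refr) &&
         readraw[q1 + 1L] == refr[last$ref_end + 1L]) {
    q1 <- q1 + 1L
    last$ref_end <- last$ref_end + 1L
  }
  oprun[[1]] <- first; oprun[[length(oprun)]] <- last
  # cigar tokens; adjacent M ops with contiguous reference are merged
  toks <- list()
  for (o in oprun) {
    if (o$op == "M") {
      len <- o$ref_end - o$ref_start
      if (len == 0L) next
      lastt <- if (length(toks)) toks[[length(toks)]] else NULL
      if (!is.null(lastt) && lastt$op == "M" && lastt$ref_end == o$ref_start) {
        toks[[length(toks)]]$ref_end <- o$ref_end
      } else {
        toks[[length(toks) + 1L]] <- list(op = "M", ref_start = o$ref_start,
                                          ref_end = o$ref_end)
      }
    } else if (o$op == "I") {
      len <- if (identical(o$kind, "error")) o$err_len else o$dend - o$dstart
      toks[[length(toks) + 1L]] <- list(op = "I", len = len)
    } else {
      toks[[length(toks) + 1L]] <- list(op = "D", ref_start = o$ref_start,
                                        ref_end = o$ref_end)
    }
  }
  cig <- vapply(toks, function(t) {
    len <- if (t$op == "I") t$len else t$ref_end - t$ref_start
    sprintf("%d%s", len, t$op)
  }, character(1))
  lS <- if (q0 > 0L) sprintf("%dS", q0) else ""
  rS <- if (q1 < total_read) sprintf("%dS", total_read - q1) else ""
  cigar <- paste0(lS, paste(cig, collapse = ""), rS)
  ref_start <- toks[[1]]$ref_start
  # MD from the M blocks
  md <- md_from_toks(toks, readraw, refr, q0)
  flag <- 0L
  if (strand == "-") flag <- flag + FLAG_REVERSE
  if (supplementary) flag <- flag + FLAG_SUPPLEMENTARY
  data.frame(read_id = read_id, flag = flag, chrom = ch, ref_start = ref_start,
             mapq = 60L, cigar = cigar, seq = fwd, md = md, stringsAsFactors = FALSE)
}

md_from_toks <- function(toks, readraw, refr, q0) {
  parts <- character(0)
  run <- 0L
  qp <- q0
  for (t in toks) {
    if (t$op == "M") {
      len <- t$ref_end - t$ref_start
      a <- readraw[(qp + 1L):(qp + len)]
      b <- refr[(t$ref_start + 1L):t$ref_end]
      mism <- which(a != b)
      prev <- 0L
      for (m in mism) {
        run <- run + (m - prev - 1L)
        parts <- c(parts, as.character(run), rawToChar(b[m]))
        run <- 0L
        prev <- m
      }
      run <- run + (len - prev)
      qp <- qp + len
    } else if (t$op == "I") {
      qp <- qp + t$len
    } else {
      parts <- c(parts, as.character(run),
                 paste0("^", rawToChar(refr[(t$ref_start + 1L):t$ref_end])))
      run <- 0L
    }
  }
  paste0(paste(parts, collapse = ""), run)
}
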