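# Donor genome construction: the donor differs from the reference by
# injected SNVs, insertions (sequence missing from the reference) and
# deletions, plus an expanded collapsed-repeat unit. Every event is
# recorded in a truth table with canonical (left-aligned) placement.

# genomic context of a 0-based breakpoint
breakpoint_context <- function(genes, chrom, pos) {
  for (g in genes) {
    if (g$chrom != chrom || pos < g$start || pos >= g$end) next
    inside_exon <- any(pos >= g$exons$start & pos < g$exons$end)
    if (inside_exon && isTRUE(g$coding)) return("coding_exon")
    return("intron")
  }
  "intergenic"
}

# sample event positions uniformly over allowed space with pairwise spacing
sample_positions <- function(n, allowed_ir, existing, spacing, max_tries = 20000L) {
  pos <- integer(0)
  tries <- 0L
  widths <- IRanges::width(allowed_ir)
  starts <- IRanges::start(allowed_ir)
  cum <- cumsum(widths)
  total <- cum[length(cum)]
  while (length(pos) < n && tries < max_tries) {
    tries <- tries + 1L
    u <- sample.int(total, 1L)
    k <- which(u <= cum)[1L]
    p <- starts[k] + (u - c(0L, cum)[k]) - 1L  # 0-based position
    if (all(abs(p - c(pos, existing)) >= spacing)) pos <- c(pos, p)
  }
  if (length(pos) < n) stopf("could not place %d events with %d bp spacing", n, spacing)
  sort(pos)
}

#' Derive a donor genome and truth tables from a reference
#'
#' Injects the configured SNVs, insertions and deletions into unique or
#' genic sequence (never into annotated repeats, blocked clusters or the
#' collapsed unit), expands the collapsed-repeat unit to k tandem copies,
#' and records every event with canonical left-aligned reference
#' breakpoints, genomic context and the expected detection regime
#' ("cigar" for insertions no longer than \code{max_cigar_insertion},
#' "clip" otherwise).
#'
#' @param reference An \code{lra_reference}.
#' @param config The same \code{\link{simulation_config}}.
#' @return An \code{lra_donor}: list(seqs, blocks, truth, reference). The
#'   blocks table maps donor intervals to reference intervals
#'   (type match | ins | collapsed_ins).
#' @export
make_donor <- function(reference, config) {
  set.seed(config$seed + 1000L)
  vs <- config$variants
  truth <- list()
  events <- list()  # per chromosome: pos-sorted INS/DEL events driving the rebuild
  eid <- 0L
  for (chrom in names(reference$seqs)) {
    glen <- nchar(reference$seqs[[chrom]])
    refseq <- reference$seqs[[chrom]]
    edge <- 5000L
    # allowed = chromosome minus repeats/collapsed/edges
    excl <- reference$repeats[reference$repeats$chrom == chrom, , drop = FALSE]
    excl_ir <- as_iranges0(excl$start, excl$end)
    if (!is.null(reference$collapsed) && reference$collapsed$chrom == chrom) {
      excl_ir <- c(excl_ir, as_iranges0(reference$collapsed$start - edge,
                                        reference$collapsed$end + edge))
    }
    allowed <- IRanges::setdiff(as_iranges0(edge, glen - edge),
                                IRanges::reduce(excl_ir + vs$min_spacing))
    n_chrom <- length(reference$seqs)
    frac <- glen / sum(nchar(reference$seqs))
    n_ins <- if (n_chrom == 1L) vs$n_ins else round(vs$n_ins * frac)
    n_del <- if (n_chrom == 1L) vs$n_del else round(vs$n_del * frac)
    n_snv <- if (n_chrom == 1L) vs$n_snv else round(vs$n_snv * frac)
    pos_all <- sample_positions(n_ins + n_del + n_snv, allowed, integer(0), vs$min_spacing)
    roles <- sample(rep(c("INS", "DEL", "SNV"), c(n_ins, n_del, n_snv)))
    ev_chrom <- list()
    for (i in seq_along(pos_all)) {
      p <- pos_all[i]
      eid <- eid + 1L
      id <- sprintf("var%04d", eid)
      if (roles[i] == "SNV") {
        rb <- substr(refseq, p + 1L, p + 1L)
        ab <- other_base(rb)
        truth[[eid]] <- data.frame(id = id, type = "SNV", chrom = chrom, pos = p,
                                   size = 1L, ref = rb, alt = ab,
                                   context = breakpoint_context(reference$genes, chrom, p),
                                   regime = NA_character_, stringsAsFactors = FALSE)
        ev_chrom[[length(ev_chrom) + 1L]] <- list(type = "SNV", pos = p, alt = ab, id = id)
      } else if (roles[i] == "INS") {
        lr <- log(vs$ins_size_range)
        size <- as.integer(round(exp(runif(1L, lr[1], lr[2]))))
        seq <- random_dna(size)
        la <- left_align_insertion(refseq, p, seq)
        truth[[eid]] <- data.frame(id = id, type = "INS", chrom = chrom, pos = la$pos,
                                   size = size, ref = "", alt = la$seq,
                                   context = breakpoint_context(reference$genes, chrom, la$pos),
                                   regime = if (size <= config$aligner$max_cigar_insertion)
                                     "cigar" else "clip", stringsAsFactors = FALSE)
        ev_chrom[[length(ev_chrom) + 1L]] <- list(type = "INS", pos = la$pos,
                                                  seq = la$seq, id = id)
      } else {
        lr <- log(vs$del_size_range)
        size <- as.integer(round(exp(runif(1L, lr[1], lr[2]))))
        la <- left_align_deletion(refseq, p, size)
        truth[[eid]] <- data.frame(id = id, type = "DEL", chrom = chrom, pos = la$start,
                                   size = size, ref = la$seq, alt = "",
                                   context = breakpoint_context(reference$genes, chrom, la$start),
                                   regime = NA_character_, stringsAsFactors = FALSE)
        ev_chrom[[length(ev_chrom) + 1L]] <- list(type = "DEL", pos = la$start,
                                                  len = size, id = id)
      }
    }
    # collapsed repeat: expansion to k copies, modelled as an insertion of
    # (k-1) extra unit copies immediately after the single reference copy
    if (!is.null(reference$collapsed) && reference$collapsed$chrom == chrom &&
        !is.null(config$collapsed) && config$collapsed$k > 1L) {
      eid <- eid + 1L
      k <- config$collapsed$k
      unit <- reference$collapsed$unit
      truth[[eid]] <- data.frame(id = "collapsed", type = "COLLAPSED", chrom = chrom,
                                 pos = reference$collapsed$end,
                                 size = (k - 1L) * nchar(unit), ref = "",
                                 alt = "", context = "intergenic",
                                 regime = NA_character_, stringsAsFactors = FALSE)
      ev_chrom[[length(ev_chrom) + 1L]] <- list(type = "COLLAPSED",
                                                pos = reference$collapsed$end,
                                                seq = strrep(unit, k - 1L),
                                                id = "collapsed")
    }
    ev_chrom <- ev_chrom[order(vapply(ev_chrom, `[[`, numeric(1), "pos"))]
    events[[chrom]] <- ev_chrom
  }

  # rebuild each chromosome and the donor<->reference block map
  donor <- character(0)
  blocks <- list()
  for (chrom in names(reference$seqs)) {
    refraw <- charToRaw(reference$seqs[[chrom]])
    glen <- length(refraw)
    parts <- list()
    rp <- 0L; dp <- 0L
    for (ev in events[[chrom]]) {
      if (ev$type == "SNV") next  # applied in place below
      if (ev$pos > rp) {
        len <- ev$pos - rp
        parts[[length(parts) + 1L]] <- list(kind = "match", ref = c(rp, ev$pos),
                                            donor = c(dp, dp + len))
        dp <- dp + len; rp <- ev$pos
      }
      if (ev$type %in% c("INS", "COLLAPSED")) {
        len <- nchar(ev$seq)
        parts[[length(parts) + 1L]] <- list(
          kind = if (ev$type == "COLLAPSED") "collapsed_ins" else "ins",
          ref = c(rp, rp), donor = c(dp, dp + len), seq = ev$seq, id = ev$id)
        dp <- dp + len
      } else if (ev$type == "DEL") {
        rp <- rp + ev$len
      }
    }
    if (rp < glen) {
      parts[[length(parts) + 1L]] <- list(kind = "match", ref = c(rp, glen),
                                          donor = c(dp, dp + glen - rp))
      dp <- dp + glen - rp
    }
    pieces <- vapply(parts, function(p) {
      if (p$kind == "match") rawToChar(refraw[(p$ref[1] + 1L):p$ref[2]]) else p$seq
    }, character(1))
    dseq <- paste(pieces, collapse = "")
    draw <- charToRaw(dseq)
    # SNVs applied in donor coordinates through the block offsets
    btab <- do.call(rbind, lapply(parts, function(p) {
      data.frame(chrom = chrom, type = p$kind, ref_start = p$ref[1], ref_end = p$ref[2],
                 donor_start = p$donor[1], donor_end = p$donor[2],
                 event_id = if (is.null(p$id)) NA_character_ else p$id,
                 stringsAsFactors = FALSE)
    }))
    for (ev in events[[chrom]]) {
      if (ev$type != "SNV") next
      d <- lift_to_donor(btab, ev$pos)
      draw[d + 1L] <- charToRaw(ev$alt)
    }
    donor[[chrom]] <- rawToChar(draw)
    blocks[[chrom]] <- btab
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(0), type = character(0), chrom = character(0),
               pos = integer(0), size = integer(0), ref = character(0),
               alt = character(0), context = character(0), regime = character(0))
  structure(list(seqs = donor, blocks = do.call(rbind, blocks), truth = truth,
                 reference = reference, config = config),
            class = "lra_donor")
}

# lift a reference position to donor coordinates (must fall in a match block)
lift_to_donor <- function(btab, pos) {
  m <- btab[btab$type == "match" & btab$ref_start <= pos & pos < btab$ref_end, , drop = FALSE]
  if (nrow(m) == 0L) stopf("position %d not liftable to donor coordinates", pos)
  m$donor_start[1L] + (pos - m$ref_start[1L])
}

# lift a reference interval [s, e) to donor coordinates; the interval must be
# contained in one match block (holds for all annotated features by design)
lift_interval_to_donor <- function(btab, start, end) {
  m <- btab[btab$type == "match" & btab$ref_start <= start & end <= btab$ref_end, , drop = FALSE]
  if (nrow(m) == 0L) return(NULL)
  off <- m$donor_start[1L] - m$ref_start[1L]
  c(start + off, end + off)
}
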