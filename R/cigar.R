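# CIGAR / MD machinery. All positions 0-based half-open.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
READ_OPS <- c("M", "I", "S", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string, e.g. \code{"10S90M2I50M"}.
#' @return data.frame with columns op (character) and len (integer).
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(data.frame(op = character(0), len = integer(0)))
  }
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(cigar)) {
    stopf("invalid CIGAR string: %s", cigar)
  }
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

#' Read/reference lengths consumed by a parsed CIGAR
#'
#' @param ops data.frame from \code{\link{parse_cigar}}.
#' @return Total bases consumed on the read (M/I/S/=/X) or on the
#'   reference (M/D/N/=/X).
#' @export
cigar_read_length <- function(ops) sum(ops$len[ops$op %in% READ_OPS])

#' @rdname cigar_read_length
#' @export
cigar_ref_length <- function(ops) sum(ops$len[ops$op %in% REF_OPS])

#' Walk a CIGAR string into aligned-segment events
#'
#' Decomposes one alignment record into its match blocks, insertions,
#' deletions and soft clips, each with both reference and read coordinates
#' (0-based half-open). The order of events follows the CIGAR.
#'
#' @param record One row of a SAM record data.frame as returned by
#'   \code{\link{read_sam}} (needs chrom, ref_start, cigar, seq).
#' @return data.frame with columns event (match|insertion|deletion|soft_clip),
#'   ref_start, ref_end, read_start, read_end, seq (inserted or clipped
#'   sequence, NA otherwise), side (left|right for soft clips).
#' @export
cigar_walk <- function(record) {
  ops <- parse_cigar(record$cigar)
  if (any(ops$op == "H") && !is.na(record$seq) && record$seq != "*") {
    hp <- which(ops$op == "H")
    # hard clips must sit at the ends and carry no stored sequence; a SEQ whose
    # length includes hard-clipped bases is malformed
    if (cigar_read_length(ops) != nchar(record$seq)) {
      stopf("record %s: hard-clipped bases present in stored sequence", record$read_id)
    }
    if (any(hp != 1L & hp != nrow(ops))) stopf("record %s: internal H op", record$read_id)
  }
  rp <- as.integer(record$ref_start)
  qp <- 0L
  n <- nrow(ops)
  ev <- vector("list", n)
  for (i in seq_len(n)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      ev[[i]] <- list("match", rp, rp + len, qp, qp + len, NA_character_, NA_character_)
      rp <- rp + len; qp <- qp + len
    } else if (op == "I") {
      ev[[i]] <- list("insertion", rp, rp, qp, qp + len,
                      substr(record$seq, qp + 1L, qp + len), NA_character_)
      qp <- qp + len
    } else if (op %in% c("D", "N")) {
      ev[[i]] <- list("deletion", rp, rp + len, qp, qp, NA_character_, NA_character_)
      rp <- rp + len
    } else if (op == "S") {
      side <- if (qp == 0L) "left" else "right"
      ev[[i]] <- list("soft_clip", rp, rp, qp, qp + len,
                      substr(record$seq, qp + 1L, qp + len), side)
      qp <- qp + len
    } # H and P consume nothing
  }
  ev <- ev[!vapply(ev, is.null, logical(1))]
  out <- do.call(rbind, lapply(ev, function(e) {
    data.frame(event = e[[1]], ref_start = e[[2]], ref_end = e[[3]],
               read_start = e[[4]], read_end = e[[5]], seq = e[[6]], side = e[[7]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(event = character(0), ref_start = integer(0), ref_end = integer(0),
                      read_start = integer(0), read_end = integer(0),
                      seq = character(0), side = character(0))
  }
  out
}

# tokenize an MD tag into a list of (kind = match_run | mismatch | deletion)
parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))[[1]]
  if (paste(toks, collapse = "") != md) stopf("invalid MD tag: %s", md)
  toks
}

#' Extract substitutions from a record's MD tag
#'
#' Walks the MD tag alongside the CIGAR match blocks to locate every
#' substituted base in both reference and read coordinates. MD deletion
#' runs are cross-checked against CIGAR D ops; any inconsistency flags
#' the record.
#'
#' @param record One SAM record row with an \code{md} field.
#' @return data.frame with columns ref_pos, read_pos (0-based), ref_base,
#'   read_base. Substitutions where the read base is N are dropped.
#' @export
md_to_substitutions <- function(record) {
  empty <- data.frame(ref_pos = integer(0), read_pos = integer(0),
                      ref_base = character(0), read_base = character(0))
  if (is.null(record$md) || is.na(record$md)) stopf("record %s: MD tag absent", record$read_id)
  ops <- parse_cigar(record$cigar)
  # aligned columns in CIGAR order: M advances both, D advances ref only
  toks <- parse_md(record$md)
  rp <- as.integer(record$ref_start); qp <- 0L
  oi <- 1L; off <- 0L  # position within current op
  n_ops <- nrow(ops)
  advance_to_aligned <- function() {
    repeat {
      if (oi > n_ops) return(invisible())
      op <- ops$op[oi]
      if (op %in% c("M", "=", "X", "D")) {
        if (off < ops$len[oi]) return(invisible())
        oi <<- oi + 1L; off <<- 0L
      } else {
        if (op %in% c("I", "S")) qp <<- qp + ops$len[oi]
        oi <<- oi + 1L; off <<- 0L
      }
    }
  }
  step <- function(k, is_del) {
    # advance k aligned columns of the expected kind; returns positions consumed
    while (k > 0L) {
      advance_to_aligned()
      if (oi > n_ops) stopf("record %s: MD tag overruns CIGAR", record$read_id)
      op <- ops$op[oi]
      if (is_del != (op == "D")) {
        stopf("record %s: MD/CIGAR inconsistency (%s vs D-run)", record$read_id, op)
      }
      take <- min(k, ops$len[oi] - off)
      rp <<- rp + take
      if (!is_del) qp <<- qp + take
      off <<- off + take
      k <- k - take
    }
  }
  subs <- list()
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      step(as.integer(t), is_del = FALSE)
    } else if (startsWith(t, "^")) {
      step(nchar(t) - 1L, is_del = TRUE)
    } else {
      advance_to_aligned()
      if (oi > n_ops || ops$op[oi] == "D") {
        stopf("record %s: MD mismatch token inside deletion", record$read_id)
      }
      rb <- substr(record$seq, qp + 1L, qp + 1L)
      subs[[length(subs) + 1L]] <- data.frame(
        ref_pos = rp, read_pos = qp, ref_base = t, read_base = rb,
        stringsAsFactors = FALSE)
      rp <- rp + 1L; qp <- qp + 1L; off <- off + 1L
    }
  }
  out <- if (length(subs)) do.call(rbind, subs) else empty
  # N bases in reads are never counted as substitutions
  out[out$read_base != "N", , drop = FALSE]
}

#' Compute an MD tag by comparing a read to the reference through its CIGAR
#'
#' @param record SAM record row (chrom, ref_start, cigar, seq).
#' @param refseqs Named character vector of reference sequences.
#' @return MD tag string.
#' @export
compute_md <- function(record, refseqs) {
  w <- cigar_walk(record)
  parts <- character(0)
  run <- 0L
  readraw <- charToRaw(record$seq)
  refraw <- charToRaw(refseqs[[record$chrom]])
  for (i in seq_len(nrow(w))) {
    ev <- w$event[i]
    if (ev == "match") {
      len <- w$ref_end[i] - w$ref_start[i]
      if (len == 0L) next
      a <- readraw[(w$read_start[i] + 1L):(w$read_start[i] + len)]
      b <- refraw[(w$ref_start[i] + 1L):(w$ref_start[i] + len)]
      mism <- which(a != b)
      prev <- 0L
      for (m in mism) {
        run <- run + (m - prev - 1L)
        parts <- c(parts, as.character(run), rawToChar(b[m]))
        run <- 0L
        prev <- m
      }
      run <- run + (len - prev)
    } else if (ev == "deletion") {
      parts <- c(parts, as.character(run),
                 paste0("^", substr(refseqs[[record$chrom]], w$ref_start[i] + 1L, w$ref_end[i])))
      run <- 0L
    }
    # insertions and clips are invisible to MD
  }
  paste0(paste(parts, collapse = ""), run)
}
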