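# Long-read simulation: bimodal lengths truncated at 1.5 kb, uniform starts
# along the donor, per-base sequencing errors with end-elevated rates.
# Error events are recorded in donor coordinates so the aligner emulator can
# project every read onto the reference exactly.

#' Simulate long reads from a donor genome
#'
#' Read lengths are drawn from the configured two-component truncated-normal
#' mixture; the read count is the target yield (depth x genome length)
#' divided by the closed-form mixture mean. Fragment starts are uniform
#' along each chromosome, with overhang beyond the chromosome ends truncated
#' (terminal fragments keep at least the minimum read length), so expected
#' depth is uniform out to the chromosome ends. Substitution, insertion and
#' deletion errors are applied at the configured per-base event rates,
#' multiplied by \code{end_multiplier} within the outer \code{end_window}
#' fraction of each read; a configurable fraction of deletion errors is
#' targeted into repeat intervals. Quality strings encode the positional
#' error model.
#'
#' @param donor An \code{lra_donor}.
#' @param config The \code{\link{simulation_config}}.
#' @return list(reads = data.frame(read_id, seq, qual), truth_reads =
#'   data.frame(read_id, chrom, donor_start, donor_end, strand, length),
#'   errors = per-read list of error events (kind, pos, len, seq, alt) in
#'   donor coordinates).
#' @export
simulate_reads <- function(donor, config) {
  set.seed(config$seed + 2000L)
  rd <- config$reads
  if (rd$depth <= 0) stopf("target depth must be positive")
  er <- config$errors
  glen <- nchar(donor$seqs)
  total <- sum(glen)
  mean_len <- mixture_mean_length(rd)
  n_reads <- max(1L, as.integer(round(rd$depth * total / mean_len)))
  lens <- draw_read_lengths(n_reads, rd)
  chroms <- names(donor$seqs)[sample.int(length(glen), n_reads, replace = TRUE,
                                         prob = glen / total)]
  draws <- lapply(setNames(names(donor$seqs), names(donor$seqs)),
                  function(ch) charToRaw(donor$seqs[[ch]]))

  # donor-coordinate repeat intervals for deletion-error targeting
  donor_repeats <- lapply(setNames(names(donor$seqs), names(donor$seqs)), function(ch) {
    rr <- donor$reference$repeats
    rr <- rr[rr$chrom == ch, , drop = FALSE]
    btab <- donor$blocks[donor$blocks$chrom == ch, , drop = FALSE]
    iv <- lapply(seq_len(nrow(rr)), function(i)
      lift_interval_to_donor(btab, rr$start[i], rr$end[i]))
    iv <- iv[!vapply(iv, is.null, logical(1))]
    if (length(iv)) do.call(rbind, iv) else matrix(numeric(0), ncol = 2L)
  })
  # ins/del errors must sit inside match blocks, clear of block boundaries
  match_blocks <- lapply(setNames(names(donor$seqs), names(donor$seqs)), function(ch) {
    b <- donor$blocks[donor$blocks$chrom == ch & donor$blocks$type == "match", , drop = FALSE]
    cbind(b$donor_start, b$donor_end)
  })

  margin <- 5L
  p_tot <- er$snv + er$ins + er$del
  q_core <- if (p_tot > 0) min(40L, as.integer(round(-10 * log10(p_tot)))) else 40L
  q_end <- if (p_tot > 0) min(40L, as.integer(round(-10 * log10(min(1, p_tot * er$end_multiplier)))))
           else 40L

  reads <- vector("list", n_reads)
  truth <- vector("list", n_reads)
  errors <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    ch <- chroms[i]
    min_len <- min(rd$min_len, glen[[ch]])
    L <- min(lens[i], glen[[ch]])
    span <- glen[[ch]] - min_len + 1L + (L - min_len)
    s0 <- sample.int(span, 1L) - 1L - (L - min_len)
    ds <- max(0L, s0)
    de <- min(s0 + L, glen[[ch]])
    strand <- if (runif(1) < 0.5) "+" else "-"
    ev <- sample_read_errors(ds, de, er, margin, donor_repeats[[ch]], match_blocks[[ch]])
    rawread <- draws[[ch]][(ds + 1L):de]
    if (nrow(ev)) {
      for (k in rev(seq_len(nrow(ev)))) {
        off <- ev$pos[k] - ds
        if (ev$kind[k] == "sub") {
          alt <- other_base(rawToChar(rawread[off + 1L]))
          ev$alt[k] <- alt
          rawread[off + 1L] <- charToRaw(alt)
        } else if (ev$kind[k] == "ins") {
          rawread <- append(rawread, charToRaw(ev$seq[k]), after = off)
        } else {
          rawread <- rawread[-((off + 1L):(off + ev$len[k]))]
        }
      }
    }
    Lr <- length(rawread)
    fseq <- rawToChar(rawread)
    oseq <- if (strand == "-") revcomp(fseq) else fseq
    ze <- max(0L, floor(er$end_window * Lr))
    qual <- paste0(strrep(rawToChar(as.raw(33L + q_end)), ze),
                   strrep(rawToChar(as.raw(33L + q_core)), Lr - 2L * ze),
                   strrep(rawToChar(as.raw(33L + q_end)), ze))
    id <- sprintf("read%06d", i)
    reads[[i]] <- list(read_id = id, seq = oseq, qual = qual)
    truth[[i]] <- list(read_id = id, chrom = ch, donor_start = ds, donor_end = de,
                       strand = strand, length = Lr)
    errors[[i]] <- ev
  }
  reads <- data.frame(read_id = vapply(reads, `[[`, character(1), "read_id"),
                      seq = vapply(reads, `[[`, character(1), "seq"),
                      qual = vapply(reads, `[[`, character(1), "qual"),
                      stringsAsFactors = FALSE)
  truth_reads <- data.frame(read_id = reads$read_id,
                            chrom = vapply(truth, `[[`, character(1), "chrom"),
                            donor_start = vapply(truth, function(x) as.integer(x$donor_start), integer(1)),
                            donor_end = vapply(truth, function(x) as.integer(x$donor_end), integer(1)),
                            strand = vapply(truth, `[[`, character(1), "strand"),
                            length = vapply(truth, function(x) as.integer(x$length), integer(1)),
                            stringsAsFactors = FALSE)
  names(errors) <- reads$read_id
  list(reads = reads, truth_reads = truth_reads, errors = errors)
}

# sample error events for one read covering donor [ds, de).
# End zones are the outer end_window fraction (minus a 5 bp boundary margin
# where no event is placed); events are drawn zone-wise so the end
# multiplier shows up in position, not only in count.
sample_read_errors <- function(ds, de, er, margin, repeat_iv, match_iv) {
  empty <- data.frame(kind = character(0), pos = integer(0), len = integer(0),
                      seq = character(0), alt = character(0), stringsAsFactors = FALSE)
  L <- de - ds
  if (L <= 4L * margin || (er$snv + er$ins + er$del) == 0) return(empty)
  ze <- floor(er$end_window * L)
  zeff <- max(0L, ze - margin)
  n_end <- 2L * zeff
  n_core <- (L - 2L * margin) - n_end
  cnt <- function(rate) {
    c(end = rbinom(1L, n_end, min(1, rate * er$end_multiplier)),
      core = rbinom(1L, n_core, rate))
  }
  pos_end <- function(n) {
    if (n == 0L || zeff == 0L) return(integer(0))
    left <- runif(n) < 0.5
    ifelse(left, ds + margin + sample.int(zeff, n, replace = TRUE) - 1L,
           de - margin - sample.int(zeff, n, replace = TRUE))
  }
  pos_core <- function(n) {
    if (n == 0L || n_core <= 0L) return(integer(0))
    ds + margin + zeff + sample.int(n_core, n, replace = TRUE) - 1L
  }
  pos_repeat <- function(n) {
    if (n == 0L) return(integer(0))
    lo <- ds + margin; hi <- de - margin
    if (nrow(repeat_iv)) {
      ov_lo <- pmax(repeat_iv[, 1], lo); ov_hi <- pmin(repeat_iv[, 2], hi)
      ok <- ov_hi > ov_lo
      if (any(ok)) {
        widths <- (ov_hi - ov_lo)[ok]
        j <- sample.int(sum(ok), n, replace = TRUE, prob = widths)
        return(as.integer(ov_lo[ok][j] + floor(runif(n) * widths[j])))
      }
    }
    pos_core(n)
  }
  nsub <- cnt(er$snv); nins <- cnt(er$ins); ndel <- cnt(er$del)
  n_del_rep <- rbinom(1L, sum(ndel), er$del_repeat_frac)
  ndel_free <- sum(ndel) - n_del_rep
  ndf_end <- min(ndel[["end"]], ndel_free)
  # (kind, zone) schedule; positions are placed with retries so that the
  # separation and block constraints do not thin the realized event counts
  kinds <- c(rep("sub", sum(nsub)), rep("ins", sum(nins)), rep("del", sum(ndel)))
  zones <- c(rep(c("end", "core"), nsub), rep(c("end", "core"), nins),
             rep("end", ndf_end), rep("core", ndel_free - ndf_end),
             rep("repeat", n_del_rep))
  if (length(kinds) == 0L) return(empty)
  sizes <- ifelse(kinds == "sub", 1L,
                  pmin(8L, 1L + stats::rgeom(length(kinds), er$indel_size_p)))
  acc_pos <- integer(0)
  rows <- vector("list", length(kinds))
  n_acc <- 0L
  for (k in seq_along(kinds)) {
    ok_pos <- NA_integer_
    for (try in 1:50) {
      p <- switch(zones[k], end = pos_end(1L), core = pos_core(1L),
                  "repeat" = pos_repeat(1L))
      if (length(p) == 0L) break
      if (length(acc_pos) && any(abs(p - acc_pos) < 10L)) next
      span_end <- p + (if (kinds[k] == "del") sizes[k] else 0L)
      if (span_end > de - margin) next
      if (kinds[k] != "sub" && nrow(match_iv) &&
          !any(match_iv[, 1] + 2L <= p & span_end <= match_iv[, 2] - 2L)) next
      ok_pos <- as.integer(p)
      break
    }
    if (is.na(ok_pos)) next
    acc_pos <- c(acc_pos, ok_pos)
    n_acc <- n_acc + 1L
    rows[[n_acc]] <- data.frame(kind = kinds[k], pos = ok_pos, len = sizes[k],
                                seq = if (kinds[k] == "ins") random_dna(sizes[k])
                                      else NA_character_,
                                alt = NA_character_, stringsAsFactors = FALSE)
  }
  if (n_acc == 0L) return(empty)
  ev <- do.call(rbind, rows[seq_len(n_acc)])
  ev <- ev[order(ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
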