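#' Build a repeat-structured toy reference genome
#'
#' Assembles each chromosome from unique background sequence interleaved
#' with (a) interspersed repeat copies of each configured class, (b) tandem
#' clusters of a single short unit with cluster lengths both below and above
#' the preassembly-blocker threshold, (c) exactly one copy of the
#' collapsed-repeat unit, and (d) gene models with exons and introns placed
#' in unique sequence. Repeat and gene annotations are returned alongside.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return An object of class \code{lra_reference}: list(seqs, repeats,
#'   genes, collapsed, config).
#' @export
build_reference <- function(config) {
  set.seed(config$seed)
  seqs <- character(0)
  repeats <- list()
  genes <- list()
  collapsed <- NULL
  gene_counter <- 0L

  # consensus unit per interspersed class, shared across chromosomes
  isp <- config$repeats$interspersed
  isp_units <- if (!is.null(isp) && nrow(isp)) {
    setNames(vapply(isp$unit_len, random_dna, character(1)), isp$class)
  } else character(0)

  for (chrom in names(config$genome_length)) {
    glen <- as.integer(config$genome_length[[chrom]])
    feats <- list()
    if (!is.null(isp) && nrow(isp)) {
      for (i in seq_len(nrow(isp))) {
        for (k in seq_len(isp$copies[i])) {
          feats[[length(feats) + 1L]] <- list(kind = "repeat", class = isp$class[i],
                                              seq = isp_units[[isp$class[i]]], unit = NA_character_)
        }
      }
    }
    for (td in config$repeats$tandem) {
      unit <- td$unit
      if (is.null(unit)) unit <- random_dna(td$unit_len)
      for (len in td$lengths) {
        if (len < 2L * nchar(unit)) stopf("tandem cluster of %d bp shorter than two units", len)
        s <- substr(strrep(unit, ceiling(len / nchar(unit))), 1L, len)
        feats[[length(feats) + 1L]] <- list(kind = "tandem", class = td$class,
                                            seq = s, unit = unit)
      }
    }
    if (!is.null(config$collapsed) && chrom == names(config$genome_length)[1L]) {
      feats[[length(feats) + 1L]] <- list(kind = "collapsed", class = NA_character_,
                                          seq = random_dna(config$collapsed$unit_len),
                                          unit = NA_character_)
    }
    gn <- config$genes
    if (!is.null(gn) && gn$n > 0L) {
      n_genes <- if (length(names(config$genome_length)) == 1L) gn$n else
        max(1L, round(gn$n * glen / sum(config$genome_length)))
      for (g in seq_len(n_genes)) {
        ne <- sample(gn$n_exons[1]:gn$n_exons[2], 1L)
        el <- sample(gn$exon_len[1]:gn$exon_len[2], ne, replace = TRUE)
        il <- if (ne > 1L) sample(gn$intron_len[1]:gn$intron_len[2], ne - 1L, replace = TRUE) else integer(0)
        # exon coordinates relative to gene start
        starts <- cumsum(c(0L, el[-ne] + il))
        feats[[length(feats) + 1L]] <- list(kind = "gene", class = NA_character_,
                                            seq = random_dna(sum(el) + sum(il)),
                                            unit = NA_character_,
                                            exon_start = starts, exon_end = starts + el)
      }
    }
    feat_total <- sum(vapply(feats, function(f) nchar(f$seq), integer(1)))
    min_gap <- 2000L
    n_gap <- length(feats) + 1L
    bg_total <- glen - feat_total
    if (bg_total < n_gap * min_gap) {
      stopf("chromosome %s: requested repeat/gene content (%d bp) exceeds genome length %d",
            chrom, feat_total + n_gap * min_gap, glen)
    }
    feats <- feats[sample.int(length(feats))]
    prop <- runif(n_gap, 0.5, 1.5)
    extra <- bg_total - n_gap * min_gap
    gaps <- min_gap + floor(prop / sum(prop) * extra)
    gaps[n_gap] <- bg_total - sum(gaps[-n_gap])
    parts <- character(2L * length(feats) + 1L)
    pos <- 0L
    pi_ <- 1L
    for (i in seq_along(feats)) {
      parts[pi_] <- random_dna(gaps[i]); pos <- pos + gaps[i]; pi_ <- pi_ + 1L
      f <- feats[[i]]
      fl <- nchar(f$seq)
      if (f$kind %in% c("repeat", "tandem")) {
        repeats[[length(repeats) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + fl, repeat_class = f$class,
          unit = if (is.na(f$unit)) NA_character_ else f$unit, stringsAsFactors = FALSE)
      } else if (f$kind == "collapsed") {
        collapsed <- list(chrom = chrom, start = pos, end = pos + fl, unit = f$seq)
      } else if (f$kind == "gene") {
        gene_counter <- gene_counter + 1L
        genes[[length(genes) + 1L]] <- list(
          gene_id = sprintf("gene%03d", gene_counter), chrom = chrom,
          strand = sample(c("+", "-"), 1L),
          start = pos, end = pos + fl,
          coding = TRUE,
          exons = data.frame(start = pos + f$exon_start, end = pos + f$exon_end))
      }
      parts[pi_] <- f$seq; pos <- pos + fl; pi_ <- pi_ + 1L
    }
    parts[pi_] <- random_dna(gaps[n_gap])
    seqs[[chrom]] <- paste(parts, collapse = "")
    stopifnot(nchar(seqs[[chrom]]) == glen)
  }
  repeats <- if (length(repeats)) do.call(rbind, repeats) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               repeat_class = character(0), unit = character(0))
  structure(list(seqs = seqs, repeats = repeats, genes = genes,
                 collapsed = collapsed, config = config),
            class = "lra_reference")
}

# tandem clusters longer than the blocker threshold (the preassembly blockers)
blocked_clusters <- function(reference) {
  r <- reference$repeats
  thr <- reference$config$aligner$blocker_threshold
  r[!is.na(r$unit) & (r$end - r$start) > thr, , drop = FALSE]
}
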