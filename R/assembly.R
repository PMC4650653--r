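# Reference-based contig assessment: N50/L50 statistics, misassembly
# classification (relocation / translocation / inversion), NA50/LA50 after
# breaking contigs at misassembly junctions, duplication ratio, per-100 kb
# variant rates and unaligned-contig accounting. Input is a block-level
# alignment table (one row per aligned block), not a live aligner.

#' Contig summary statistics
#'
#' N50 is the length of the contig at which half the total assembly size is
#' contained in contigs that long or longer; L50 its rank in the
#' descending-length ordering.
#'
#' @param seqs Named character vector of contig sequences, or a numeric
#'   vector of contig lengths (GC\% reported as NA then).
#' @return list(count, total, largest, n50, l50, gc).
#' @export
contig_stats <- function(seqs) {
  if (length(seqs) == 0L) stopf("empty contig set")
  lens <- if (is.character(seqs)) nchar(seqs) else as.numeric(seqs)
  s <- sort(lens, decreasing = TRUE)
  csum <- cumsum(as.numeric(s))
  l50 <- which(csum >= sum(as.numeric(s)) / 2)[1L]
  gc <- if (is.character(seqs)) {
    all <- paste(seqs, collapse = "")
    100 * (nchar(gsub("[^GC]", "", all)) / nchar(all))
  } else NA_real_
  list(count = length(lens), total = sum(lens), largest = max(lens),
       n50 = unname(s[l50]), l50 = l50, gc = gc)
}

#' Read a block-level contig alignment table
#'
#' Tab-separated columns: contig, contig_start, contig_end, chrom,
#' ref_start, ref_end, strand, identity and optionally snvs, short_indels,
#' long_indels per block. Coordinates 0-based half-open.
#'
#' @param path TSV path.
#' @return data.frame of alignment blocks.
#' @export
read_alignment_blocks <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("contig", "contig_start", "contig_end", "chrom", "ref_start",
            "ref_end", "strand", "identity")
  if (!all(need %in% names(tb))) {
    stopf("alignment block table missing columns: %s",
          paste(setdiff(need, names(tb)), collapse = ", "))
  }
  for (cc in c("snvs", "short_indels", "long_indels")) {
    if (is.null(tb[[cc]])) tb[[cc]] <- 0L
  }
  tb
}

#' Convert PAF records to the block table
#'
#' Uses columns 1-12 of a PAF file (minimap2-style); identity is matched
#' bases over block length.
#'
#' @param path PAF path.
#' @return data.frame of alignment blocks.
#' @export
paf_to_blocks <- function(path) {
  f <- strsplit(readLines(path), "\t", fixed = TRUE)
  do.call(rbind, lapply(f, function(x) {
    data.frame(contig = x[1], contig_start = as.integer(x[3]),
               contig_end = as.integer(x[4]), chrom = x[6],
               ref_start = as.integer(x[8]), ref_end = as.integer(x[9]),
               strand = x[5],
               identity = as.numeric(x[10]) / max(1, as.numeric(x[11])),
               snvs = 0L, short_indels = 0L, long_indels = 0L,
               stringsAsFactors = FALSE)
  }))
}

#' Classify misassembly events from adjacent alignment blocks
#'
#' For each pair of blocks adjacent on the contig: different chromosomes
#' give a translocation; same chromosome on opposite strands an inversion;
#' same chromosome and strand with a reference discontinuity of at least
#' \code{min_gap} bp relative to the contig-coordinate step a relocation.
#'
#' @param blocks Alignment block data.frame (see
#'   \code{\link{read_alignment_blocks}}).
#' @param min_gap Relocation discontinuity threshold (bp, default 1000).
#' @return data.frame contig, junction (index of the left block), type
#'   (relocation | translocation | inversion), distance.
#' @export
classify_misassemblies <- function(blocks, min_gap = 1000L) {
  out <- list()
  for (ctg in unique(blocks$contig)) {
    b <- blocks[blocks$contig == ctg, , drop = FALSE]
    b <- b[order(b$contig_start), , drop = FALSE]
    if (nrow(b) < 2L) next
    for (j in seq_len(nrow(b) - 1L)) {
      a <- b[j, ]; nxt <- b[j + 1L, ]
      if (a$chrom != nxt$chrom) {
        type <- "translocation"; dist <- NA_real_
      } else if (a$strand != nxt$strand) {
        type <- "inversion"; dist <- NA_real_
      } else {
        contig_step <- nxt$contig_start - a$contig_end
        ref_step <- if (a$strand == "+") nxt$ref_start - a$ref_end
                    else a$ref_start - nxt$ref_end
        dist <- abs(ref_step - contig_step)
        type <- if (dist >= min_gap) "relocation" else NA_character_
      }
      if (!is.na(type)) {
        out[[length(out) + 1L]] <- data.frame(contig = ctg, junction = j,
                                              type = type, distance = dist,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(0), junction = integer(0), type = character(0),
               distance = numeric(0))
}

#' Alignment-based assembly metrics
#'
#' Genome coverage is the union of aligned reference intervals over the
#' genome length; duplication ratio is total aligned contig bases over
#' covered reference bases; NA50/LA50 are N50/L50 after breaking each
#' contig at its misassembly junctions; variant rates are per 100 kb of
#' aligned contig bases.
#'
#' @param blocks Alignment block data.frame.
#' @param contig_lengths Named integer vector of all contig lengths
#'   (including unaligned contigs).
#' @param refseqs Named character vector of reference sequences.
#' @param repeats,genes Optional annotation for target-space coverage.
#' @param min_gap Relocation threshold passed to the classifier.
#' @param unaligned_min_frac Contigs with a smaller aligned fraction count
#'   as partially unaligned.
#' @return list of metrics (see fields).
#' @export
alignment_metrics <- function(blocks, contig_lengths, refseqs, repeats = NULL,
                              genes = NULL, min_gap = 1000L,
                              unaligned_min_frac = 0.5) {
  glen <- sum(nchar(refseqs))
  cov_bases <- 0
  for (ch in unique(blocks$chrom)) {
    bb <- blocks[blocks$chrom == ch, , drop = FALSE]
    cov_bases <- cov_bases + sum(IRanges::width(IRanges::reduce(
      as_iranges0(bb$ref_start, bb$ref_end))))
  }
  aligned_contig_bases <- sum(blocks$contig_end - blocks$contig_start)
  dup <- if (cov_bases > 0) aligned_contig_bases / cov_bases else NA_real_
  mis <- classify_misassemblies(blocks, min_gap = min_gap)
  # break contigs at misassembly junctions; piece length = contiguous
  # contig span of the block run between breaks
  pieces <- numeric(0)
  for (ctg in unique(blocks$contig)) {
    b <- blocks[blocks$contig == ctg, , drop = FALSE]
    b <- b[order(b$contig_start), , drop = FALSE]
    brk <- mis$junction[mis$contig == ctg]
    grp <- cumsum(c(1L, as.integer(seq_len(nrow(b) - 1L) %in% brk)))
    for (g in split(seq_len(nrow(b)), grp)) {
      pieces <- c(pieces, b$contig_end[g[length(g)]] - b$contig_start[g[1L]])
    }
  }
  na_stats <- if (length(pieces)) contig_stats(pieces) else
    list(n50 = NA_real_, l50 = NA_integer_)
  aligned_frac <- vapply(names(contig_lengths), function(ctg) {
    b <- blocks[blocks$contig == ctg, , drop = FALSE]
    if (nrow(b) == 0L) return(0)
    sum(IRanges::width(IRanges::reduce(as_iranges0(b$contig_start, b$contig_end)))) /
      contig_lengths[[ctg]]
  }, numeric(1))
  target_cov <- function(targets) {
    if (is.null(targets) || nrow(targets) == 0L) return(NA_real_)
    iv <- data.frame(chrom = blocks$chrom, start = blocks$ref_start,
                     end = blocks$ref_end, stringsAsFactors = FALSE)
    tot <- sum(vapply(unique(targets$chrom), function(ch)
      sum(IRanges::width(IRanges::reduce(as_iranges0(
        targets$start[targets$chrom == ch], targets$end[targets$chrom == ch])))),
      numeric(1)))
    covered_target_bases(cbind(iv, read_id = "x"), targets) / tot
  }
  gene_targets <- if (is.null(genes) || !length(genes)) NULL else
    data.frame(chrom = vapply(genes, `[[`, character(1), "chrom"),
               start = vapply(genes, function(g) as.integer(g$start), integer(1)),
               end = vapply(genes, function(g) as.integer(g$end), integer(1)),
               stringsAsFactors = FALSE)
  per100 <- function(x) 1e5 * x / max(1, aligned_contig_bases)
  list(genome_coverage = 100 * cov_bases / glen,
       duplication_ratio = dup,
       na50 = na_stats$n50, la50 = na_stats$l50,
       relocations = sum(mis$type == "relocation"),
       translocations = sum(mis$type == "translocation"),
       inversions = sum(mis$type == "inversion"),
       snvs_per_100kb = per100(sum(blocks$snvs)),
       short_indels_per_100kb = per100(sum(blocks$short_indels)),
       long_indels_per_100kb = per100(sum(blocks$long_indels)),
       fully_unaligned = sum(aligned_frac == 0),
       partially_unaligned = sum(aligned_frac > 0 & aligned_frac < unaligned_min_frac),
       repeat_coverage = if (is.null(repeats)) NA_real_ else 100 * target_cov(repeats),
       gene_coverage = if (is.null(gene_targets)) NA_real_ else 100 * target_cov(gene_targets),
       misassemblies = mis)
}

#' Full assembly report in the style of a reference-based QC table
#'
#' @param contigs Named character vector of contig sequences.
#' @param blocks Alignment block data.frame.
#' @param refseqs Named character vector of reference sequences.
#' @param ... Passed to \code{\link{alignment_metrics}}.
#' @return list(stats = \code{\link{contig_stats}} output, metrics =
#'   \code{\link{alignment_metrics}} output).
#' @export
assembly_report <- function(contigs, blocks, refseqs, ...) {
  list(stats = contig_stats(contigs),
       metrics = alignment_metrics(blocks, setNames(nchar(contigs), names(contigs)),
                                   refseqs, ...))
}
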