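# Repeat BED, gene GFF3 and insertion VCF readers/writers.
# BED is 0-based half-open (used unchanged internally); GFF3 and VCF are
# 1-based and converted exactly once at this boundary.

REPEAT_CLASSES <- c("DNA", "LINE", "SINE", "LTR", "RC_Helitron", "Unknown",
                    "Simple", "Satellite", "Low_complexity")

#' Read repeat annotations from a BED file
#'
#' Expects at least 4 columns: chrom, start, end, repeat class. An optional
#' 5th column carries the tandem unit sequence.
#'
#' @param path BED path.
#' @return data.frame chrom, start, end, repeat_class, unit (NA if absent);
#'   coordinates 0-based half-open.
#' @export
read_bed_repeats <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tb) < 4L) stopf("repeat BED %s needs >= 4 columns", path)
  names(tb)[1:4] <- c("chrom", "start", "end", "repeat_class")
  if (ncol(tb) >= 5L) names(tb)[5] <- "unit"
  bad <- !(tb$repeat_class %in% REPEAT_CLASSES)
  if (any(bad)) {
    stopf("unknown repeat class '%s'; allowed: %s", tb$repeat_class[bad][1L],
          paste(REPEAT_CLASSES, collapse = ", "))
  }
  if (any(tb$start >= tb$end)) stopf("BED interval with start >= end in %s", path)
  if (is.null(tb$unit)) tb$unit <- NA_character_
  tb$unit[tb$unit %in% c("", ".")] <- NA_character_
  tb[, c("chrom", "start", "end", "repeat_class", "unit")]
}

#' Write repeat annotations as BED
#' @param repeats data.frame as from \code{\link{read_bed_repeats}}.
#' @param path Output path.
#' @export
write_bed_repeats <- function(repeats, path) {
  unit <- if (is.null(repeats$unit)) rep(NA_character_, nrow(repeats)) else repeats$unit
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", repeats$chrom, repeats$start, repeats$end,
                   repeats$repeat_class, ifelse(is.na(unit), ".", unit))
  writeLines(lines, path)
  invisible(path)
}

#' Convert RepeatMasker .out annotation to the internal repeat BED
#'
#' Maps RepeatMasker class/family strings onto the closed class vocabulary
#' (DNA, LINE, SINE, LTR, RC_Helitron, Unknown, Simple, Satellite,
#' Low_complexity) and converts the 1-based closed coordinates to BED.
#'
#' @param path RepeatMasker .out path.
#' @param bed_path Output BED path.
#' @export
repeatmasker_to_bed <- function(path, bed_path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]  # column-header block
  lines <- trimws(lines[nzchar(trimws(lines))])
  f <- strsplit(lines, "\\s+")
  cls <- vapply(f, `[[`, character(1), 11L)
  map <- function(x) {
    base <- sub("/.*$", "", x)
    switch(base,
           "DNA" = "DNA", "LINE" = "LINE", "SINE" = "SINE", "LTR" = "LTR",
           "RC" = "RC_Helitron",
           "Simple_repeat" = "Simple", "Satellite" = "Satellite",
           "Low_complexity" = "Low_complexity",
           "Unknown")
  }
  out <- data.frame(chrom = vapply(f, `[[`, character(1), 5L),
                    start = as.integer(vapply(f, `[[`, character(1), 6L)) - 1L,
                    end = as.integer(vapply(f, `[[`, character(1), 7L)),
                    repeat_class = vapply(cls, map, character(1)),
                    unit = NA_character_, stringsAsFactors = FALSE)
  write_bed_repeats(out, bed_path)
  invisible(out)
}

#' Read protein-coding gene models from a GFF3 file
#'
#' Uses gene and exon features; exon Parent (or gene_id) attributes link
#' exons to genes. GFF3 1-based closed coordinates become 0-based half-open.
#'
#' @param path GFF3 path.
#' @return list of gene models: each a list(gene_id, chrom, strand, start,
#'   end, exons = data.frame(start, end), coding = TRUE/FALSE).
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) == 9L]
  type <- vapply(f, `[[`, character(1), 3L)
  attr_field <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  genes <- list()
  for (x in f[type == "gene"]) {
    a <- x[9]
    gid <- attr_field(a, "ID")
    genes[[gid]] <- list(gene_id = gid, chrom = x[1], strand = x[7],
                         start = as.integer(x[4]) - 1L, end = as.integer(x[5]),
                         coding = !identical(attr_field(a, "biotype"), "non_coding"),
                         exons = data.frame(start = integer(0), end = integer(0)))
  }
  for (x in f[type == "exon"]) {
    gid <- attr_field(x[9], "Parent")
    if (is.null(genes[[gid]])) next
    genes[[gid]]$exons <- rbind(genes[[gid]]$exons,
                                data.frame(start = as.integer(x[4]) - 1L,
                                           end = as.integer(x[5])))
  }
  for (gid in names(genes)) {
    ex <- genes[[gid]]$exons
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stopf("gene %s: overlapping exons", gid)
    }
    rownames(ex) <- NULL
    genes[[gid]]$exons <- ex
  }
  unname(genes)
}

#' Write gene models as GFF3
#' @param genes List of gene models (see \code{\link{read_gff_genes}}).
#' @param path Output path.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, sprintf("%s\tlongreadaudit\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id,
                              if (isTRUE(g$coding)) "" else ";biotype=non_coding"))
    if (nrow(g$exons)) {
      lines <- c(lines, sprintf("%s\tlongreadaudit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                g$chrom, g$exons$start + 1L, g$exons$end, g$strand, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write recovered insertions as VCF 4.2
#'
#' POS is the 1-based reference base immediately before the breakpoint.
#' Gap-bearing close-breakpoint calls are rendered with a run of 100 N
#' between the two fragments and flagged \code{GAPPED=1}. INFO carries
#' CATEGORY, SUPPORT, CONTEXT, SVLEN and END.
#'
#' @param calls Insertion call data.frame (see
#'   \code{\link{merge_and_annotate}}).
#' @param path Output path.
#' @param refseqs Named character vector of reference sequences (for the
#'   anchor REF base and contig header lines).
#' @export
write_insertions_vcf <- function(calls, path, refseqs) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(refseqs), nchar(refseqs)),
           "##ALT=<ID=INS,Description=\"Insertion relative to the reference\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Insertion size (lower bound if gapped)\">",
           "##INFO=<ID=CATEGORY,Number=1,Type=String,Description=\"Recovery mode\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
           "##INFO=<ID=CONTEXT,Number=1,Type=String,Description=\"Genomic context\">",
           "##INFO=<ID=GAPPED,Number=0,Type=Flag,Description=\"Sequence contains an unknown-length gap\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    pos1 <- cl$breakpoint  # base before the breakpoint, 1-based == 0-based breakpoint
    refbase <- if (pos1 >= 1L) substr(refseqs[[cl$chrom]], pos1, pos1) else "N"
    gapped <- grepl("-", cl$seq, fixed = TRUE)
    altseq <- gsub("-", strrep("N", 100L), cl$seq, fixed = TRUE)
    info <- sprintf("SVLEN=%d;CATEGORY=%s;SUPPORT=%d;CONTEXT=%s%s",
                    cl$size, cl$category, cl$support, cl$context,
                    if (gapped) ";GAPPED" else "")
    rows <- c(rows, sprintf("%s\t%d\tins%d\t%s\t%s\t.\tPASS\t%s",
                            cl$chrom, pos1, i, refbase, paste0(refbase, altseq), info))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
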