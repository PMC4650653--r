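# Pipeline orchestration: simulate -> align -> variants -> insertions ->
# coverage -> repeats -> (validate), writing the TSV/VCF/BED/FASTA report
# bundle. Each stage is a plain function over in-memory objects; this
# wrapper wires them and persists artifacts.

#' Run the simulation stage and return all in-memory objects
#'
#' @param config A \code{\link{simulation_config}}.
#' @return list(reference, donor, sim, aln) with the reference, donor,
#'   simulated reads and emulated alignment records.
#' @export
simulate_dataset <- function(config) {
  reference <- build_reference(config)
  donor <- make_donor(reference, config)
  sim <- simulate_reads(donor, config)
  aln <- emulate_alignment(sim, donor, config)
  list(reference = reference, donor = donor, sim = sim, aln = aln)
}

#' Run the full audit pipeline on a simulated dataset
#'
#' Stages run in dependency order; every threshold used is recorded in the
#' returned object. When \code{outdir} is given, the artifact bundle
#' (reference.fa, donor.fa, reads.fastq, alignments.sam, repeats.bed,
#' genes.gff3, truth tables, variant/insertion/coverage/repeat TSVs and
#' insertions.vcf) is written there.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param outdir Optional output directory.
#' @param validate Also run the short-read validation stage (simulated
#'   donor-derived short reads against the validation contigs).
#' @param long_cutoff Long-indel size cutoff (bp).
#' @param coverage_levels Subsampling depths for recovery rates.
#' @return list with every stage's result (dataset, events, sites, summary,
#'   insertions, depth, gaps, lengths, curves, recovery, enrichment,
#'   clusters, validation).
#' @export
run_pipeline <- function(config, outdir = NULL, validate = TRUE,
                         long_cutoff = 9L, coverage_levels = c(3, 6, 12, 24)) {
  ds <- simulate_dataset(config)
  refseqs <- ds$reference$seqs
  records <- ds$aln$records
  events <- extract_read_variants(records)
  depth <- depth_track(records, refseqs)
  sites <- aggregate_sites(events, depth, refseqs)
  summary <- error_summary(events, records, long_cutoff = long_cutoff)
  ins <- recover_insertions(records, sites, refseqs, ds$reference$genes,
                            min_size = long_cutoff)
  gaps <- extract_gaps(depth)
  tr <- ds$sim$truth_reads
  read_lengths <- setNames(tr$length, tr$read_id)
  lengths <- length_stats(tr$length[tr$read_id %in% records$read_id[records$is_primary]])
  genome_targets <- data.frame(chrom = names(refseqs), start = 0L,
                               end = nchar(refseqs), stringsAsFactors = FALSE)
  curves <- accumulative_coverage(records, read_lengths, genome_targets)
  avail <- depth$mean
  levels_ok <- coverage_levels[coverage_levels <= avail]
  recovery <- if (length(levels_ok) && nrow(ds$reference$repeats))
    recovery_rates(records, refseqs, ds$reference$repeats, ds$reference$genes,
                   coverage_levels = levels_ok, seed = config$seed) else NULL
  enrichment <- gap_enrichment(gaps, ds$reference$repeats, refseqs)
  clusters <- flag_blockers(find_tandem_clusters(refseqs),
                            threshold = config$aligner$blocker_threshold)
  cn <- NULL
  if (!is.null(ds$reference$collapsed)) {
    track_supp <- depth_track(records, refseqs, include_supplementary = TRUE)
    cl <- ds$reference$collapsed
    cn <- copy_number(track_supp, cl$chrom, cl$start, cl$end)
  }
  valid <- NULL
  if (validate && nrow(ins)) {
    vref <- build_validation_reference(ins, refseqs)
    # short reads drawn from the donor carry the inserted sequence, so true
    # insertions accumulate junction coverage on their validation contigs
    srec <- simulate_validation_reads(vref, ds$donor, ins, depth = 30,
                                      seed = config$seed + 5000L)
    valid <- confirm_genomic(vref, srec)
    ins$validation_status[valid$call_index] <- valid$status
  }
  res <- list(config = config, dataset = ds, events = events, sites = sites,
              summary = summary, insertions = ins, depth = depth, gaps = gaps,
              lengths = lengths, curves = curves,
              intersection = intersection_point(curves),
              recovery = recovery, enrichment = enrichment, clusters = clusters,
              copy_number = cn, validation = valid)
  if (!is.null(outdir)) write_bundle(res, outdir)
  res
}

# short reads for validation, emulating mapping of donor-derived reads:
# a contig receives coverage only when its sequence is actually present in
# the donor (checked by a seeded search around the insertion), so spurious
# calls accumulate no junction coverage
simulate_validation_reads <- function(vref, donor, calls, depth = 30,
                                      read_len = 100L, seed = 1L) {
  present <- vapply(seq_len(nrow(vref$info)), function(k) {
    r <- vref$info[k, ]
    ctg <- vref$seqs[[r$contig]]
    j <- if (!is.na(r$junction_left)) r$junction_left else r$junction_right
    lo <- max(1L, j - 24L)
    seed <- substr(ctg, lo, min(nchar(ctg), lo + 47L))
    ch <- calls$chrom[r$call_index]
    length(Biostrings::matchPattern(seed, Biostrings::DNAString(donor$seqs[[ch]]),
                                    max.mismatch = 2L)) > 0L
  }, logical(1))
  keep <- vref$seqs[vref$info$contig[present]]
  if (length(keep) == 0L) {
    return(data.frame(read_id = character(0), flag = integer(0), chrom = character(0),
                      ref_start = integer(0), mapq = integer(0), cigar = character(0),
                      seq = character(0), md = character(0), strand = character(0),
                      is_supplementary = logical(0), is_primary = logical(0)))
  }
  simulate_short_reads(keep, depth = depth, read_len = read_len, seed = seed)
}

write_bundle <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  ds <- res$dataset
  write_fasta(ds$reference$seqs, p("reference.fa"))
  write_fasta(ds$donor$seqs, p("donor.fa"))
  write_fastq(ds$sim$reads, p("reads.fastq"))
  write_sam(ds$aln$records, p("alignments.sam"), refseqs = ds$reference$seqs)
  write_bed_repeats(ds$reference$repeats, p("repeats.bed"))
  write_gff_genes(ds$reference$genes, p("genes.gff3"))
  tsv <- function(d, f) write.table(d, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(ds$donor$truth, "truth_variants.tsv")
  tsv(ds$sim$truth_reads, "truth_reads.tsv")
  tsv(res$events, "per_read_events.tsv")
  tsv(res$sites, "variant_sites.tsv")
  tsv(res$insertions, "insertions.tsv")
  if (nrow(res$insertions)) {
    write_insertions_vcf(res$insertions, p("insertions.vcf"), ds$reference$seqs)
  }
  tsv(res$gaps, "gaps.bed")
  tsv(res$lengths$strata, "length_hist.tsv")
  tsv(res$curves, "accumulative_curves.tsv")
  rl <- setNames(ds$sim$truth_reads$length, ds$sim$truth_reads$read_id)
  tsv(per_chromosome_profile(ds$aln$records, rl, ds$reference$seqs),
      "chromosome_profile.tsv")
  if (!is.null(res$recovery)) tsv(res$recovery$repeats, "recovery_rates.tsv")
  tsv(res$enrichment, "gap_enrichment.tsv")
  tsv(res$clusters, "tandem_clusters.bed")
  prof <- data.frame(window = seq_len(100L), res$summary$profile)
  tsv(prof, "positional_profile.tsv")
  err <- data.frame(metric = c("aligned_bases",
                               paste0("ratio_", c("snv", "ins", "del")),
                               paste0("ratio_bases_", c("snv", "ins", "del"))),
                    value = c(res$summary$aligned_bases, res$summary$ratio,
                              res$summary$ratio_bases))
  tsv(err, "error_summary.tsv")
  invisible(outdir)
}
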