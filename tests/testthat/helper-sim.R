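# Shared fixtures. The demo dataset is built once per test session and
# reused by every module test that needs realistic alignments.

.fixture_cache <- new.env(parent = emptyenv())

# a moderately sized study-like configuration scaled to test runtimes
demo_config <- function(seed = 5L, depth = 15, errors_on = TRUE) {
  simulation_config(
    seed = seed,
    genome_length = c(chrI = 400000L),
    repeats = list(
      interspersed = data.frame(
        class = c("DNA", "LINE", "SINE", "LTR", "RC_Helitron"),
        unit_len = c(300L, 1200L, 300L, 450L, 500L),
        copies = c(8L, 3L, 6L, 3L, 3L), stringsAsFactors = FALSE),
      tandem = list(list(class = "Simple", unit = "TGATA", lengths = c(300L, 2000L)),
                    list(class = "Satellite", unit = NULL, unit_len = 35L,
                         lengths = c(1500L)))),
    collapsed = list(unit_len = 3000L, k = 10L),
    genes = list(n = 8L, n_exons = c(3L, 5L), exon_len = c(100L, 300L),
                 intron_len = c(60L, 300L)),
    variants = list(n_snv = 20L, n_ins = 10L, ins_size_range = c(9L, 800L),
                    n_del = 5L, del_size_range = c(10L, 50L), min_spacing = 3000L),
    reads = list(depth = depth, mix = list(w = c(0.35, 0.65), mu = c(1800, 9800),
                                           sigma = c(800, 1200)), min_len = 1500L),
    errors = if (errors_on)
      list(snv = 1e-4, ins = 2e-4, del = 1e-3, indel_size_p = 0.6,
           end_window = 0.05, end_multiplier = 5, del_repeat_frac = 0.5)
    else list(snv = 0, ins = 0, del = 0, indel_size_p = 0.6,
              end_window = 0.05, end_multiplier = 1, del_repeat_frac = 0))
}

demo_dataset <- function() {
  if (is.null(.fixture_cache$demo)) {
    .fixture_cache$demo <- simulate_dataset(demo_config())
  }
  .fixture_cache$demo
}

demo_analysis <- function() {
  if (is.null(.fixture_cache$analysis)) {
    ds <- demo_dataset()
    events <- extract_read_variants(ds$aln$records)
    depth <- depth_track(ds$aln$records, ds$reference$seqs)
    sites <- aggregate_sites(events, depth, ds$reference$seqs)
    .fixture_cache$analysis <- list(ds = ds, events = events, depth = depth,
                                    sites = sites)
  }
  .fixture_cache$analysis
}

# minimal primary record constructor for hand-built fixtures
mk_record <- function(read_id, chrom, ref_start, cigar, seq, md = NA_character_,
                      flag = 0L) {
  data.frame(read_id = read_id, flag = flag, chrom = chrom,
             ref_start = as.integer(ref_start), mapq = 60L, cigar = cigar,
             seq = seq, md = md,
             strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
             is_supplementary = bitwAnd(flag, 2048L) != 0L,
             is_primary = bitwAnd(flag, 2048L) == 0L && bitwAnd(flag, 256L) == 0L,
             stringsAsFactors = FALSE)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
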