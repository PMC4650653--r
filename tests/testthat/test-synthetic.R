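test_that("reference construction places the configured repeat landscape", {
  cfg <- demo_config(seed = 11)
  ref <- build_reference(cfg)
  expect_equal(nchar(ref$seqs[["chrI"]]), 400000L)
  simple <- ref$repeats[ref$repeats$repeat_class == "Simple", ]
  expect_setequal(simple$end - simple$start, c(300L, 2000L))
  expect_true(all(simple$unit == "TGATA"))
  big <- simple[simple$end - simple$start == 2000L, ]
  expect_equal(substr(ref$seqs[[big$chrom]], big$start + 1L, big$start + 10L),
               "TGATATGATA")
  expect_equal(ref$collapsed$end - ref$collapsed$start, 3000L)
  expect_length(ref$genes, 8L)
  # genes fall in unique sequence: no overlap with any repeat
  for (g in ref$genes) {
    expect_false(any(ref$repeats$start < g$end & ref$repeats$end > g$start &
                       ref$repeats$chrom == g$chrom))
  }
})

test_that("zero-repeat config yields background-only genome, oversized content errors", {
  cfg <- demo_config(seed = 2)
  cfg$repeats <- list(interspersed = NULL, tandem = list())
  cfg$collapsed <- NULL
  cfg$genes$n <- 0L
  ref <- build_reference(cfg)
  expect_equal(nrow(ref$repeats), 0L)
  expect_null(ref$collapsed)

  cfg2 <- demo_config(seed = 2)
  cfg2$genome_length <- c(chrI = 30000L)
  expect_error(build_reference(cfg2), "exceeds genome length")
})

test_that("donor carries the injected events with canonical truth records", {
  an <- demo_analysis()
  ds <- an$ds
  truth <- ds$donor$truth
  ref <- ds$reference$seqs[["chrI"]]
  don <- ds$donor$seqs[["chrI"]]
  expect_equal(nchar(don) - nchar(ref),
               sum(truth$size[truth$type %in% c("INS", "COLLAPSED")]) -
                 sum(truth$size[truth$type == "DEL"]))
  snv <- truth[truth$type == "SNV", ][1, ]
  expect_equal(substr(ref, snv$pos + 1L, snv$pos + 1L), snv$ref)
  expect_false(snv$ref == snv$alt)
  # collapsed repeat expanded to k copies in the donor
  expect_equal(truth$size[truth$type == "COLLAPSED"], (10L - 1L) * 3000L)
  # insertion truth is left-aligned: no further shift possible
  for (i in which(truth$type == "INS")) {
    la <- left_align_insertion(ref, truth$pos[i], truth$alt[i])
    expect_equal(la$pos, truth$pos[i])
  }
})

test_that("zero variant rates give donor identical to reference", {
  cfg <- demo_config(seed = 3, errors_on = FALSE)
  cfg$variants$n_snv <- 0L; cfg$variants$n_ins <- 0L; cfg$variants$n_del <- 0L
  cfg$collapsed <- NULL
  ref <- build_reference(cfg)
  don <- make_donor(ref, cfg)
  expect_identical(don$seqs, ref$seqs)
  expect_equal(nrow(don$truth), 0L)
})

test_that("read count matches the yield expectation from the mixture mean", {
  an <- demo_analysis()
  cfg <- an$ds$reference$config
  expected <- cfg$reads$depth * sum(nchar(an$ds$donor$seqs)) /
    longreadaudit:::mixture_mean_length(cfg$reads)
  expect_lt(abs(nrow(an$ds$sim$reads) - expected) / expected, 0.01)
  expect_true(all(an$ds$sim$truth_reads$donor_end - an$ds$sim$truth_reads$donor_start >=
                    1500L))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- demo_config(seed = 21)
  cfg$genome_length <- c(chrI = 120000L)
  cfg$collapsed <- NULL
  cfg$repeats$tandem <- list(list(class = "Simple", unit = "TGATA", lengths = 300L))
  cfg$repeats$interspersed <- NULL
  cfg$genes$n <- 2L
  cfg$variants$n_snv <- 5L; cfg$variants$n_ins <- 2L; cfg$variants$n_del <- 1L
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$reference$seqs, b$reference$seqs)
  expect_identical(a$donor$truth, b$donor$truth)
  expect_identical(a$sim$reads, b$sim$reads)
  expect_identical(a$aln$records, b$aln$records)
})

test_that("every emitted record conserves read length through the CIGAR", {
  ds <- demo_dataset()
  rec <- ds$aln$records
  mapped <- rec[bitwAnd(rec$flag, 4L) == 0L, ]
  ok <- vapply(seq_len(nrow(mapped)), function(i)
    cigar_read_length(parse_cigar(mapped$cigar[i])) == nchar(mapped$seq[i]),
    logical(1))
  expect_true(all(ok))
  # and the FASTQ read lengths match the truth table
  expect_equal(nchar(ds$sim$reads$seq), ds$sim$truth_reads$length)
})

test_that("error-free reads are exact donor substrings", {
  cfg <- demo_config(seed = 8, errors_on = FALSE)
  cfg$genome_length <- c(chrI = 100000L)
  cfg$repeats <- list(interspersed = NULL, tandem = list())
  cfg$collapsed <- NULL; cfg$genes$n <- 0L
  cfg$variants$n_snv <- 0L; cfg$variants$n_ins <- 0L; cfg$variants$n_del <- 0L
  ds <- simulate_dataset(cfg)
  tr <- ds$sim$truth_reads
  for (i in sample(nrow(tr), 20)) {
    fwd <- if (tr$strand[i] == "-") {
      chartr("ACGT", "TGCA", paste(rev(strsplit(ds$sim$reads$seq[i], "")[[1]]),
                                   collapse = ""))
    } else ds$sim$reads$seq[i]
    expect_identical(fwd, substr(ds$donor$seqs[[tr$chrom[i]]],
                                 tr$donor_start[i] + 1L, tr$donor_end[i]))
  }
})

test_that("aligner emulator applies the insertion regime rules", {
  # constructed donor with one small and one large insertion
  set.seed(77)
  refseq <- random_dna_str(40000)
  cfg <- demo_config(seed = 77, errors_on = FALSE)
  cfg$aligner$max_cigar_insertion <- 100L
  cfg$aligner$min_anchor <- 1000L
  ref <- list(seqs = c(chrI = refseq),
              repeats = data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), repeat_class = character(0),
                                   unit = character(0)),
              genes = list(), collapsed = NULL, config = cfg)
  class(ref) <- "lra_reference"
  small_ins <- random_dna_str(20)
  big_ins <- random_dna_str(800)
  blocks <- data.frame(chrom = "chrI",
                       type = c("match", "ins", "match", "ins", "match"),
                       ref_start = c(0L, 10000L, 10000L, 30000L, 30000L),
                       ref_end = c(10000L, 10000L, 30000L, 30000L, 40000L),
                       donor_start = c(0L, 10000L, 10020L, 30020L, 30820L),
                       donor_end = c(10000L, 10020L, 30020L, 30820L, 40820L),
                       event_id = c(NA, "i1", NA, "i2", NA),
                       stringsAsFactors = FALSE)
  donor_seq <- paste0(substr(refseq, 1, 10000), small_ins,
                      substr(refseq, 10001, 30000), big_ins,
                      substr(refseq, 30001, 40000))
  donor <- structure(list(seqs = c(chrI = donor_seq), blocks = blocks,
                          truth = NULL, reference = ref, config = cfg),
                     class = "lra_donor")
  mkread <- function(id, ds, de) {
    list(reads = data.frame(read_id = id,
                            seq = substr(donor_seq, ds + 1L, de), qual = "",
                            stringsAsFactors = FALSE),
         truth_reads = data.frame(read_id = id, chrom = "chrI", donor_start = ds,
                                  donor_end = de, strand = "+",
                                  length = de - ds, stringsAsFactors = FALSE),
         errors = setNames(list(data.frame()), id))
  }
  # s = 20 with 3 kb flanks -> single record with an I op
  aln1 <- emulate_alignment(mkread("a", 7000L, 13020L), donor, cfg)
  expect_match(aln1$records$cigar, "^3000M20I3000M$")
  # s = 800 with 4 kb / 2 kb flanks -> longer flank aligned, rest soft-clipped
  aln2 <- emulate_alignment(mkread("b", 26020L, 32820L), donor, cfg)
  expect_match(aln2$records$cigar, "^4000M2800S$")
  expect_equal(aln2$records$ref_start, 26000L)
  # small s with a sub-anchor flank also falls back to the clip regime
  aln3 <- emulate_alignment(mkread("c", 9500L, 15020L), donor, cfg)
  expect_match(aln3$records$cigar, "S")
})

test_that("reads inside a blocked tandem cluster are withheld", {
  ds <- demo_dataset()
  cfg <- ds$reference$config
  bc <- longreadaudit:::blocked_clusters(ds$reference)
  expect_true(nrow(bc) >= 2L)
  expect_gt(ds$aln$n_withheld, 0L)
  # every withheld read overlaps a blocked cluster by more than the threshold
  tr <- ds$sim$truth_reads
  wh <- tr[tr$read_id %in% ds$aln$withheld_ids, ]
  btab <- ds$donor$blocks
  for (i in seq_len(nrow(wh))) {
    iv <- do.call(rbind, lapply(seq_len(nrow(bc)), function(j)
      longreadaudit:::lift_interval_to_donor(
        btab[btab$chrom == bc$chrom[j], , drop = FALSE], bc$start[j], bc$end[j])))
    ov <- sum(pmax(0, pmin(iv[, 2], wh$donor_end[i]) - pmax(iv[, 1], wh$donor_start[i])))
    expect_gt(ov, cfg$aligner$blocker_threshold)
  }
})

test_that("realized error rates match configuration within 3 binomial SE", {
  cfg <- demo_config(seed = 13)
  cfg$genome_length <- c(chrI = 300000L)
  cfg$repeats <- list(interspersed = NULL, tandem = list())
  cfg$collapsed <- NULL; cfg$genes$n <- 0L
  cfg$variants$n_snv <- 0L; cfg$variants$n_ins <- 0L; cfg$variants$n_del <- 0L
  cfg$errors$end_multiplier <- 1
  cfg$errors$del_repeat_frac <- 0
  ds <- simulate_dataset(cfg)
  ev <- do.call(rbind, ds$sim$errors)
  total <- sum(ds$sim$truth_reads$donor_end - ds$sim$truth_reads$donor_start)
  map <- c(sub = "snv", ins = "ins", del = "del")
  for (kind in names(map)) {
    p <- cfg$errors[[map[[kind]]]]
    n_obs <- sum(ev$kind == kind)
    se <- sqrt(p * (1 - p) * total)
    expect_lt(abs(n_obs - p * total), 3 * se)
  }
})
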