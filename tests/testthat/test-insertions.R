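insertion_call_row_public <- longreadaudit:::insertion_call_row

# constructed-fixture environment shared by the mode tests
ins_fixture <- local({
  set.seed(99)
  refseq <- random_dna_str(60000)
  ins <- random_dna_str(800)
  bp <- 30000L
  list(refs = c(chrI = refseq), ins = ins, bp = bp)
})

spanning_record <- function(fx, left_flank, right_flank, id = "r1") {
  bp <- fx$bp
  seq <- paste0(substr(fx$refs[["chrI"]], bp - left_flank + 1L, bp), fx$ins,
                substr(fx$refs[["chrI"]], bp + 1L, bp + right_flank))
  mk_record(id, "chrI", bp - left_flank,
            sprintf("%dM%dS", left_flank, nchar(fx$ins) + right_flank), seq,
            md = sprintf("%d", left_flank))
}

partial_record <- function(fx, side, flank, ins_from, ins_to, id) {
  bp <- fx$bp
  part <- substr(fx$ins, ins_from, ins_to)
  if (side == "right") {
    seq <- paste0(substr(fx$refs[["chrI"]], bp - flank + 1L, bp), part)
    mk_record(id, "chrI", bp - flank, sprintf("%dM%dS", flank, nchar(part)), seq,
              md = sprintf("%d", flank))
  } else {
    seq <- paste0(part, substr(fx$refs[["chrI"]], bp + 1L, bp + flank))
    mk_record(id, "chrI", bp, sprintf("%dS%dM", nchar(part), flank), seq,
              md = sprintf("%d", flank))
  }
}

test_that("unaligned ends carry the clip and its breakpoint", {
  fx <- ins_fixture
  ends <- unaligned_ends(spanning_record(fx, 4000L, 2000L))
  expect_equal(nrow(ends), 1L)
  expect_equal(ends$side, "right")
  expect_equal(ends$breakpoint, fx$bp)
  expect_equal(nchar(ends$clip_seq), 2800L)
  # hard-clipped input is refused
  hc <- mk_record("h", "chrI", 0L, "10H50M", random_dna_str(50))
  expect_error(unaligned_ends(hc), "hard-clipped")
})

test_that("within-read promotion applies the size threshold", {
  sites <- data.frame(chrom = "chrI", type = "INS", pos = c(10L, 20L),
                      size = c(12L, 5L), ref = "", alt = c(strrep("G", 12), "GGGGG"),
                      support = 3L, depth = 4L, called = TRUE,
                      read_ids = "a,b,c", stringsAsFactors = FALSE)
  calls <- find_within_read(sites)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$size, 12L)
  expect_equal(calls$category, "within_read")
})

test_that("self-mapped recovery returns the exact insertion from one clip", {
  fx <- ins_fixture
  sm <- find_self_mapped(unaligned_ends(spanning_record(fx, 4000L, 2000L)), fx$refs)
  expect_equal(nrow(sm$calls), 1L)
  expect_equal(sm$calls$breakpoint, fx$bp)
  expect_identical(sm$calls$seq, fx$ins)
  # left-side clip, symmetric
  sm2 <- find_self_mapped(unaligned_ends(
    mk_record("r2", "chrI", fx$bp,
              sprintf("%dS%dM", 2000L + nchar(fx$ins), 4000L),
              paste0(substr(fx$refs[["chrI"]], fx$bp - 2000L + 1L, fx$bp), fx$ins,
                     substr(fx$refs[["chrI"]], fx$bp + 1L, fx$bp + 4000L)),
              md = "4000")), fx$refs)
  expect_equal(nrow(sm2$calls), 1L)
  expect_identical(sm2$calls$seq, fx$ins)
  # a clip of pure novel sequence yields nothing
  novel <- mk_record("r3", "chrI", fx$bp - 3000L, "3000M900S",
                     paste0(substr(fx$refs[["chrI"]], fx$bp - 3000L + 1L, fx$bp),
                            random_dna_str(900)), md = "3000")
  sm3 <- find_self_mapped(unaligned_ends(novel), fx$refs)
  expect_equal(nrow(sm3$calls), 0L)
})

test_that("overlapping clips cross-map, non-overlapping close the breakpoint", {
  fx <- ins_fixture
  recA <- partial_record(fx, "right", 3000L, 1L, 700L, "rA")
  recB <- partial_record(fx, "left", 3000L, 401L, 1000L, "rB")  # truncated at 800
  recB <- partial_record(fx, "left", 3000L, 401L, 800L, "rB")
  pc <- find_breakpoint_pairs(unaligned_ends(rbind(recA, recB)))
  expect_equal(nrow(pc$cross), 1L)
  expect_identical(pc$cross$seq, fx$ins)
  expect_equal(pc$cross$size, 800L)

  recB2 <- partial_record(fx, "left", 3000L, 741L, 800L, "rB2")
  pc2 <- find_breakpoint_pairs(unaligned_ends(rbind(recA, recB2)))
  expect_equal(nrow(pc2$cross), 0L)
  expect_equal(nrow(pc2$close), 1L)
  expect_equal(pc2$close$size, 700L + 60L)
  expect_match(pc2$close$seq, "-")

  # distance rule: breakpoints 50 kb apart never pair
  recFar <- mk_record("far", "chrI", 0L, "2000M500S",
                      paste0(substr(fx$refs[["chrI"]], 1L, 2000L), random_dna_str(500)),
                      md = "2000")
  pc3 <- find_breakpoint_pairs(unaligned_ends(rbind(recFar, recB2)))
  expect_equal(nrow(pc3$cross) + nrow(pc3$close), 0L)

  # an end never pairs with the same read's other end
  both <- mk_record("same", "chrI", fx$bp - 1000L, "500S1000M500S",
                    paste0(random_dna_str(500),
                           substr(fx$refs[["chrI"]], fx$bp - 1000L + 1L, fx$bp),
                           random_dna_str(500)), md = "1000")
  pc4 <- find_breakpoint_pairs(unaligned_ends(both, min_clip_len = 30L))
  expect_equal(nrow(pc4$cross) + nrow(pc4$close), 0L)
})

test_that("merging unifies modes by precedence and annotates context", {
  fx <- ins_fixture
  genes <- list(list(gene_id = "g1", chrom = "chrI", strand = "+",
                     start = fx$bp - 500L, end = fx$bp + 1500L, coding = TRUE,
                     exons = data.frame(start = c(fx$bp - 500L, fx$bp + 1000L),
                                        end = c(fx$bp + 100L, fx$bp + 1500L))))
  calls <- rbind(
    insertion_call_row_public("within_read", "chrI", fx$bp, fx$ins, 800L, c("a", "b")),
    insertion_call_row_public("self_mapped", "chrI", fx$bp, fx$ins, 800L, c("b", "c")))
  m <- merge_and_annotate(calls, genes, fx$refs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$category, "within_read")
  expect_equal(m$support, 3L)
  expect_equal(m$context, "coding_exon")
  # idempotence
  m2 <- merge_and_annotate(m[, names(calls)], genes, fx$refs)
  expect_equal(m2$support, m$support)
  expect_equal(nrow(m2), 1L)
  # intron vs intergenic
  calls_intron <- insertion_call_row_public("self_mapped", "chrI", fx$bp + 500L,
                                            random_dna_str(50), 50L, "x")
  expect_equal(merge_and_annotate(calls_intron, genes, fx$refs)$context, "intron")
  calls_far <- insertion_call_row_public("self_mapped", "chrI", fx$bp + 20000L,
                                         random_dna_str(50), 50L, "x")
  expect_equal(merge_and_annotate(calls_far, genes, fx$refs)$context, "intergenic")
})

test_that("truth recovery on an error-free simulation is exact and unique", {
  cfg <- demo_config(seed = 31, errors_on = FALSE)
  cfg$genome_length <- c(chrI = 250000L)
  cfg$repeats <- list(interspersed = NULL, tandem = list())
  cfg$collapsed <- NULL
  cfg$reads$depth <- 12
  cfg$variants$n_snv <- 0L; cfg$variants$n_del <- 0L
  cfg$variants$n_ins <- 8L; cfg$variants$ins_size_range <- c(9L, 1500L)
  ds <- simulate_dataset(cfg)
  ev <- extract_read_variants(ds$aln$records)
  depth <- depth_track(ds$aln$records, ds$reference$seqs)
  sites <- aggregate_sites(ev, depth, ds$reference$seqs)
  ins <- recover_insertions(ds$aln$records, sites, ds$reference$seqs,
                            ds$reference$genes)
  tru <- ds$donor$truth[ds$donor$truth$type == "INS", ]
  for (i in seq_len(nrow(tru))) {
    m <- which(ins$chrom == tru$chrom[i] & ins$breakpoint == tru$pos[i])
    expect_length(m, 1L)
    expect_identical(ins$seq[m], tru$alt[i])
  }
  # no double counting: merged calls <= one per truth event
  expect_lte(nrow(ins), nrow(tru))
})
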