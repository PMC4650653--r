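blk <- function(contig, cs, ce, chrom, rs, re, strand = "+") {
  data.frame(contig = contig, contig_start = cs, contig_end = ce, chrom = chrom,
             ref_start = rs, ref_end = re, strand = strand, identity = 1,
             snvs = 0L, short_indels = 0L, long_indels = 0L, stringsAsFactors = FALSE)
}

test_that("contig statistics follow the N50/L50 definitions", {
  expect_equal(contig_stats(c(10, 10, 10, 10))$n50, 10)
  expect_equal(contig_stats(c(10, 10, 10, 10))$l50, 2L)
  one <- contig_stats(c(a = "ACGTACGT"))
  expect_equal(one$n50, 8L)
  expect_equal(one$l50, 1L)
  expect_equal(one$gc, 50)
  expect_error(contig_stats(character(0)), "empty")
})

test_that("N50/L50 match brute force on random contig sets", {
  set.seed(71)
  for (i in 1:30) {
    lens <- sample(100:50000, sample(3:300, 1), replace = TRUE)
    cs <- contig_stats(lens)
    s <- sort(lens, decreasing = TRUE)
    tot <- sum(as.numeric(s))
    k <- 1L
    while (sum(as.numeric(s[1:k])) < tot / 2) k <- k + 1L
    expect_equal(cs$n50, s[k])
    expect_equal(cs$l50, k)
  }
})

test_that("misassembly classification covers the 12 constructed regimes", {
  cases <- list(
    # same chromosome, same strand, increasing distance around the 1 kb rule
    list(blk("c01", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c01", 10000, 20000, "chrI", 10000, 20000)), NULL),
    list(blk("c02", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c02", 10000, 20000, "chrI", 10500, 20500)), NULL),          # 500 < 1 kb
    list(blk("c03", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c03", 10000, 20000, "chrI", 10999, 20999)), NULL),          # 999: none
    list(blk("c04", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c04", 10000, 20000, "chrI", 11000, 21000)), "relocation"),  # exactly 1 kb
    list(blk("c05", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c05", 10000, 20000, "chrI", 50000, 60000)), "relocation"),  # 40 kb jump
    list(blk("c06", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c06", 10000, 20000, "chrI", 8000, 18000)), "relocation"),   # overlap jump
    list(blk("c07", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c07", 10000, 20000, "chrV", 0, 10000)), "translocation"),
    list(blk("c08", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c08", 10000, 20000, "chrV", 50000, 60000)), "translocation"),
    list(blk("c09", 0, 10000, "chrI", 0, 10000) |> rbind(
      blk("c09", 10000, 20000, "chrI", 10000, 20000, "-")), "inversion"),
    list(blk("c10", 0, 10000, "chrI", 0, 10000, "-") |> rbind(
      blk("c10", 10000, 20000, "chrI", 10000, 20000)), "inversion"),
    list(blk("c11", 0, 10000, "chrII", 0, 10000, "-") |> rbind(
      blk("c11", 10000, 20000, "chrI", 10000, 20000)), "translocation"),
    list(blk("c12", 0, 10000, "chrI", 0, 10000), NULL))                # single block
  for (cs in cases) {
    mis <- classify_misassemblies(cs[[1]])
    if (is.null(cs[[2]])) {
      expect_equal(nrow(mis), 0L, info = cs[[1]]$contig[1])
    } else {
      expect_equal(mis$type, cs[[2]], info = cs[[1]]$contig[1])
    }
  }
})

test_that("alignment metrics: coverage, duplication and NA50 breaking", {
  refs <- c(chrI = strrep("A", 100000))
  b1 <- blk("ctg1", 0, 10000, "chrI", 0, 10000)
  m1 <- alignment_metrics(b1, c(ctg1 = 10000L), refs)
  expect_equal(m1$genome_coverage, 10)
  expect_equal(m1$duplication_ratio, 1.0)
  # the same region covered twice doubles the ratio
  b2 <- rbind(b1, blk("ctg2", 0, 10000, "chrI", 0, 10000))
  m2 <- alignment_metrics(b2, c(ctg1 = 10000L, ctg2 = 10000L), refs)
  expect_equal(m2$duplication_ratio, 2.0)
  # a relocation at the contig midpoint halves the NA50 pieces
  b3 <- rbind(blk("ctg3", 0, 10000, "chrI", 0, 10000),
              blk("ctg3", 10000, 20000, "chrI", 50000, 60000))
  m3 <- alignment_metrics(b3, c(ctg3 = 20000L), refs)
  expect_equal(m3$relocations, 1L)
  expect_equal(m3$na50, 10000)
  # hand-broken comparison: breaking the contig in two gives the same N50
  expect_equal(m3$na50, contig_stats(c(10000, 10000))$n50)
  # unaligned accounting
  b4 <- blk("ctg4", 0, 1000, "chrI", 0, 1000)
  m4 <- alignment_metrics(b4, c(ctg4 = 10000L, ctg5 = 5000L), refs)
  expect_equal(m4$fully_unaligned, 1L)
  expect_equal(m4$partially_unaligned, 1L)
})

test_that("NA50 never exceeds N50", {
  set.seed(73)
  refs <- c(chrI = strrep("A", 1000000))
  for (i in 1:10) {
    n_ctg <- sample(3:10, 1)
    blocks <- list(); lens <- integer(0)
    for (ci in seq_len(n_ctg)) {
      nb <- sample(1:4, 1)
      len <- 0L
      for (bi in seq_len(nb)) {
        w <- sample(2000:20000, 1)
        rs <- sample(0:900000, 1)
        strand <- sample(c("+", "-"), 1)
        blocks[[length(blocks) + 1L]] <- blk(sprintf("t%d", ci), len, len + w,
                                             "chrI", rs, rs + w, strand)
        len <- len + w
      }
      lens[sprintf("t%d", ci)] <- len
    }
    bl <- do.call(rbind, blocks)
    m <- alignment_metrics(bl, lens, refs)
    expect_lte(m$na50, contig_stats(lens)$n50)
  }
})

test_that("block tables round-trip through TSV and PAF conversion", {
  b <- rbind(blk("c1", 0, 5000, "chrI", 100, 5100),
             blk("c1", 5000, 9000, "chrII", 0, 4000, "-"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(b, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_alignment_blocks(f), b)
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c("c1\t9000\t0\t5000\t+\tchrI\t100000\t100\t5100\t4900\t5000\t60",
               "c1\t9000\t5000\t9000\t-\tchrII\t100000\t0\t4000\t3800\t4000\t60"),
             paf)
  pb <- paf_to_blocks(paf)
  expect_equal(pb$contig_start, c(0L, 5000L))
  expect_equal(pb$strand, c("+", "-"))
  expect_equal(pb$identity, c(4900 / 5000, 3800 / 4000))
})
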