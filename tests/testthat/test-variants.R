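test_that("per-read extraction turns CIGAR/MD into typed events", {
  rec <- rbind(
    mk_record("r1", "c1", 100L, "5M2I3M", "AAAAATTCCC", md = "8"),
    mk_record("r2", "c1", 0L, "8M", strrep("A", 8), md = "8"),
    mk_record("r3", "c1", 0L, "3M2D3M", "AAATTT", md = "3^AC3"))
  ev <- extract_read_variants(rec)
  expect_equal(ev$type[ev$read_id == "r1"], "INS")
  expect_equal(ev$size[ev$read_id == "r1"], 2L)
  expect_equal(ev$alt[ev$read_id == "r1"], "TT")
  expect_false("r2" %in% ev$read_id)
  del <- ev[ev$read_id == "r3", ]
  expect_equal(del$type, "DEL")
  expect_equal(del$pos, 3L)
  expect_equal(del$size, 2L)
  # soft clips are not variants
  rec2 <- mk_record("r4", "c1", 0L, "5S10M", random_dna_str(15), md = "10")
  expect_equal(nrow(extract_read_variants(rec2)), 0L)
})

test_that("site calling follows the support-fraction rule", {
  refs <- c(c1 = random_dna_str(2000))
  track <- list(per_chrom = list(c1 = rep(4L, 2000)), mean = 4)
  class(track) <- "depth_track"
  ev <- data.frame(read_id = c("a", "b", "c"), chrom = "c1", type = "INS",
                   pos = 105L, size = 2L, ref = "", alt = "TT",
                   read_frac = 0.5, stringsAsFactors = FALSE)
  s <- aggregate_sites(ev, track, refs)
  expect_true(s$called)          # 3/4 > 0.5
  expect_equal(s$support, 3L)

  track$per_chrom$c1 <- rep(3L, 2000)
  s2 <- aggregate_sites(ev[1, ], track, refs)
  expect_false(s2$called)        # 1/3 <= 0.5, but the event is retained
  expect_equal(nrow(s2), 1L)

  ev_far <- ev; ev_far$pos <- 5000L
  expect_error(aggregate_sites(ev_far, track, refs), "beyond")
})

test_that("equivalent homopolymer indel placements merge after left-alignment", {
  # reference with an A-homopolymer: an insertion of AA reported at any
  # breakpoint inside the run is the same event
  set.seed(4)
  refs <- c(c1 = paste0(random_dna_str(50), "CAAAAAT", random_dna_str(50)))
  hp_bp <- 51L  # 0-based leftmost breakpoint inside the A-run (after the C)
  track <- list(per_chrom = list(c1 = rep(10L, nchar(refs))), mean = 10)
  class(track) <- "depth_track"
  # brute-force enumeration of equivalent placements along the run
  placements <- lapply(0:4, function(k)
    data.frame(read_id = paste0("r", k), chrom = "c1", type = "INS",
               pos = hp_bp + k, size = 2L, ref = "", alt = "AA",
               read_frac = 0.5, stringsAsFactors = FALSE))
  ev <- do.call(rbind, placements)
  s <- aggregate_sites(ev, track, refs)
  expect_equal(nrow(s), 1L)
  expect_equal(s$support, 5L)
  expect_equal(s$pos, hp_bp)  # canonical leftmost placement
  # deletions likewise
  ev_d <- do.call(rbind, lapply(0:3, function(k)
    data.frame(read_id = paste0("d", k), chrom = "c1", type = "DEL",
               pos = hp_bp + k, size = 1L, ref = "A", alt = "",
               read_frac = 0.5, stringsAsFactors = FALSE)))
  s_d <- aggregate_sites(ev_d, track, refs)
  expect_equal(nrow(s_d), 1L)
  expect_equal(s_d$support, 4L)
  expect_equal(s_d$pos, hp_bp)
})

test_that("error summary computes base ratios, size classes and windows", {
  rec <- mk_record("r1", "c1", 0L, "10000M", strrep("A", 10000), md = "10000")
  ev <- data.frame(read_id = "r1", chrom = "c1", type = "SNV", pos = 10L,
                   size = 1L, ref = "C", alt = "A", read_frac = 4950 / 10000,
                   stringsAsFactors = FALSE)
  es <- error_summary(ev, rec)
  expect_equal(es$aligned_bases, 10000)
  expect_equal(unname(es$ratio["SNV"]), 1e-4)  # 0.01%
  expect_equal(which(es$profile[, "SNV"] == 1L) - 1L, 49L)  # window 49, 0-based

  ev2 <- rbind(ev, data.frame(read_id = "r1", chrom = "c1", type = "DEL",
                              pos = 100L, size = 12L, ref = strrep("A", 12),
                              alt = "", read_frac = 0.01, stringsAsFactors = FALSE))
  es2 <- error_summary(ev2, rec)
  expect_equal(unname(es2$ratio_bases["DEL"]), 12 / 10000)
  expect_equal(es2$size_class["long", "DEL"], 1)
  expect_equal(es2$size_class["short", "SNV"], 1)
  expect_error(error_summary(ev, rec[0, ]), "aligned")
})

test_that("extraction recovers exactly the simulated error events", {
  # error-free donor == reference, so every extracted event is a read error
  cfg <- demo_config(seed = 19)
  cfg$genome_length <- c(chrI = 150000L)
  cfg$repeats <- list(interspersed = NULL, tandem = list())
  cfg$collapsed <- NULL; cfg$genes$n <- 0L
  cfg$variants$n_snv <- 0L; cfg$variants$n_ins <- 0L; cfg$variants$n_del <- 0L
  ds <- simulate_dataset(cfg)
  ev <- extract_read_variants(ds$aln$records)
  inj <- do.call(rbind, ds$sim$errors)
  expect_equal(sum(ev$type == "SNV"), sum(inj$kind == "sub"))
  expect_equal(sum(ev$type == "INS"), sum(inj$kind == "ins"))
  expect_equal(sum(ev$type == "DEL"), sum(inj$kind == "del"))
  expect_equal(sum(ev$size[ev$type == "DEL"]), sum(inj$len[inj$kind == "del"]))
})

test_that("deletion calls concentrate in repeats when artifacts target them", {
  an <- demo_analysis()
  ds <- an$ds
  sites <- an$sites
  reps <- ds$reference$repeats
  glen <- sum(nchar(ds$reference$seqs))
  repeat_frac <- sum(reps$end - reps$start) / glen
  dels <- sites[sites$type == "DEL", ]
  in_rep <- vapply(seq_len(nrow(dels)), function(i)
    any(reps$chrom == dels$chrom[i] & reps$start <= dels$pos[i] &
          dels$pos[i] < reps$end), logical(1))
  expect_gt(mean(in_rep), repeat_frac)
})
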