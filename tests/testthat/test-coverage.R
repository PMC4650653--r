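test_that("depth counts M bases only and gaps are maximal zero runs", {
  refs <- c(c1 = strrep("A", 20))
  rec <- rbind(mk_record("a", "c1", 0L, "10M", strrep("A", 10), md = "10"),
               mk_record("b", "c1", 5L, "10M", strrep("A", 10), md = "10"))
  tr <- depth_track(rec, refs)
  v <- tr$per_chrom$c1
  expect_equal(v[6:10], rep(2L, 5))
  expect_equal(v[1:5], rep(1L, 5))
  gaps <- extract_gaps(tr)
  expect_equal(gaps$start, 15L)
  expect_equal(gaps$end, 20L)

  # deletions span but add no depth
  recD <- mk_record("d", "c1", 0L, "5M5D5M", strrep("A", 10), md = "5^AAAAA5")
  vD <- depth_track(recD, refs)$per_chrom$c1
  expect_equal(vD[6:10], rep(0L, 5))
  expect_equal(vD[11:15], rep(1L, 5))

  # no alignments: one full-length gap per chromosome
  g0 <- extract_gaps(depth_track(rec[0, ], refs))
  expect_equal(g0$length, 20L)
})

test_that("N50 and median follow their definitions", {
  ls <- length_stats(c(2, 2, 2, 3, 3), min_len = 1L, open_from = 10L)
  expect_equal(ls$n50, 3)
  ls2 <- length_stats(rep(7L, 10), min_len = 1L, open_from = 10L)
  expect_equal(ls2$n50, 7L)
  expect_equal(ls2$median, 7L)
  expect_error(length_stats(integer(0)), "empty")
})

test_that("N50 equals the brute-force prefix enumeration on random sets", {
  set.seed(41)
  brute_n50 <- function(lens) {
    s <- sort(lens, decreasing = TRUE)
    tot <- sum(as.numeric(s))
    for (k in seq_along(s)) {
      if (sum(as.numeric(s[1:k])) >= tot / 2) return(s[k])
    }
  }
  for (i in 1:30) {
    lens <- sample(1500:20000, sample(5:1000, 1), replace = TRUE)
    expect_equal(length_stats(lens)$n50, brute_n50(lens))
  }
})

test_that("length strata form 139 closed bins plus one open bin", {
  set.seed(42)
  lens <- sample(1500:30000, 5000, replace = TRUE)
  st <- length_stats(lens)$strata
  expect_equal(nrow(st), 140L)
  expect_equal(st$low[1], 1500L)
  expect_equal(st$low[140], 15400L)
  expect_true(is.infinite(st$high[140]))
  expect_equal(sum(st$count), length(lens))
  expect_equal(sum(st$yield), sum(lens))
})

test_that("accumulative curves behave at the grid boundaries", {
  refs <- c(c1 = strrep("A", 10000))
  rec <- rbind(mk_record("short", "c1", 0L, "2000M", strrep("A", 2000), md = "2000"),
               mk_record("long", "c1", 5000L, "4000M", strrep("A", 4000), md = "4000"))
  rl <- c(short = 2000L, long = 9000L)
  targets <- data.frame(chrom = "c1", start = 0L, end = 10000L)
  cv <- accumulative_coverage(rec, rl, targets, grid = c(1500L, 5000L, 15500L))
  # below every read length: nothing is shorter
  expect_equal(cv$frac_shorter[cv$L == 1500], 0)
  # above every read length: longer-set empty, shorter-set covers all covered
  expect_equal(cv$frac_longer[cv$L == 15500], 0)
  expect_equal(cv$frac_shorter[cv$L == 15500], 0.6)
  # monotonicity
  expect_true(all(diff(cv$frac_shorter) >= 0))
  expect_true(all(diff(cv$frac_longer) <= 0))
  expect_error(accumulative_coverage(rec, rl, targets[0, ]), "empty target")
})

test_that("union of shorter and longer subsets equals the full covered set", {
  an <- demo_analysis()
  ds <- an$ds
  refs <- ds$reference$seqs
  rec <- ds$aln$records
  iv <- longreadaudit:::aligned_intervals(rec)
  rl <- setNames(ds$sim$truth_reads$length, ds$sim$truth_reads$read_id)
  iv$len <- unname(rl[iv$read_id])
  L <- 6000L
  cov_of <- function(d) {
    if (nrow(d) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
  }
  full <- cov_of(iv)
  both <- IRanges::reduce(c(cov_of(iv[iv$len < L, ]), cov_of(iv[iv$len >= L, ])))
  expect_identical(as.data.frame(full), as.data.frame(both))
})

test_that("intersection point minimizes the curve difference", {
  curves <- data.frame(L = c(1500, 1600, 1700), frac_shorter = c(0.1, 0.5, 0.9),
                       frac_longer = c(0.9, 0.5, 0.1))
  ip <- intersection_point(curves)
  expect_equal(ip$L, 1600)
  expect_true(ip$crossed)
  curves2 <- data.frame(L = c(1500, 1600), frac_shorter = c(0.1, 0.2),
                        frac_longer = c(0.8, 0.9))
  ip2 <- intersection_point(curves2)
  expect_equal(ip2$L, 1500)
  expect_false(ip2$crossed)
  # ties resolve to the smaller L
  curves3 <- data.frame(L = c(1500, 1600), frac_shorter = c(0.4, 0.6),
                        frac_longer = c(0.6, 0.4))
  expect_equal(intersection_point(curves3)$L, 1500)
})

test_that("per-chromosome profile attributes coverage to strata", {
  refs <- c(c1 = strrep("A", 10000))
  rec <- mk_record("r", "c1", 0L, "2000M", strrep("A", 2000), md = "2000")
  pr <- per_chromosome_profile(rec, c(r = 2000L), refs,
                               breaks = c(1500L, 3000L), n_bins = 10L)
  s1 <- pr[pr$stratum == "[1500,3000)", ]
  expect_equal(s1$covered_frac[1:2], c(1, 1))
  expect_equal(sum(s1$covered_frac > 0), 2L)
  expect_true(all(pr$covered_frac[pr$stratum == "[3000,Inf)"] == 0))
})
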