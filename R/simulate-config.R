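#' Simulation configuration
#'
#' Bundles every knob of the synthetic data generator. Defaults emulate the
#' study conditions the pipeline is designed around: a 2 Mb repeat-structured
#' chromosome; a donor genome differing by SNVs and 9-2000 bp insertions
#' (sequence "missing" from the reference); reads with a bimodal length
#' mixture peaking near 1.5 kb and 10 kb truncated at 1.5 kb; per-base error
#' rates of 0.01\% (SNV), 0.02\% (insertion) and 0.10\% (deletion) with a
#' 5x multiplier over the outer 5\% of each read; and an aligner emulator
#' with a 1 kb minimum anchor that renders insertions of at most 100 bp as
#' CIGAR I ops and larger ones as soft-clipped unaligned ends.
#'
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @param genome_length Named integer vector of chromosome lengths.
#' @param repeats List describing the repeat landscape: \code{interspersed}
#'   is a data.frame (class, unit_len, copies); \code{tandem} a list of
#'   list(class, unit, lengths) where each length yields one cluster of the
#'   repeated unit.
#' @param collapsed NULL, or list(unit_len, k): a single-copy region in the
#'   reference carried at k tandem copies by the donor (depth-spike model).
#' @param genes List(n, exon_len, n_exons, intron_len): gene models placed
#'   in unique sequence.
#' @param variants List: n_snv; n_ins and ins_size_range (log-uniform,
#'   default 9-2000 bp); n_del and del_size_range; min_spacing between
#'   injected events (also the guaranteed anchor flank).
#' @param reads List: depth (mean genome coverage); mix with weights w,
#'   means mu and sds sigma of the two length modes; min_len (1500 bp).
#' @param errors List: per-base event-start rates snv, ins, del;
#'   indel_size_p (geometric size parameter; error indel sizes are
#'   1 + rgeom, capped at 8 bp); end_window (fraction of read length at
#'   each end); end_multiplier; del_repeat_frac (fraction of deletion
#'   errors targeted into repeat intervals, modelling the observation that
#'   read deletions concentrate in repetitive sequence).
#' @param aligner List: min_anchor, max_cigar_insertion, max_cigar_deletion,
#'   blocker_threshold (tandem clusters longer than this block preassembly;
#'   a read is withheld when it contains more than this many cluster bases).
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = c(chrI = 2000000L),
                              repeats = list(
                                interspersed = data.frame(
                                  class = c("DNA", "LINE", "SINE", "LTR", "RC_Helitron"),
                                  unit_len = c(300L, 1200L, 300L, 450L, 500L),
                                  copies = c(40L, 12L, 30L, 15L, 15L),
                                  stringsAsFactors = FALSE),
                                tandem = list(
                                  list(class = "Simple", unit = "TGATA",
                                       lengths = c(300L, 600L, 2000L)),
                                  list(class = "Satellite", unit = NULL, unit_len = 35L,
                                       lengths = c(400L, 1500L)))),
                              collapsed = list(unit_len = 7200L, k = 20L),
                              genes = list(n = 20L, n_exons = c(3L, 6L),
                                           exon_len = c(100L, 300L),
                                           intron_len = c(60L, 400L)),
                              variants = list(n_snv = 100L,
                                              n_ins = 50L, ins_size_range = c(9L, 2000L),
                                              n_del = 20L, del_size_range = c(10L, 80L),
                                              min_spacing = 3000L),
                              reads = list(depth = 24,
                                           mix = list(w = c(0.35, 0.65),
                                                      mu = c(1800, 9800),
                                                      sigma = c(800, 1200)),
                                           min_len = 1500L),
                              errors = list(snv = 1e-4, ins = 2e-4, del = 1e-3,
                                            indel_size_p = 0.6,
                                            end_window = 0.05, end_multiplier = 5,
                                            del_repeat_frac = 0.5),
                              aligner = list(min_anchor = 1000L,
                                             max_cigar_insertion = 100L,
                                             max_cigar_deletion = 100L,
                                             blocker_threshold = 500L)) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              repeats = repeats, collapsed = collapsed, genes = genes,
              variants = variants, reads = reads, errors = errors,
              aligner = aligner)
  rates <- c(cfg$errors$snv, cfg$errors$ins, cfg$errors$del,
             cfg$errors$end_window, cfg$errors$del_repeat_frac)
  if (any(rates < 0 | rates > 1)) stopf("error rates and fractions must lie in [0, 1]")
  if (cfg$reads$min_len < 1500L) stopf("minimum read length must be >= 1500 bp")
  if (is.null(names(genome_length)) || any(genome_length <= 0)) {
    stopf("genome_length must be a named vector of positive lengths")
  }
  class(cfg) <- "simulation_config"
  cfg
}

# mean of the length mixture truncated at min_len (closed form)
mixture_mean_length <- function(reads) {
  mu <- reads$mix$mu; sigma <- reads$mix$sigma; w <- reads$mix$w
  a <- (reads$min_len - mu) / sigma
  mass <- 1 - pnorm(a)
  tmean <- mu + sigma * dnorm(a) / mass
  wt <- w * mass / sum(w * mass)
  sum(wt * tmean)
}

# n draws from the truncated mixture
draw_read_lengths <- function(n, reads) {
  mu <- reads$mix$mu; sigma <- reads$mix$sigma; w <- reads$mix$w
  a <- (reads$min_len - mu) / sigma
  mass <- 1 - pnorm(a)
  wt <- w * mass / sum(w * mass)
  comp <- sample.int(length(w), n, replace = TRUE, prob = wt)
  u <- runif(n, pnorm(a[comp]), 1)
  as.integer(round(qnorm(u) * sigma[comp] + mu[comp]))
}
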