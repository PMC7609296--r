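test_that("heptamer table is complete over all 16,384 contexts", {
  fx <- toy_annotations()
  nc <- toy_cohort()
  tab <- fit_heptamer_scores(fx$annotations$reference, nc$sites)
  expect_equal(nrow(tab), 16384L)
  expect_equal(sum(tab$occurrence), fx$config$genome_length - 6L)
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  # occurrence counts equal a Biostrings 7-mer recount
  dna <- Biostrings::DNAString(unclass(fx$annotations$reference)[[1]])
  bs <- Biostrings::oligonucleotideFrequency(dna, width = 7)
  expect_equal(tab$occurrence, unname(bs[tab$heptamer]))
  # variant tallies conserve the qualifying-SNP count at scoreable positions
  qual <- unique(nc$sites[nchar(ref) == 1 & nchar(alt) == 1 & af > 1e-4,
                          .(contig, pos)])
  L <- fx$config$genome_length
  expect_equal(sum(tab$variants), qual[pos >= 4 & pos <= L - 3, .N])
})

test_that("a variant-free cohort gives all-zero tolerance scores", {
  fx <- toy_annotations()
  empty <- data.table::data.table(contig = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  af = numeric())
  tab <- fit_heptamer_scores(fx$annotations$reference, empty)
  expect_equal(nrow(tab), 16384L)
  expect_true(all(tab$score == 0))
})

test_that("window observed counts match a brute-force interval recount", {
  fx <- toy_annotations()
  nc <- toy_cohort()
  tab <- fit_heptamer_scores(fx$annotations$reference, nc$sites)
  track <- score_windows(fx$annotations$reference, nc$sites, tab)
  qual_pos <- unique(nc$sites[nchar(ref) == 1 & nchar(alt) == 1 & af > 1e-4,
                              pos])
  set.seed(1)
  for (r in sample(nrow(track), 20)) {
    expect_equal(track$observed[r],
                 window_recount_oracle(qual_pos, track$start[r],
                                       track$end[r]))
  }
})

test_that("exact tiling conserves observed vs expected totals", {
  fx <- toy_annotations()
  nc <- toy_cohort()
  tab <- fit_heptamer_scores(fx$annotations$reference, nc$sites)
  track <- score_windows(fx$annotations$reference, nc$sites, tab,
                         window = 550, step = 550)
  expect_lte(abs(sum(track$observed) - sum(track$expected)) /
               sum(track$observed), 0.005)
})

test_that("percentile bins are equal-count and the track is deterministic", {
  fx <- toy_annotations()
  nc <- toy_cohort()
  tab <- fit_heptamer_scores(fx$annotations$reference, nc$sites)
  t1 <- score_windows(fx$annotations$reference, nc$sites, tab)
  t2 <- score_windows(fx$annotations$reference, nc$sites, tab)
  expect_identical(t1, t2)
  sizes <- t1[, .N, by = percentile][, N]
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_setequal(unique(t1$percentile), 1:100)
  # lower percentile = lower cdts
  expect_lte(max(t1[percentile == 1, cdts]), min(t1[percentile == 100, cdts]))
})

test_that("windows shorter than a contig are dropped and tiny contigs skipped", {
  ref <- structure(stats::setNames(strrep("ACGT", 100), "c1"),
                   class = "synth_reference")
  sites <- data.table::data.table(contig = "c1", pos = 10L, ref = "A",
                                  alt = "G", af = 0.5)
  tab <- fit_heptamer_scores(ref, sites)
  expect_warning(expect_error(
    score_windows(ref, sites, tab, window = 550), "no contig"), "skipped")
  tr <- score_windows(ref, sites, tab, window = 100, step = 100)
  expect_equal(nrow(tr), 4L)
  expect_true(all(tr$end <= 400L))
})

test_that("element coverage by percentile matches a per-bp oracle", {
  fx <- toy_annotations()
  nc <- toy_cohort()
  tab <- fit_heptamer_scores(fx$annotations$reference, nc$sites)
  track <- score_windows(fx$annotations$reference, nc$sites, tab,
                         window = 550, step = 110)
  cov <- element_coverage_by_percentile(track, fx$annotations$elements)
  expect_equal(dim(cov), c(100L, length(unique(fx$annotations$elements$family))))
  # families partition the genome, so each slice row sums to 1
  expect_true(all(abs(rowSums(cov) - 1) < 1e-9))
  L <- fx$config$genome_length
  for (pct in c(1, 50, 100)) {
    oracle <- coverage_oracle(track, fx$annotations$elements, pct, L)
    expect_equal(cov[pct, names(oracle)], oracle, tolerance = 1e-9)
  }
  # a single family covering the whole genome has fraction 1 everywhere
  whole <- data.table::data.table(contig = names(fx$annotations$reference),
                                  start = 0L, end = L, family = "genome")
  cov1 <- element_coverage_by_percentile(track, whole)
  expect_true(all(abs(cov1 - 1) < 1e-12))
  expect_error(element_coverage_by_percentile(
    track, data.table::data.table(contig = "chr1", start = 10L, end = 5L,
                                  family = "bad")), "malformed")
})

test_that("planted constrained regions fall into low percentiles", {
  cfg <- sim_config(seed = 13, genome_length = 5e5, n_samples = 200,
                    site_density = 0.03,
                    class_fractions = c(intron_intergenic = 1),
                    class_deficit = c(intron_intergenic = 0))
  ref <- generate_reference(cfg)
  cr <- data.table::data.table(contig = "chr1",
                               start = seq(25000L, 475000L, by = 50000L),
                               deficit = 0.5)
  cr[, end := start + 8000L]
  coh <- simulate_cohort_variants(ref, cfg, genotypes = FALSE,
                                  constrained_regions = cr)
  tab <- fit_heptamer_scores(ref, coh$sites)
  track <- score_windows(ref, coh$sites, tab)
  inside <- rep(FALSE, nrow(track))
  for (r in seq_len(nrow(cr))) {
    inside <- inside | (track$start >= cr$start[r] & track$end <= cr$end[r])
  }
  expect_lt(median(track$percentile[inside]), 20)
  # element enrichment: constrained family over-represented in slice 1
  fams <- data.table::data.table(
    contig = "chr1",
    start = c(cr$start, 0L), end = c(cr$end, cfg$genome_length),
    family = c(rep("constrained", nrow(cr)), "all"))
  cov <- element_coverage_by_percentile(track, fams)
  expect_gt(cov[1, "constrained"], cov[100, "constrained"])
})

test_that("heptamer composition z-scores are normalized and detect GC bias", {
  set.seed(5)
  at_rich <- paste(sample(c("A", "T"), 30000, replace = TRUE, prob = c(.5, .5)),
                   collapse = "")
  gc_rich <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE,
                          prob = c(.1, .4, .4, .1)), collapse = "")
  uniform <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
                   collapse = "")
  ref <- structure(c(c1 = paste0(at_rich, gc_rich, uniform)),
                   class = "synth_reference")
  elements <- data.table::data.table(
    contig = "c1", start = c(0L, 30000L, 60000L),
    end = c(30000L, 60000L, 90000L),
    family = c("at_fam", "gc_fam", "mix_fam"))
  z <- heptamer_composition_zscores(ref, elements)
  live <- !attr(z, "zero_sd")
  expect_true(all(abs(rowMeans(z[live, ])) < 1e-12))
  expect_true(all(abs(apply(z[live, ], 1, sd) - 1) < 1e-12))
  expect_true(all(z[!live, ] == 0))
  gc_count <- vapply(strsplit(rownames(z), ""), function(x) sum(x %in% c("G", "C")),
                     integer(1))
  gc_only <- gc_count == 7L & live
  expect_true(mean(z[gc_only, "gc_fam"] > 0) > 0.99)

  # identical-composition families: all z = 0
  ref2 <- structure(c(c1 = strrep("ACGTGCA", 2000)), class = "synth_reference")
  el2 <- data.table::data.table(contig = "c1", start = c(0L, 7000L),
                                end = c(7000L, 14000L),
                                family = c("f1", "f2"))
  z2 <- heptamer_composition_zscores(ref2, el2)
  expect_true(all(z2 == 0))
})
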