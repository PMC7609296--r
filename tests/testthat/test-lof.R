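# a hand-built two-exon gene on a tiny contig for exact consequence checks:
# CDS = ATG TGG AAA TAA split after codon 2, intron of 20 bp with GT..AG
make_toy_gene <- function() {
  # layout: 10 bp pad | exon1 (6 bp: ATGTGG) | intron (20 bp) | exon2
  # (6 bp: AAATAA) | pad
  pad5 <- strrep("C", 10)
  exon1 <- "ATGTGG"
  intron <- paste0("GT", strrep("C", 16), "AG")
  exon2 <- "AAATAA"
  pad3 <- strrep("C", 10)
  seq <- paste0(pad5, exon1, intron, exon2, pad3)
  ref <- structure(stats::setNames(seq, "chrT"), class = "synth_reference")
  gm <- list(
    genes = data.table::data.table(gene_id = "TOY", contig = "chrT",
                                   strand = "+", start = 11L, end = 42L),
    exons = data.table::data.table(gene_id = "TOY", exon_rank = 1:2,
                                   start = c(11L, 37L), end = c(16L, 42L)))
  list(reference = ref, gm = gm)
}

test_that("consequence engine classifies crafted variants correctly", {
  fx <- make_toy_gene()
  sites <- data.table::data.table(
    contig = "chrT",
    pos = c(16L, 14L, 17L, 12L, 37L, 39L, 13L, 20L),
    id = paste0("x", 1:8),
    ref = c("G", "T", "G", "T", "A", "A", "G", "C"),
    alt = c("A", "A", "C", "C", "G", "AGTC", "GT", "A"))
  ann <- annotate_consequence(sites, fx$gm, fx$reference)
  # TGG codon2 -> TGA (pos 16 G>A): stop gained
  expect_equal(ann[pos == 16 & alt == "A", class], "stop_gained")
  expect_true(ann[pos == 16, is_plof])
  # codon2 TGG -> AGG (pos 14 T>A): missense
  expect_equal(ann[pos == 14, class], "missense")
  # intron +1 (pos 17 is first intron base, G>C): splice disruption
  expect_equal(ann[pos == 17, class], "splice_disrupt")
  # ATG pos2 T>C -> ACG: start lost
  expect_equal(ann[pos == 12, class], "start_lost")
  # exon2 first base A>G: AAA -> GAA, missense
  expect_equal(ann[pos == 37, class], "missense")
  # 3-bp insertion in CDS: in-frame
  expect_equal(ann[pos == 39, class], "inframe_indel")
  expect_false(ann[pos == 39, is_plof])
  # 1-bp insertion in CDS at pos 13: frameshift
  expect_equal(ann[pos == 13, class], "frameshift")
  # deep intron SNV is noncoding
  expect_equal(ann[pos == 20, class], "noncoding")
})

test_that("synonymous changes at the stop codon are not stop_lost", {
  fx <- make_toy_gene()
  # TAA -> TGA (pos 41 A>G) is still a stop: synonymous
  s <- data.table::data.table(contig = "chrT", pos = 41L, id = "y1",
                              ref = "A", alt = "G")
  ann <- annotate_consequence(s, fx$gm, fx$reference)
  expect_equal(ann$class, "synonymous")
  # TAA -> CAA (pos 40 T>C): stop lost
  s2 <- data.table::data.table(contig = "chrT", pos = 40L, id = "y2",
                               ref = "T", alt = "C")
  expect_equal(annotate_consequence(s2, fx$gm, fx$reference)$class,
               "stop_lost")
})

test_that("potential-LOF enumeration matches the retranslation oracle", {
  for (seed in 1:8) {
    ann <- make_random_toy_gene(seed)
    gi <- build_gene_index(ann, ann$reference)
    expect_equal(as.integer(enumerate_potential_lof(gi$RND)),
                 potential_lof_oracle("RND", ann),
                 info = paste("seed", seed))
  }
})

test_that("intronless genes contribute no potential splice disruptions", {
  fx <- make_toy_gene()
  # single-exon variant of the toy gene
  seq <- paste0(strrep("C", 10), "ATGTGGAAATAA", strrep("C", 10))
  ref <- structure(stats::setNames(seq, "chrT"), class = "synth_reference")
  gm <- list(genes = data.table::data.table(gene_id = "ONE", contig = "chrT",
                                            strand = "+", start = 11L,
                                            end = 22L),
             exons = data.table::data.table(gene_id = "ONE", exon_rank = 1L,
                                            start = 11L, end = 22L))
  gi <- build_gene_index(gm, ref)
  pot <- enumerate_potential_lof(gi$ONE)
  expect_equal(unname(attr(pot, "by_class")["splice_disrupt"]), 0)
})

test_that("degenerate gene models are rejected", {
  # ATG TAA: no internal codons
  seq <- paste0(strrep("C", 10), "ATGTAA", strrep("C", 10))
  ref <- structure(stats::setNames(seq, "chrT"), class = "synth_reference")
  gm <- list(genes = data.table::data.table(gene_id = "MINI", contig = "chrT",
                                            strand = "+", start = 11L,
                                            end = 16L),
             exons = data.table::data.table(gene_id = "MINI", exon_rank = 1L,
                                            start = 11L, end = 16L))
  gi <- build_gene_index(gm, ref)
  expect_error(enumerate_potential_lof(gi$MINI), "too short")
  # CDS length not divisible by 3: gene skipped with warning
  gm2 <- list(genes = gm$genes,
              exons = data.table::data.table(gene_id = "MINI", exon_rank = 1L,
                                             start = 11L, end = 15L))
  expect_warning(gi2 <- build_gene_index(gm2, ref), "divisible")
  expect_length(gi2, 0L)
})

test_that("gene constraint table counts observed pLOF and knockouts", {
  fx <- make_toy_gene()
  # cohort: a rare hom-alt stop_gained in sample 1 plus a common missense
  sites <- data.table::data.table(
    contig = "chrT", pos = c(16L, 37L), id = c("k1", "k2"),
    ref = c("G", "A"), alt = c("A", "G"),
    ac = c(2L, 150L), an = 400L, af = c(2, 150) / 400, is_indel = FALSE)
  geno <- rbind(c(2L, rep(0L, 199)), rep(c(1L, 0L), 100))
  coh <- structure(list(sites = sites, geno = geno,
                        samples = data.table::data.table(
                          sample_id = sprintf("s%03d", 1:200))),
                   class = "cohort")
  tab <- gene_constraint_table(coh, fx$gm, fx$reference,
                               pli_annotations = data.table::data.table(
                                 gene_id = "TOY", pli = 0.99))
  expect_equal(tab$observed_lof, 1L)
  expect_true(tab$has_hom_rare_plof)
  expect_true(tab$is_lof_intolerant)
  expect_equal(tab$op_ratio, 1L / tab$potential_lof)
  expect_gt(tab$potential_lof, 0)

  # zero-pLOF cohort: all OP ratios are 0, no knockouts
  coh0 <- coh
  coh0$sites <- sites[2]
  coh0$geno <- geno[2, , drop = FALSE]
  tab0 <- gene_constraint_table(coh0, fx$gm, fx$reference)
  expect_equal(tab0$op_ratio, 0)
  expect_false(tab0$has_hom_rare_plof)
  expect_true(is.na(tab0$pli))
  expect_false(tab0$is_lof_intolerant)
})

test_that("observed pLOF equals an independent per-record recount", {
  fx <- toy_annotations()
  coh <- toy_cohort()
  gi <- build_gene_index(fx$annotations, fx$annotations$reference)
  ann <- annotate_consequence(coh$sites, fx$annotations,
                              fx$annotations$reference, gene_index = gi)
  tab <- gene_constraint_table(coh, fx$annotations,
                               fx$annotations$reference, annotated = ann)
  recount <- sapply(tab$gene_id, function(g) {
    sel <- ann$gene_id == g & ann$is_plof
    sel[is.na(sel)] <- FALSE
    length(unique(paste(ann$pos[sel], ann$alt[sel])))
  })
  expect_equal(tab$observed_lof, unname(recount))
})

test_that("SFS construction is exact", {
  sites <- data.table::data.table(ac = c(1L, 1L, 5L),
                                  true_class = "synonymous")
  s <- build_sfs(sites, "synonymous", 10L)
  expect_equal(s$counts[1], 2L)
  expect_equal(s$counts[5], 1L)
  expect_equal(sum(s$counts), 3L)
  expect_error(build_sfs(data.table::data.table(ac = 12L, true_class = "x"),
                         "x", 10L), "inconsistent")
})

test_that("neutral spectrum has the i^-1 singleton/doubleton ratio", {
  cfg <- sim_config(seed = 51, genome_length = 1e6, n_samples = 250,
                    site_density = 0.05,
                    class_fractions = c(intron_intergenic = 1),
                    class_deficit = c(intron_intergenic = 0))
  coh <- simulate_cohort_variants(generate_reference(cfg), cfg,
                                  genotypes = FALSE)
  s <- build_sfs(coh$sites, "intron_intergenic", 500L)
  expect_equal(s$counts[1] / s$counts[2], 2, tolerance = 0.1)
})

test_that("selection fraction is 0 on identical spectra and errors on degenerate input", {
  s <- structure(list(counts = c(100L, 50L, 33L), class = "a",
                      n_chrom = 4L), class = "sfs")
  f <- fraction_under_selection(s, s)
  expect_equal(f$fraction, 0)
  expect_false(f$negative_flag)
  ref_singletons <- structure(list(counts = c(100L, 0L, 0L), class = "r",
                                   n_chrom = 4L), class = "sfs")
  expect_error(fraction_under_selection(s, ref_singletons), "degenerate")
})

test_that("rare variant groups keep pLOF and flagged missense under the MAF cut", {
  fx <- make_toy_gene()
  sites <- data.table::data.table(
    contig = "chrT", pos = c(16L, 37L, 38L, 14L), id = paste0("g", 1:4),
    ref = c("G", "A", "A", "T"), alt = c("A", "G", "T", "A"),
    ac = c(2L, 3L, 2L, 20L), an = 1000L,
    af = c(2, 3, 2, 20) / 1000, is_indel = FALSE)
  ann <- annotate_consequence(sites, fx$gm, fx$reference)
  flags <- data.table::data.table(contig = "chrT", pos = 37L, ref = "A",
                                  alt = "G", flag = TRUE)
  groups <- build_rare_variant_groups(ann, flags)
  # g1 (pLOF), g2 (flagged missense) in; g3 (unflagged missense) out;
  # g4 (start_lost pLOF) excluded: MAF 0.02 >= 0.01
  expect_equal(sort(groups$TOY), c("g1", "g2"))
  # no flags and no pLOF: empty mapping
  expect_equal(build_rare_variant_groups(ann[class == "missense" &
                                               af > 0.001]), list())
  # unknown flagged site warns
  badflags <- data.table::data.table(contig = "chrT", pos = 9999L, ref = "A",
                                     alt = "G", flag = TRUE)
  expect_warning(build_rare_variant_groups(ann, badflags), "unknown")
})

test_that("gene-based significance threshold is alpha over genes", {
  expect_identical(gene_test_threshold(), 0.05 / 20000)
  expect_equal(gene_test_threshold(), 2.5e-6)
})
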