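# Independent oracles and shared fixtures for the test suite. Oracles use
# different computational paths than the package implementation.

# ---- Hardy-Weinberg oracle: closed-form factorial enumeration ------------

# P(het = h | N genotypes, n_rare rare-allele copies), via lgamma
hwe_oracle_dist <- function(N, n_rare) {
  h_min <- if (n_rare %% 2L == 0L) 0L else 1L
  h <- seq.int(h_min, min(n_rare, 2L * N - n_rare), by = 2L)
  a <- (n_rare - h) / 2
  r <- N - h - a
  logp <- lgamma(N + 1) - lgamma(r + 1) - lgamma(h + 1) - lgamma(a + 1) +
    h * log(2) + lgamma(n_rare + 1) + lgamma(2 * N - n_rare + 1) -
    lgamma(2 * N + 1)
  list(h = h, prob = exp(logp))
}

# exact two-sided p by full enumeration (same tie rule as the test:
# include every h whose probability is <= observed * (1 + 1e-7))
hwe_oracle_p <- function(n_hom_ref, n_het, n_hom_alt) {
  N <- n_hom_ref + n_het + n_hom_alt
  n_alt <- n_het + 2L * n_hom_alt
  n_rare <- min(n_alt, 2L * N - n_alt)
  if (n_rare == 0L) return(1)
  d <- hwe_oracle_dist(N, n_rare)
  p_obs <- d$prob[match(n_het, d$h)]
  sum(d$prob[d$prob <= p_obs * (1 + 1e-7)])
}

# all two-sided p-values of a (N, n_rare) configuration from a distribution,
# shared tie rule
p_from_dist <- function(dist) {
  vapply(dist$prob, function(p0) {
    sum(dist$prob[dist$prob <= p0 * (1 + 1e-7)])
  }, numeric(1))
}

# ---- potential-LOF oracle: substitute-and-retranslate --------------------

# Recount potential pLOF alt alleles of a gene by editing the reference,
# re-splicing the CDS and translating the whole protein with Biostrings.
potential_lof_oracle <- function(gene_id, annotations) {
  ref <- unclass(annotations$reference)[[1]]
  sel <- annotations$exons$gene_id == gene_id
  ex <- annotations$exons[sel][order(exon_rank)]
  cds_pos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
  splice_pos <- integer(0)
  if (nrow(ex) > 1) {
    for (e in seq_len(nrow(ex) - 1L)) {
      splice_pos <- c(splice_pos, ex$end[e] + 1L, ex$end[e] + 2L,
                      ex$start[e + 1L] - 2L, ex$start[e + 1L] - 1L)
    }
  }
  splice_cds <- function(seq) {
    paste(substring(seq, cds_pos, cds_pos), collapse = "")
  }
  prot <- function(cds) {
    seqinr::translate(strsplit(cds, "")[[1]])
  }
  aa_ref <- prot(splice_cds(ref))
  n_aa <- length(aa_ref)
  count <- 3L * length(splice_pos)        # essential splice sites all pLOF
  for (p in cds_pos) {
    ref_base <- substring(ref, p, p)
    for (b in setdiff(c("A", "C", "G", "T"), ref_base)) {
      edited <- ref
      substring(edited, p, p) <- b
      aa_alt <- prot(splice_cds(edited))
      changed <- which(aa_ref != aa_alt)
      if (!length(changed)) next
      i <- changed[1]
      plof <- (i == 1L) ||                                   # start lost
        (aa_alt[i] == "*" && i < n_aa) ||                    # premature stop
        (i == n_aa && aa_ref[i] == "*" && aa_alt[i] != "*")  # stop lost
      if (plof) count <- count + 1L
    }
  }
  count
}

# ---- interval-recount oracles --------------------------------------------

# observed qualifying-SNP count in [start, end), brute force over positions
window_recount_oracle <- function(positions, start, end) {
  sum(positions > start & positions <= end)   # 1-based pos in 0-based window
}

# per-bp element coverage of a percentile slice
coverage_oracle <- function(track, elements, pct, genome_length) {
  w <- track[track$percentile == pct, ]
  in_slice <- logical(genome_length)
  for (r in seq_len(nrow(w))) {
    in_slice[(w$start[r] + 1L):w$end[r]] <- TRUE
  }
  fams <- sort(unique(elements$family))
  out <- stats::setNames(numeric(length(fams)), fams)
  for (f in fams) {
    e <- elements[elements$family == f, ]
    in_fam <- logical(genome_length)
    for (r in seq_len(nrow(e))) {
      if (e$end[r] > e$start[r]) in_fam[(e$start[r] + 1L):e$end[r]] <- TRUE
    }
    out[f] <- sum(in_slice & in_fam) / sum(in_slice)
  }
  out
}

# random small toy gene (5-25 codons, 1-3 exons) on its own contig, as a
# synth_annotations-shaped list, for enumeration-oracle checks
make_random_toy_gene <- function(seed) {
  set.seed(seed)
  n_codons <- sample(5:25, 1)
  n_exons <- sample(1:3, 1)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                             collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  cds_len <- nchar(orf)
  if (n_exons > 1) {
    cuts <- sort(sample(seq(3, cds_len - 3, by = 3), n_exons - 1))
    exon_len <- diff(c(0, cuts, cds_len))
  } else exon_len <- cds_len
  intron_len <- if (n_exons > 1) sample(20:40, n_exons - 1, replace = TRUE)
                else integer(0)
  pieces <- character(0)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- 11L
  off <- 0L
  for (e in seq_len(n_exons)) {
    starts[e] <- pos
    ends[e] <- pos + exon_len[e] - 1L
    pieces <- c(pieces, substring(orf, off + 1L, off + exon_len[e]))
    off <- off + exon_len[e]
    pos <- ends[e] + 1L
    if (e < n_exons) {
      il <- intron_len[e]
      pieces <- c(pieces, paste0("GT", paste(sample(c("A", "C", "G", "T"),
                                                    il - 4, replace = TRUE),
                                             collapse = ""), "AG"))
      pos <- pos + il
    }
  }
  seq <- paste0(strrep("C", 10), paste(pieces, collapse = ""), strrep("C", 10))
  ref <- structure(stats::setNames(seq, "chrR"), class = "synth_reference")
  structure(list(
    reference = ref,
    genes = data.table::data.table(gene_id = "RND", contig = "chrR",
                                   strand = "+", start = starts[1],
                                   end = ends[n_exons]),
    exons = data.table::data.table(gene_id = "RND",
                                   exon_rank = seq_len(n_exons),
                                   start = starts, end = ends)),
    class = "synth_annotations")
}

# ---- shared fixtures (built once per test run) ---------------------------

toy_annotations <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, genome_length = 1e5, n_samples = 40,
                        n_genes = 8, site_density = 0.02)
      ref <- generate_reference(cfg)
      cache <<- list(config = cfg, annotations = generate_annotations(ref, cfg))
    }
    cache
  }
})

toy_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- toy_annotations()
      coh <- simulate_cohort_variants(fx$annotations, fx$config)
      cache <<- normalize_sites(coh)
    }
    cache
  }
})
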