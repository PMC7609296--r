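#' Bundled star-allele / pharmacogene variant definition table
#'
#' Reads the editable allele-definition TSV shipped with the package: one
#' row per non-default allele with its defining variant (rsID, ref/alt) and
#' functional status (`no_function`, `decreased`, `increased`, `normal`,
#' `profile` for genotype-profile-only variants). The default allele (`*1`,
#' or `*1A` for SLCO1B1) carries no row. Genomic coordinates in the bundled
#' file are synthetic placeholders — within this package they only serve as
#' site identifiers for the synthetic cohort. SLCO1B1 *15 (the *1B + *5
#' composite haplotype) is deliberately absent: with unphased genotypes and
#' one defining variant per haplotype it cannot be distinguished from
#' *1B/*5.
#'
#' @param path TSV path (default: the bundled table).
#' @return data.table: gene, allele, rsid, contig, pos, ref, alt, func.
#' @export
read_star_allele_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pgx_allele_defs.tsv",
                                package = "varcohort")
  tab <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("gene", "allele", "rsid", "contig", "ref", "alt", "func")))
  if (anyDuplicated(tab[, .(gene, rsid)])) {
    stop("rsIDs must be unique within gene")
  }
  tab
}

#' Default star allele per gene
#' @param gene gene symbol.
#' @return allele name assigned to haplotypes carrying no defining variant.
#' @export
pgx_default_allele <- function(gene) {
  switch(gene, SLCO1B1 = "*1A", CYP2C19 = "*1", CYP2C9 = "*1",
         VKORC1 = "G", ALDH2 = "G", CYP1A2 = "A",
         ADH1B = "ref", "*1")
}

#' Generate a pharmacogene cohort
#'
#' Assigns each of the 2n haplotypes of each gene a star allele by a
#' multinomial draw over the configured allele frequencies (remainder mass
#' to the default allele), so every haplotype carries at most one defining
#' variant and diplotypes are unambiguous. Genotypes at the defining sites
#' are the per-sample counts of each allele.
#'
#' @param config a [sim_config()]; `pgx_allele_freqs` must only name alleles
#'   present in `star_table`.
#' @param star_table allele-definition table ([read_star_allele_table()]).
#' @return object of class `pgx_cohort`: `sites` (allele-definition rows
#'   plus realized ac/an/af), `geno` (defining variants x samples dosage
#'   matrix, rownames = rsid), `samples` (metadata), `truth` (data.table:
#'   sample_id, gene, hap1, hap2).
#' @export
generate_pgx_cohort <- function(config, star_table = read_star_allele_table()) {
  freqs <- config$pgx_allele_freqs
  for (g in names(freqs)) {
    unknown <- setdiff(names(freqs[[g]]), star_table[gene == g, allele])
    if (length(unknown)) {
      stop("pgx_allele_freqs for ", g, " names undefined alleles: ",
           paste(unknown, collapse = ", "))
    }
    if (sum(freqs[[g]]) > 1) stop("frequencies for ", g, " sum to > 1")
  }
  n <- config$n_samples
  with_seed(config$seed + 7L, {
    samples <- generate_sample_metadata(n, config$seed + 3L)
    truth <- list()
    geno_rows <- list()
    for (g in names(freqs)) {
      f <- freqs[[g]]
      alleles <- c(pgx_default_allele(g), names(f))
      prob <- c(1 - sum(f), unname(f))
      haps <- matrix(sample(alleles, 2L * n, replace = TRUE, prob = prob),
                     nrow = 2L)
      truth[[g]] <- data.table::data.table(
        sample_id = samples$sample_id, gene = g,
        hap1 = haps[1, ], hap2 = haps[2, ])
      defs <- star_table[gene == g]
      for (r in seq_len(nrow(defs))) {
        al <- defs$allele[r]
        geno_rows[[defs$rsid[r]]] <-
          as.integer(haps[1, ] == al) + as.integer(haps[2, ] == al)
      }
    }
    geno <- do.call(rbind, geno_rows)
    defs_used <- star_table[rsid %in% rownames(geno)]
    defs_used <- defs_used[match(rownames(geno), rsid)]
    ac <- rowSums(geno)
    sites <- data.table::data.table(defs_used,
                                    ac = ac, an = 2L * n, af = ac / (2 * n))
    structure(list(sites = sites, geno = geno, samples = samples,
                   truth = data.table::rbindlist(truth)),
              class = "pgx_cohort")
  })
}
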