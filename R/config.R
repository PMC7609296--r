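#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic-data module. The defaults define a
#' 2 Mb single-contig genome with 500 diploid samples, an allele-count
#' spectrum following the neutral \eqn{i^{-\alpha}} law with class-specific
#' non-singleton deficits, a two-population divergence target, an additive
#' trait architecture and star-allele frequencies for the pharmacogene
#' cohort. Identical config + seed yields byte-identical outputs.
#'
#' @param seed integer seed driving all randomness of the generator.
#' @param genome_length genome size in bp (>= 1e5 for the default pipeline;
#'   smaller values are accepted by individual generators for toy runs).
#' @param n_samples number of diploid samples.
#' @param n_genes number of non-overlapping protein-coding gene models.
#' @param site_density variants per bp (default 0.025, i.e. 50,000 sites on
#'   the 2 Mb default genome).
#' @param sfs_exponent exponent \eqn{\alpha} of the allele-count law
#'   \eqn{P(AC = i) \propto i^{-\alpha}}; 1 is the neutral expectation.
#' @param class_deficit named fractions in \[0,1) thinning non-singleton
#'   allele-count bins of each consequence class (purifying-selection
#'   emulation). Classes absent from the vector get deficit 0.
#' @param class_fractions named mixing proportions of true consequence
#'   classes over simulated sites (must sum to 1).
#' @param fst_target Balding-Nichols divergence F between the two simulated
#'   populations, in (0, 1).
#' @param h2 narrow-sense heritability of the quantitative trait in \[0,1\].
#' @param n_causal number of causal variants for the trait.
#' @param prevalence population prevalence of the liability-threshold binary
#'   disease.
#' @param indel_fraction fraction of simulated sites that are indels
#'   (length 1-6 bp, within the <= 10 bp pipeline limit).
#' @param transition_prob probability a simulated SNV is a transition
#'   (0.678 gives Ti/Tv close to 2.1, typical of WGS cohorts).
#' @param lcr_fraction fraction of the genome masked as low-complexity
#'   regions (default 0.02).
#' @param pgx_allele_freqs named list: gene -> named numeric vector of
#'   non-reference star-allele (or genotype-profile variant) frequencies.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_samples = 500L,
                       n_genes = 50L,
                       site_density = 0.025,
                       sfs_exponent = 1,
                       class_deficit = c(lof = 0.5, nonsynonymous = 0.3,
                                         synonymous = 0.1, intron_intergenic = 0),
                       class_fractions = c(intron_intergenic = 0.88,
                                           synonymous = 0.05,
                                           nonsynonymous = 0.055,
                                           lof = 0.015),
                       fst_target = 0.15,
                       h2 = 0.5,
                       n_causal = 20L,
                       prevalence = 0.1,
                       indel_fraction = 0.08,
                       transition_prob = 0.678,
                       lcr_fraction = 0.02,
                       pgx_allele_freqs = default_pgx_freqs()) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (genome_length < 7) stop("degenerate config: genome_length < 7")
  if (n_samples < 1 || n_genes < 1) stop("counts must be > 0")
  if (sfs_exponent <= 0) stop("sfs_exponent must be > 0")
  if (any(class_deficit < 0 | class_deficit >= 1)) {
    stop("class_deficit entries must lie in [0, 1)")
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1")
  }
  if (fst_target <= 0 || fst_target >= 1) stop("fst_target must be in (0, 1)")
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (indel_fraction < 0 || indel_fraction >= 1) stop("indel_fraction in [0, 1)")
  if (lcr_fraction < 0 || lcr_fraction > 0.5) stop("lcr_fraction in [0, 0.5]")
  for (g in names(pgx_allele_freqs)) {
    f <- pgx_allele_freqs[[g]]
    if (any(f < 0) || sum(f) > 1) {
      stop("pgx_allele_freqs for gene ", g, " must be >= 0 and sum to <= 1")
    }
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    site_density = site_density, sfs_exponent = sfs_exponent,
    class_deficit = class_deficit, class_fractions = class_fractions,
    fst_target = fst_target, h2 = h2, n_causal = as.integer(n_causal),
    prevalence = prevalence, indel_fraction = indel_fraction,
    transition_prob = transition_prob, lcr_fraction = lcr_fraction,
    pgx_allele_freqs = pgx_allele_freqs
  ), class = "sim_config")
}

#' Default star-allele / pharmacogene variant frequencies
#'
#' East Asian population frequencies for the bundled pharmacogene panel:
#' CYP2C19 star alleles, CYP2C9 *2/*3, VKORC1 rs9923231, SLCO1B1 alleles and
#' the alcohol/caffeine metabolism profile variants (ALDH2 rs671, ADH1B
#' rs1229984 / rs2066702, CYP1A2 rs762551).
#'
#' @return named list of named numeric frequency vectors, one per gene.
#' @export
default_pgx_freqs <- function() {
  list(
    CYP2C19 = c("*2" = 0.31, "*3" = 0.06, "*17" = 0.015),
    CYP2C9  = c("*2" = 0.002, "*3" = 0.035),
    VKORC1  = c("A" = 0.90),
    SLCO1B1 = c("*1B" = 0.55, "*5" = 0.01, "*17" = 0.12),
    ALDH2   = c("A" = 0.21),
    ADH1B   = c("rs1229984_T" = 0.70),
    CYP1A2  = c("C" = 0.36)
  )
}
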