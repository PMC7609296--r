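#' Simulate a multi-sample variant cohort with a controlled allele-count law
#'
#' Draws variant sites along the genome, assigns each a true consequence
#' class, and realizes an allele-count spectrum with
#' \eqn{P(AC = i) \propto i^{-\alpha}} over \eqn{i = 1, \dots, 2n - 1}. For
#' classes with a configured deficit \eqn{d}, all non-singleton bins
#' (\eqn{i \ge 2}) are thinned by the factor \eqn{1 - d}, emulating
#' purifying selection against the class while leaving the singleton bin
#' (dominated by new mutations) untouched. Genotypes are assigned by random
#' placement of the AC alternate alleles among the 2n chromosomes, so the
#' realized AC is exact per site and founders are in approximate
#' Hardy-Weinberg proportions.
#'
#' @param annotations output of [generate_annotations()] (used for its
#'   edited reference); alternatively a bare `synth_reference`.
#' @param config a [sim_config()].
#' @param genotypes if `FALSE`, skip the genotype matrix (AC/AN/AF and truth
#'   labels only) — useful for large spectrum-only simulations.
#' @param n_sites number of candidate sites before selection thinning
#'   (default `round(site_density * genome_length)`).
#' @param constrained_regions optional data.table (contig, start, end —
#'   0-based half-open — and deficit) of planted constrained regions whose
#'   non-singleton sites are additionally thinned by `deficit`.
#' @return object of class `cohort`: list with `sites` (data.table: contig,
#'   pos, id, ref, alt, ac, an, af, true_class, is_indel), `geno` (integer
#'   dosage matrix, sites x samples, or NULL), `samples` (metadata
#'   data.table: sample_id, age, sex, height, weight, population).
#' @export
simulate_cohort_variants <- function(annotations, config, genotypes = TRUE,
                                     n_sites = NULL,
                                     constrained_regions = NULL) {
  if (config$n_samples < 2) stop("n_samples must be >= 2")
  reference <- if (inherits(annotations, "synth_annotations")) {
    annotations$reference
  } else annotations
  contig <- names(reference)[1]
  seq <- unclass(reference)[[1]]
  L <- nchar(seq)
  n_sites <- as.integer(n_sites %||% round(config$site_density * L))
  if (n_sites < 1) {
    warning("site_density x genome_length < 1: empty cohort")
    return(empty_cohort(config))
  }
  n <- config$n_samples
  an <- 2L * n

  with_seed(config$seed + 2L, {
    pos <- sort(sample.int(L - 10L, n_sites))
    classes <- names(config$class_fractions)
    if (inherits(annotations, "synth_annotations")) {
      # location-aware truth labels: positions inside CDS exons draw a
      # coding class; everything else is intron/intergenic
      ex <- annotations$exons
      in_exon <- rep(FALSE, n_sites)
      for (r in seq_len(nrow(ex))) {
        in_exon <- in_exon | (pos >= ex$start[r] & pos <= ex$end[r])
      }
      coding <- setdiff(classes, "intron_intergenic")
      cw <- config$class_fractions[coding]
      true_class <- rep("intron_intergenic", n_sites)
      if (any(in_exon) && length(coding)) {
        true_class[in_exon] <- sample(coding, sum(in_exon), replace = TRUE,
                                      prob = cw / sum(cw))
      }
    } else {
      true_class <- sample(classes, n_sites, replace = TRUE,
                           prob = config$class_fractions)
    }
    # allele counts from the i^(-alpha) law; purifying selection is then
    # emulated by REJECTION: a non-singleton site of a class with deficit d
    # is dropped with probability d (singletons, i.e. fresh mutations, are
    # never thinned). Thinning removes sites, so constrained classes and
    # regions end up with both a skewed SFS and a lower site density.
    i <- seq_len(an - 1L)
    base_w <- i^(-config$sfs_exponent)
    ac <- sample.int(an - 1L, n_sites, replace = TRUE, prob = base_w)
    d_site <- config$class_deficit[true_class]
    d_site[is.na(d_site)] <- 0
    if (!is.null(constrained_regions) && nrow(constrained_regions) > 0) {
      for (r in seq_len(nrow(constrained_regions))) {
        hit <- contig == constrained_regions$contig[r] &
          pos > constrained_regions$start[r] &
          pos <= constrained_regions$end[r]
        d_site[hit] <- 1 - (1 - d_site[hit]) *
          (1 - constrained_regions$deficit[r])
      }
    }
    keep <- ac == 1L | runif(n_sites) >= d_site
    pos <- pos[keep]; true_class <- true_class[keep]; ac <- ac[keep]
    n_sites <- length(pos)
    # alleles
    is_indel <- runif(n_sites) < config$indel_fraction
    ref <- substring(seq, pos, pos)
    alt <- character(n_sites)
    snv <- !is_indel
    alt[snv] <- mutate_base(ref[snv], config$transition_prob)
    if (any(is_indel)) {
      ins <- runif(sum(is_indel)) < 0.5
      len <- sample.int(6L, sum(is_indel), replace = TRUE)
      idx <- which(is_indel)
      # insertions: REF = anchor base, ALT = anchor + random bases
      # deletions:  REF = anchor + following bases, ALT = anchor base
      for (k in seq_along(idx)) {
        p <- pos[idx[k]]
        if (ins[k]) {
          alt[idx[k]] <- paste0(ref[idx[k]],
                                paste(sample(BASES, len[k], replace = TRUE),
                                      collapse = ""))
        } else {
          ref[idx[k]] <- substring(seq, p, p + len[k])
          alt[idx[k]] <- substring(seq, p, p)
        }
      }
    }
    geno <- NULL
    if (genotypes) {
      geno <- matrix(0L, nrow = n_sites, ncol = n)
      for (s in seq_len(n_sites)) {
        chrom_idx <- sample.int(an, ac[s])
        geno[s, ] <- tabulate((chrom_idx + 1L) %/% 2L, nbins = n)
      }
    }
    sites <- data.table::data.table(
      contig = contig, pos = pos,
      id = sprintf("var%06d", seq_len(n_sites)),
      ref = ref, alt = alt, ac = ac, an = an, af = ac / an,
      true_class = true_class, is_indel = is_indel)
    samples <- generate_sample_metadata(n, config$seed + 3L)
    structure(list(sites = sites, geno = geno, samples = samples,
                   config = config),
              class = "cohort")
  })
}

empty_cohort <- function(config) {
  structure(list(
    sites = data.table::data.table(contig = character(), pos = integer(),
                                   id = character(), ref = character(),
                                   alt = character(), ac = integer(),
                                   an = integer(), af = numeric(),
                                   true_class = character(),
                                   is_indel = logical()),
    geno = NULL,
    samples = generate_sample_metadata(config$n_samples, config$seed + 3L),
    config = config), class = "cohort")
}

# substitute each base: transition with probability p_ti, otherwise one of
# the two transversions uniformly
mutate_base <- function(ref, p_ti) {
  TI <- c(A = "G", G = "A", C = "T", T = "C")
  TV <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  n <- length(ref)
  ti <- runif(n) < p_ti
  out <- character(n)
  out[ti] <- TI[ref[ti]]
  if (any(!ti)) {
    pick <- 1L + (runif(sum(!ti)) < 0.5)
    out[!ti] <- mapply(function(r, k) TV[[r]][k], ref[!ti], pick)
  }
  out
}

#' Generate cohort sample metadata
#'
#' Ages around the mid-fifties, 64.8% women, sex-dependent height and
#' weight, and two population labels in equal proportion — the covariate
#' structure the phenotype simulator and PRS adjustment assume.
#'
#' @param n number of samples.
#' @param seed RNG seed.
#' @return data.table: sample_id, age (years), sex (0 = male, 1 = female),
#'   height (cm), weight (kg), population.
#' @export
generate_sample_metadata <- function(n, seed = 1L) {
  with_seed(seed, {
    sex <- rbinom(n, 1L, 0.648)
    age <- round(pmin(pmax(rnorm(n, 54, 10), 30), 85))
    height <- round(rnorm(n, ifelse(sex == 1, 158, 170), 6.5), 1)
    weight <- round(rnorm(n, ifelse(sex == 1, 60, 70), 9), 1)
    data.table::data.table(
      sample_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, height = height, weight = weight,
      population = rep_len(c("north", "south"), n))
  })
}
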