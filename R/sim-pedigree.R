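#' Simulate a cohort with labeled pedigree pairs
#'
#' Founders are drawn in Hardy-Weinberg proportions from uniform(0.05, 0.5)
#' allele frequencies; non-founders are built by Mendelian transmission
#' (each parent transmits one allele per site: a heterozygote transmits
#' either allele with probability 1/2). Duplicate samples are exact genotype
#' copies. A truth table of all labeled pairs is returned for relatedness
#' benchmarking.
#'
#' @param n_founders number of unrelated founders.
#' @param n_sites number of independent biallelic SNPs.
#' @param n_po number of parent-offspring trios to add (each child is a new
#'   sample from two distinct founder parents).
#' @param n_sib number of full-sibling pairs to add (two children per pair
#'   from the same two founder parents).
#' @param n_second number of second-degree (half-sibling) pairs to add.
#' @param n_dup number of duplicate samples to add (copies of founders).
#' @param seed RNG seed.
#' @return list of class `pedigree_cohort`: `geno` (sites x samples dosage
#'   matrix), `samples` (character ids), `af` (true founder allele
#'   frequencies), `pairs` (data.table: id1, id2, relationship in
#'   duplicate/parent_offspring/full_sib/second_degree).
#' @export
simulate_pedigree_cohort <- function(n_founders = 100L, n_sites = 20000L,
                                     n_po = 5L, n_sib = 5L, n_second = 5L,
                                     n_dup = 2L, seed = 1L) {
  if (n_founders < 4) stop("need at least 4 founders")
  with_seed(seed, {
    p <- runif(n_sites, 0.05, 0.5)
    founders <- matrix(rbinom(n_sites * n_founders, 2L, p),
                       nrow = n_sites, ncol = n_founders)
    ids <- sprintf("F%03d", seq_len(n_founders))
    geno_list <- list(founders)
    id_list <- list(ids)
    pairs <- list()

    transmit <- function(g) {
      # one transmitted allele per site from a parent dosage vector
      ifelse(g == 0L, 0L, ifelse(g == 2L, 1L, rbinom(length(g), 1L, 0.5)))
    }
    child_of <- function(i, j) transmit(founders[, i]) + transmit(founders[, j])

    new_cols <- list(); new_ids <- character(0)
    used <- 0L
    next_parents <- function() {
      used <<- used + 2L
      if (used > n_founders) stop("not enough founders for requested pedigree")
      c(used - 1L, used)
    }
    for (k in seq_len(n_po)) {
      pr <- next_parents()
      cid <- sprintf("PO%02d", k)
      new_cols[[length(new_cols) + 1L]] <- child_of(pr[1], pr[2])
      new_ids <- c(new_ids, cid)
      pairs[[length(pairs) + 1L]] <- data.table::data.table(
        id1 = ids[pr[1]], id2 = cid, relationship = "parent_offspring")
    }
    for (k in seq_len(n_sib)) {
      pr <- next_parents()
      c1 <- sprintf("SB%02da", k); c2 <- sprintf("SB%02db", k)
      new_cols[[length(new_cols) + 1L]] <- child_of(pr[1], pr[2])
      new_cols[[length(new_cols) + 1L]] <- child_of(pr[1], pr[2])
      new_ids <- c(new_ids, c1, c2)
      pairs[[length(pairs) + 1L]] <- data.table::data.table(
        id1 = c1, id2 = c2, relationship = "full_sib")
    }
    for (k in seq_len(n_second)) {
      pr <- next_parents()
      extra <- if (used < n_founders) { used <- used + 1L; used } else 1L
      c1 <- sprintf("HS%02da", k); c2 <- sprintf("HS%02db", k)
      new_cols[[length(new_cols) + 1L]] <- child_of(pr[1], pr[2])
      new_cols[[length(new_cols) + 1L]] <- child_of(pr[1], extra)
      new_ids <- c(new_ids, c1, c2)
      pairs[[length(pairs) + 1L]] <- data.table::data.table(
        id1 = c1, id2 = c2, relationship = "second_degree")
    }
    for (k in seq_len(n_dup)) {
      src <- k
      did <- sprintf("DUP%02d", k)
      new_cols[[length(new_cols) + 1L]] <- founders[, src]
      new_ids <- c(new_ids, did)
      pairs[[length(pairs) + 1L]] <- data.table::data.table(
        id1 = ids[src], id2 = did, relationship = "duplicate")
    }
    geno <- cbind(founders,
                  if (length(new_cols)) do.call(cbind, new_cols) else NULL)
    all_ids <- c(ids, new_ids)
    colnames(geno) <- all_ids
    structure(list(geno = geno, samples = all_ids, af = p,
                   founder_ids = ids,
                   pairs = data.table::rbindlist(pairs)),
              class = "pedigree_cohort")
  })
}

#' Simulate a two-population cohort at a target Fst
#'
#' Ancestral allele frequencies are uniform(0.1, 0.9); each subpopulation's
#' frequency is drawn from the Balding-Nichols Beta distribution with mean
#' \eqn{p} and variance \eqn{F p (1 - p)}, i.e.
#' \eqn{Beta(p (1-F)/F, (1-p)(1-F)/F)} with \eqn{F} = `fst_target`.
#' Genotypes are Hardy-Weinberg within each subpopulation.
#'
#' @param n_per_pop samples per population.
#' @param n_sites number of independent biallelic SNPs.
#' @param fst_target Balding-Nichols F in (0, 1).
#' @param seed RNG seed.
#' @return list of class `structured_cohort`: `geno` (sites x samples),
#'   `samples`, `population` (label per sample), `p_anc`, `p_pop` (sites x 2
#'   matrix of realized subpopulation frequencies).
#' @export
simulate_structured_cohort <- function(n_per_pop = 100L, n_sites = 20000L,
                                       fst_target = 0.15, seed = 1L) {
  if (fst_target <= 0 || fst_target >= 1) stop("fst_target must be in (0,1)")
  with_seed(seed, {
    p <- runif(n_sites, 0.1, 0.9)
    shape <- (1 - fst_target) / fst_target
    p1 <- rbeta(n_sites, p * shape, (1 - p) * shape)
    p2 <- rbeta(n_sites, p * shape, (1 - p) * shape)
    g1 <- matrix(rbinom(n_sites * n_per_pop, 2L, p1), nrow = n_sites)
    g2 <- matrix(rbinom(n_sites * n_per_pop, 2L, p2), nrow = n_sites)
    geno <- cbind(g1, g2)
    ids <- c(sprintf("P1_%03d", seq_len(n_per_pop)),
             sprintf("P2_%03d", seq_len(n_per_pop)))
    colnames(geno) <- ids
    structure(list(geno = geno, samples = ids,
                   population = rep(c("pop1", "pop2"), each = n_per_pop),
                   p_anc = p, p_pop = cbind(p1, p2)),
              class = "structured_cohort")
  })
}

#' Simulate pedigree relatedness and population structure together
#'
#' Convenience wrapper returning both a [simulate_pedigree_cohort()] and a
#' [simulate_structured_cohort()] built from one [sim_config()].
#'
#' @param config a [sim_config()].
#' @param n_sites SNPs per component (default 20,000).
#' @return list with elements `pedigree` and `structure`.
#' @export
simulate_relatedness_and_structure <- function(config, n_sites = 20000L) {
  list(
    pedigree = simulate_pedigree_cohort(
      n_founders = max(20L, config$n_samples %/% 5L), n_sites = n_sites,
      seed = config$seed + 4L),
    structure = simulate_structured_cohort(
      n_per_pop = max(50L, config$n_samples %/% 2L), n_sites = n_sites,
      fst_target = config$fst_target, seed = config$seed + 5L)
  )
}
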