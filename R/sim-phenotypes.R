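#' Simulate phenotypes and a discovery-GWAS base summary-statistics table
#'
#' Adds to a simulated cohort (i) a quantitative trait
#' \eqn{y = \sum_j \beta_j g_j + \gamma_1 age + \gamma_2 age^2 + \gamma_3 sex + \epsilon}
#' whose genetic and residual variance components realize the configured
#' heritability \eqn{h^2 = V_G / (V_G + V_\epsilon)}, and (ii) a binary
#' disease from a liability threshold at the configured prevalence (the
#' liability shares the same genetic component). A larger independent
#' discovery cohort is then simulated at the same sites and regressed one
#' variant at a time to produce GWAS base summary statistics for PRS
#' construction.
#'
#' @param cohort a [simulate_cohort_variants()] cohort with genotypes.
#' @param config a [sim_config()] (uses `h2`, `n_causal`, `prevalence`).
#' @param n_discovery discovery-cohort size (default 5000).
#' @param gamma covariate effects `c(age, age2, sex)` on the trait (default
#'   `c(0.02, 0.0002, 0.5)`).
#' @param causal_ids optional variant ids to use as causal (default: sampled
#'   among common sites, AF > 0.05).
#' @return list of class `pheno_sim`: `samples` (metadata + trait, disease),
#'   `base_stats` (data.table: contig, pos, id, effect_allele, other_allele,
#'   beta, se, p), `causal` (data.table: id, beta), `cohort` (input cohort
#'   with phenotypes attached).
#' @export
simulate_phenotypes_and_base_gwas <- function(cohort, config,
                                              n_discovery = 5000L,
                                              gamma = c(0.02, 2e-4, 0.5),
                                              causal_ids = NULL) {
  if (config$h2 < 0 || config$h2 > 1) stop("h2 must be in [0, 1]")
  if (is.null(cohort$geno)) stop("cohort must carry genotypes")
  sites <- cohort$sites
  snv <- !sites$is_indel
  common <- which(snv & sites$af > 0.05 & sites$af < 0.95)
  if (is.null(causal_ids)) {
    if (config$n_causal > length(common)) {
      stop("n_causal exceeds the number of common sites")
    }
  } else if (!all(causal_ids %in% sites$id)) {
    stop("unknown causal variant ids")
  }

  with_seed(config$seed + 6L, {
    causal <- if (is.null(causal_ids)) {
      sort(sample(common, config$n_causal))
    } else match(causal_ids, sites$id)
    m <- length(causal)
    h2 <- config$h2
    beta <- if (m > 0 && h2 > 0) rnorm(m) else numeric(m)
    p_c <- sites$af[causal]

    # scale betas so Var(G) = h2 under HWE dosage variance 2p(1-p),
    # with Var(eps) = 1 - h2
    if (m > 0 && h2 > 0) {
      vg <- sum(beta^2 * 2 * p_c * (1 - p_c))
      if (vg > 0) beta <- beta * sqrt(h2 / vg)
    }
    G_target <- if (m > 0) {
      as.numeric(crossprod(cohort$geno[causal, , drop = FALSE], beta))
    } else rep(0, ncol(cohort$geno))

    meta <- data.table::copy(cohort$samples)
    eps <- rnorm(nrow(meta), 0, sqrt(max(1 - h2, 0)))
    meta[, trait := G_target + gamma[1] * age + gamma[2] * age^2 +
           gamma[3] * sex + eps]
    # liability threshold disease: same genetic component, fresh residual
    liab <- G_target + rnorm(nrow(meta), 0, sqrt(max(1 - h2, 0)))
    thr <- quantile(liab, 1 - config$prevalence)
    meta[, disease := as.integer(liab > thr)]

    # independent discovery cohort, simulated in HWE at the cohort AFs.
    # GWAS base panels carry common variation; restrict to AF >= 0.01 plus
    # the causal sites, and regress in blocks to bound memory.
    disc_idx <- sort(union(which(snv & sites$af >= 0.01 & sites$af <= 0.99),
                           causal))
    pd <- sites$af[disc_idx]
    bd <- numeric(length(disc_idx))
    bd[match(causal, disc_idx)] <- beta
    # genetic values first (only causal sites needed), then per-block stats
    caus_in_disc <- which(bd != 0)
    Gc <- matrix(rbinom(length(caus_in_disc) * n_discovery, 2L,
                        pd[caus_in_disc]),
                 nrow = length(caus_in_disc), ncol = n_discovery)
    yd <- rnorm(n_discovery, 0, sqrt(max(1 - h2, 0)))
    if (length(caus_in_disc)) {
      yd <- yd + as.numeric(crossprod(Gc, bd[caus_in_disc]))
    }
    base <- list(beta = numeric(length(disc_idx)),
                 se = numeric(length(disc_idx)),
                 p = numeric(length(disc_idx)))
    blocks <- split(seq_along(disc_idx),
                    ceiling(seq_along(disc_idx) / 2000))
    for (bl in blocks) {
      in_caus <- match(bl, caus_in_disc)
      Gd <- matrix(rbinom(length(bl) * n_discovery, 2L, pd[bl]),
                   nrow = length(bl))
      hit <- !is.na(in_caus)
      if (any(hit)) Gd[hit, ] <- Gc[in_caus[hit], , drop = FALSE]
      st <- marginal_gwas(Gd, yd)
      base$beta[bl] <- st$beta; base$se[bl] <- st$se; base$p[bl] <- st$p
    }
    base_stats <- data.table::data.table(
      contig = sites$contig[disc_idx], pos = sites$pos[disc_idx],
      id = sites$id[disc_idx],
      effect_allele = sites$alt[disc_idx], other_allele = sites$ref[disc_idx],
      beta = base$beta, se = base$se, p = base$p)
    base_stats <- base_stats[!is.na(beta)]

    out_cohort <- cohort
    out_cohort$samples <- meta
    structure(list(samples = meta, base_stats = base_stats,
                   causal = data.table::data.table(id = sites$id[causal],
                                                   beta = beta),
                   cohort = out_cohort),
              class = "pheno_sim")
  })
}

# Vectorized per-variant simple linear regression y ~ g:
# beta = cov(g,y)/var(g), se from residual variance, two-sided t p-value.
marginal_gwas <- function(G, y) {
  n <- length(y)
  yc <- y - mean(y)
  gm <- rowMeans(G)
  Gc_y <- as.numeric(G %*% yc) - gm * sum(yc)     # sum over samples of (g-gm)*yc
  ssg <- rowSums(G^2) - n * gm^2
  beta <- Gc_y / ssg
  sst <- sum(yc^2)
  sse <- sst - beta * Gc_y
  df <- n - 2L
  se <- sqrt(pmax(sse, 0) / df / ssg)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  mono <- ssg <= 0
  beta[mono] <- NA_real_; se[mono] <- NA_real_; p[mono] <- NA_real_
  list(beta = beta, se = se, p = p)
}
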