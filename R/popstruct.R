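# popstruct module: SNP pruning, PCA, Hudson pairwise Fst and PLINK-style
# IBD/PI_HAT relatedness with the unrelated-set cut.

#' SNP pruning configuration
#'
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param call_rate_min minimum genotyping rate (default 0.90).
#' @param hwe_p_min exclusive minimum HWE exact p (default 1e-6).
#' @param r2_max r-squared at or above which one SNP of a pair is removed
#'   (default 0.5).
#' @param window_snps,step_snps pruning window of 50 SNPs sliding by 5.
#' @return list of class `prune_config`.
#' @export
prune_config <- function(maf_min = 0.01, call_rate_min = 0.90,
                         hwe_p_min = 1e-6, r2_max = 0.5,
                         window_snps = 50L, step_snps = 5L) {
  stopifnot(maf_min > 0, maf_min < 0.5, r2_max > 0, r2_max <= 1,
            step_snps <= window_snps)
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, r2_max = r2_max,
                 window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps)),
            class = "prune_config")
}

#' Prune SNPs by MAF, call rate, HWE and windowed LD
#'
#' Applies the marginal filters, then slides a `window_snps`-wide window by
#' `step_snps` over the surviving SNPs (genomic order): within each window,
#' for every pair with r-squared >= `r2_max` the LATER SNP is removed
#' (deterministic tie-break).
#'
#' @param geno dosage matrix (SNPs x samples); rownames used as SNP ids.
#' @param config a [prune_config()].
#' @param positions optional integer positions for ordering (default: row
#'   order).
#' @return integer vector of retained row indices (named by SNP id when
#'   rownames exist).
#' @export
prune_snps <- function(geno, config = prune_config(), positions = NULL) {
  n <- ncol(geno)
  called <- !is.na(geno)
  an <- 2L * rowSums(called)
  ac <- rowSums(geno, na.rm = TRUE)
  af <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(af, 1 - af)
  rate <- rowMeans(called)
  n0 <- rowSums(geno == 0L, na.rm = TRUE)
  n1 <- rowSums(geno == 1L, na.rm = TRUE)
  n2 <- rowSums(geno == 2L, na.rm = TRUE)
  hwe <- rep(NA_real_, nrow(geno))
  nz <- an > 0
  hwe[nz] <- hwe_exact_test(n0[nz], n1[nz], n2[nz])
  keep <- which(!is.na(maf) & maf >= config$maf_min &
                  rate >= config$call_rate_min &
                  !is.na(hwe) & hwe > config$hwe_p_min)
  if (length(keep) < 2) stop("fewer than 2 SNPs pass the marginal filters")
  if (!is.null(positions)) keep <- keep[order(positions[keep])]
  alive <- rep(TRUE, length(keep))
  gk <- geno[keep, , drop = FALSE]
  w <- config$window_snps; s <- config$step_snps
  start <- 1L
  repeat {
    idx <- which(alive)
    idx <- idx[idx >= start & idx < start + w]
    if (length(idx) > 1) {
      cc <- suppressWarnings(stats::cor(t(gk[idx, , drop = FALSE]),
                                        use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      for (a in seq_along(idx)) {
        if (!alive[idx[a]]) next
        hits <- which(r2[a, ] >= config$r2_max)
        hits <- hits[hits > a & alive[idx[hits]]]
        if (length(hits)) alive[idx[hits]] <- FALSE
      }
    }
    if (start + w > length(keep)) break
    start <- start + s
  }
  keep[alive]
}

#' Principal component analysis of a genotype matrix
#'
#' Sites are centered by 2\eqn{\hat p} and scaled by
#' \eqn{\sqrt{2 \hat p (1 - \hat p)}}; monomorphic sites are dropped with a
#' warning; missing dosages contribute 0 after centering. The top-k
#' right-singular vectors give sample coordinates; each PC's sign is fixed
#' so its largest-magnitude loading is positive.
#'
#' @param geno dosage matrix (SNPs x samples).
#' @param k number of components (default 10, capped at n_samples - 1).
#' @return list of class `pca_result`: `coords` (samples x k),
#'   `explained` (variance fractions), `d` (singular values).
#' @export
run_pca <- function(geno, k = 10L) {
  n <- ncol(geno)
  if (k >= n) k <- n - 1L
  p <- rowMeans(geno, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic sites dropped")
    geno <- geno[poly, , drop = FALSE]
    p <- p[poly]
  }
  X <- (geno - 2 * p) / sqrt(2 * p * (1 - p))
  X[is.na(X)] <- 0
  sv <- svd(X, nu = 0, nv = k)
  coords <- sv$v %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PC", seq_len(k))
  rownames(coords) <- colnames(geno)
  explained <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  structure(list(coords = coords, explained = explained, d = sv$d),
            class = "pca_result")
}

# Hudson Fst components for one pair of AF/size vectors
hudson_components <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Pairwise Hudson Fst between labeled populations
#'
#' Ratio-of-averages Hudson estimator: per site the numerator
#' \eqn{(p_1 - p_2)^2 - p_1(1-p_1)/(n_1 - 1) - p_2(1-p_2)/(n_2 - 1)} and
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)} are computed from sample
#' allele frequencies and HAPLOID sample sizes, and Fst is the ratio of
#' their sums over sites. Small negative estimates are possible and
#' flagged.
#'
#' @param geno dosage matrix (SNPs x samples).
#' @param populations label per sample (>= 2 samples per label).
#' @return data.table of class `fst_table`: pop1, pop2, fst, n_sites,
#'   negative_flag.
#' @export
pairwise_fst <- function(geno, populations) {
  labs <- sort(unique(populations))
  if (length(labs) < 2) stop("need >= 2 populations")
  stats_by_pop <- lapply(labs, function(l) {
    g <- geno[, populations == l, drop = FALSE]
    if (ncol(g) < 2) stop("population ", l, " has < 2 samples")
    called <- !is.na(g)
    nhap <- 2 * rowSums(called)
    if (all(nhap == 0)) stop("population ", l, " has zero called alleles")
    list(p = rowSums(g, na.rm = TRUE) / nhap, n = nhap)
  })
  names(stats_by_pop) <- labs
  out <- list()
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      a <- stats_by_pop[[i]]; b <- stats_by_pop[[j]]
      ok <- a$n > 2 & b$n > 2 & !is.na(a$p) & !is.na(b$p)
      hc <- hudson_components(a$p[ok], b$p[ok], a$n[ok], b$n[ok])
      fst <- sum(hc$num) / sum(hc$den)
      out[[length(out) + 1L]] <- data.table::data.table(
        pop1 = labs[i], pop2 = labs[j], fst = fst, n_sites = sum(ok),
        negative_flag = fst < 0)
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "class", c("fst_table", class(res)))
  res
}

# Per-site finite-sample expectations of IBS-class probabilities given IBD
# state, from without-replacement draws of 4 (IBD0) or 3 (IBD1) alleles out
# of the 2N observed (the method-of-moments bias correction).
ibs_expectations <- function(ac, an) {
  x <- ac; y <- an - ac; t <- an
  f2 <- function(v) v * (v - 1)
  f3 <- function(v) v * (v - 1) * (v - 2)
  t4 <- t * (t - 1) * (t - 2) * (t - 3)
  t3 <- t * (t - 1) * (t - 2)
  t2 <- t * (t - 1)
  e00 <- 2 * f2(x) * f2(y) / t4
  e01 <- (4 * f3(x) * y + 4 * f3(y) * x) / t4
  e02 <- 1 - e00 - e01
  e11 <- 2 * x * y / t2
  e12 <- 1 - e11
  list(e00 = e00, e01 = e01, e02 = e02, e11 = e11, e12 = e12)
}

#' PLINK-style IBD estimation and the unrelated sample set
#'
#' For every sample pair, counts sites by identity-by-state (IBS 0/1/2) and
#' inverts the method-of-moments system against the expected IBS-class
#' probabilities under IBD 0/1/2 (computed from cohort allele counts with
#' finite-sample, without-replacement corrections). Probabilities are
#' clipped to [0,1] and renormalized; PI_HAT = P(IBD=2) + P(IBD=1)/2. The
#' unrelated set greedily removes the sample with the most relationships at
#' PI_HAT >= `threshold` until no related pair remains.
#'
#' @param geno dosage matrix of pruned common SNPs (SNPs x samples).
#' @param threshold relatedness cut on PI_HAT (default 0.1875, separating
#'   2nd- from 3rd-degree relatives).
#' @param sample_ids ids (default colnames).
#' @return list of class `ibd_result`: `pairs` (data.table: id1, id2, P0,
#'   P1, P2, pi_hat, is_related), `unrelated` (character ids).
#' @export
estimate_ibd_and_unrelated <- function(geno, threshold = 0.1875,
                                       sample_ids = colnames(geno)) {
  n <- ncol(geno)
  if (n < 2) stop("need >= 2 samples")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  called <- !is.na(geno)
  an <- 2 * rowSums(called)
  ac <- rowSums(geno, na.rm = TRUE)
  usable <- an >= 4 & ac > 0 & ac < an
  g <- geno[usable, , drop = FALSE]
  ex <- ibs_expectations(ac[usable], an[usable])
  E00 <- sum(ex$e00); E01 <- sum(ex$e01); E02 <- sum(ex$e02)
  E11 <- sum(ex$e11); E12 <- sum(ex$e12)
  m <- nrow(g)
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    gi <- g[, i]
    d <- abs(g[, (i + 1L):n, drop = FALSE] - gi)
    # IBS = 2 - |dosage difference|, except |d| = 0 with opposite homozygotes
    # cannot occur (|d| = 2 covers that); missing handled upstream
    n_ibs0 <- colSums(d == 2L, na.rm = TRUE)
    n_ibs1 <- colSums(d == 1L, na.rm = TRUE)
    n_obs <- colSums(!is.na(d))
    n_ibs2 <- n_obs - n_ibs0 - n_ibs1
    scale <- n_obs / m
    p0 <- n_ibs0 / (E00 * scale)
    p1 <- (n_ibs1 - p0 * E01 * scale) / (E11 * scale)
    p2 <- (n_ibs2 - p0 * E02 * scale - p1 * E12 * scale) / n_obs
    p0 <- pmin(pmax(p0, 0), 1)
    p1 <- pmin(pmax(p1, 0), 1)
    p2 <- pmin(pmax(p2, 0), 1)
    tot <- p0 + p1 + p2
    p0 <- p0 / tot; p1 <- p1 / tot; p2 <- p2 / tot
    pairs[[i]] <- data.table::data.table(
      id1 = sample_ids[i], id2 = sample_ids[(i + 1L):n],
      P0 = p0, P1 = p1, P2 = p2, pi_hat = p2 + p1 / 2)
  }
  pairs <- data.table::rbindlist(pairs)
  pairs[, is_related := pi_hat >= threshold]
  # greedy unrelated set
  ids <- sample_ids
  rel <- pairs[is_related == TRUE, .(id1, id2)]
  while (nrow(rel) > 0) {
    counts <- table(c(rel$id1, rel$id2))
    worst <- names(counts)[which.max(counts)]
    ids <- setdiff(ids, worst)
    rel <- rel[id1 != worst & id2 != worst]
  }
  structure(list(pairs = pairs, unrelated = ids, threshold = threshold),
            class = "ibd_result")
}
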