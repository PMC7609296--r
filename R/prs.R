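# prs module: base-summary harmonization, LD clumping, scoring with
# covariate adjustment, top/median/tail stratification and disease-risk
# metrics.

#' Harmonize GWAS base summary statistics against target sites
#'
#' Keeps genome-wide significant variants (p < `p_threshold`), drops
#' strand-ambiguous A/T and C/G SNPs, and matches the remainder to the
#' target sites by position and allele pair: when the base effect allele is
#' the target ALT the weight is kept as-is, when it is the target REF the
#' beta sign is flipped. Unmatched variants are dropped with a tally.
#' Inputs must share one coordinate system (no liftover is attempted).
#'
#' @param base data.table: contig, pos, effect_allele, other_allele, beta,
#'   se, p.
#' @param target data.table of target sites: contig, pos, id, ref, alt.
#' @param p_threshold significance cutoff, exclusive (default 5e-8).
#' @return data.table of matched weights (contig, pos, id, effect_allele =
#'   target alt, beta, p) with a `tally` attribute (data.table: step, n).
#' @export
harmonize_base_stats <- function(base, target, p_threshold = 5e-8) {
  b <- data.table::as.data.table(base)
  n0 <- nrow(b)
  b <- b[p < p_threshold]
  n_sig <- nrow(b)
  ambiguous <- (b$effect_allele == "A" & b$other_allele == "T") |
    (b$effect_allele == "T" & b$other_allele == "A") |
    (b$effect_allele == "C" & b$other_allele == "G") |
    (b$effect_allele == "G" & b$other_allele == "C")
  b <- b[!ambiguous]
  n_unamb <- nrow(b)
  b <- b[, .(contig, pos, effect_allele, other_allele, beta, p)]
  tg <- data.table::as.data.table(target)[, .(contig, pos, id, ref, alt)]
  m <- merge(b, tg, by = c("contig", "pos"))
  keep_as_is <- m$effect_allele == m$alt & m$other_allele == m$ref
  flip <- m$effect_allele == m$ref & m$other_allele == m$alt
  m[, beta_alt := data.table::fifelse(keep_as_is, beta,
                                      data.table::fifelse(flip, -beta,
                                                          NA_real_))]
  m <- m[!is.na(beta_alt)]
  out <- m[, .(contig, pos, id, effect_allele = alt, beta = beta_alt, p)]
  if (nrow(out) == 0) stop("no scorable variants after harmonization")
  data.table::setattr(out, "tally", data.table::data.table(
    step = c("input", "significant", "strand_unambiguous", "matched"),
    n = c(n0, n_sig, n_unamb, nrow(out))))
  out
}

#' Greedy LD clumping of matched weights
#'
#' Processes variants in ascending p-value order: each kept index variant
#' removes every remaining variant within `window_kb` whose squared dosage
#' correlation with it exceeds `r2_threshold`. Ties in p are broken by
#' genomic position, so the output is deterministic. Monomorphic variants
#' have undefined r2, treated as 0 (flagged).
#'
#' @param weights harmonized weights ([harmonize_base_stats()]).
#' @param geno dosage matrix (variants x samples) with rownames = variant
#'   id, supplying the LD reference.
#' @param r2_threshold r-squared cutoff (default 0.1).
#' @param window_kb window half-width in kb (default 250).
#' @return the retained subset of `weights` (index variants).
#' @export
ld_clump <- function(weights, geno, r2_threshold = 0.1, window_kb = 250) {
  w <- data.table::as.data.table(weights)
  g <- geno[w$id, , drop = FALSE]
  ord <- order(w$p, w$contig, w$pos)
  alive <- rep(TRUE, nrow(w))
  kept <- logical(nrow(w))
  win <- window_kb * 1000
  gv <- apply(g, 1, stats::var)
  for (k in ord) {
    if (!alive[k]) next
    kept[k] <- TRUE
    alive[k] <- FALSE
    near <- which(alive & w$contig == w$contig[k] &
                    abs(w$pos - w$pos[k]) <= win)
    if (!length(near)) next
    r2 <- rep(0, length(near))
    if (gv[k] > 0) {
      ok <- gv[near] > 0
      if (any(ok)) {
        r2[ok] <- suppressWarnings(
          cor(g[k, ], t(g[near[ok], , drop = FALSE])))^2
      }
    }
    alive[near[r2 > r2_threshold]] <- FALSE
  }
  w[kept]
}

#' Compute and covariate-adjust polygenic risk scores
#'
#' Raw score per sample = sum of beta x alt-allele dosage over the index
#' variants; missing dosages are mean-imputed at 2 x AF (logged per
#' variant). The adjusted score is the residual of the raw score regressed
#' on age, age^2, sex and the first two ancestry PCs. Samples are grouped
#' by adjusted score: top 10%, tail (bottom) 10%, median (rest).
#'
#' @param weights index-variant weights (id, beta).
#' @param geno dosage matrix (variants x samples, rownames = id).
#' @param covariates data.table with sample_id, age, sex and (optionally)
#'   PC1, PC2 — column order must match `geno` columns.
#' @return data.table of class `prs_result`: sample_id, raw, adjusted,
#'   group.
#' @export
compute_and_adjust_prs <- function(weights, geno, covariates) {
  g <- geno[weights$id, , drop = FALSE]
  af <- rowMeans(g, na.rm = TRUE) / 2
  n_imp <- rowSums(is.na(g))
  if (any(n_imp > 0)) {
    message(sum(n_imp > 0), " variants had missing dosages; mean-imputed")
    for (r in which(n_imp > 0)) g[r, is.na(g[r, ])] <- 2 * af[r]
  }
  raw <- as.numeric(crossprod(g, weights$beta))
  cov <- data.table::as.data.table(covariates)
  if (nrow(cov) != length(raw)) stop("covariate rows must match samples")
  X <- data.frame(age = cov$age, age2 = cov$age^2, sex = cov$sex)
  if (all(c("PC1", "PC2") %in% names(cov))) {
    X$PC1 <- cov$PC1; X$PC2 <- cov$PC2
  }
  fit <- stats::lm(raw ~ ., data = cbind(raw = raw, X))
  adjusted <- stats::resid(fit)
  res <- data.table::data.table(sample_id = cov$sample_id, raw = raw,
                                adjusted = adjusted)
  res[, group := prs_groups(adjusted)]
  data.table::setattr(res, "class", c("prs_result", class(res)))
  res
}

# top/tail 10% by adjusted score (ties broken by order), median = rest
prs_groups <- function(score) {
  n <- length(score)
  k <- round(0.10 * n)
  rk <- rank(score, ties.method = "first")
  data.table::fcase(rk > n - k, "top", rk <= k, "tail", default = "median")
}

#' Compare trait across PRS groups
#'
#' Per-group mean/sd/n for a quantitative trait and the two-tailed Welch
#' t-test of top vs tail.
#'
#' @param result [compute_and_adjust_prs()] output.
#' @param trait numeric trait aligned to `result` rows (NAs allowed for up
#'   to 10% of samples).
#' @return list of class `prs_group_test`: `groups` (data.table), `t`, `p`,
#'   `direction` (sign of top mean - tail mean).
#' @export
stratify_and_test <- function(result, trait) {
  if (mean(is.na(trait)) > 0.10) stop("trait missing for > 10% of samples")
  d <- data.table::data.table(group = result$group, trait = trait)
  d <- d[!is.na(trait)]
  groups <- d[, .(mean = mean(trait), sd = stats::sd(trait), n = .N),
              by = group]
  top <- d[group == "top", trait]
  tail_ <- d[group == "tail", trait]
  if (length(top) < 2 || length(tail_) < 2) stop("group n < 2")
  tt <- stats::t.test(top, tail_)
  structure(list(groups = groups, t = unname(tt$statistic), p = tt$p.value,
                 direction = sign(mean(top) - mean(tail_))),
            class = "prs_group_test")
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' @param score numeric predictor.
#' @param status binary outcome (0/1).
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(score, status) {
  status <- as.integer(status)
  n1 <- sum(status == 1L); n0 <- sum(status == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Disease-risk metrics for the top PRS decile
#'
#' Logistic regression of disease status on the top-decile indicator plus
#' covariates; the top-decile odds ratio with its Wald 95% CI, and the AUC
#' of the adjusted score against status.
#'
#' @param result [compute_and_adjust_prs()] output.
#' @param status binary disease status aligned to `result`.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list of class `prs_risk`: `or`, `ci` (length-2), `p`, `auc`,
#'   `estimable` (FALSE with a message when a stratum has no cases).
#' @export
disease_risk_metrics <- function(result, status, covariates = NULL) {
  top <- as.integer(result$group == "top")
  status <- as.integer(status)
  if (length(unique(status[top == 1L])) < 2 ||
      length(unique(status[top == 0L])) < 2) {
    message("a stratum has no cases or no controls; OR not estimable")
    return(structure(list(or = NA_real_, ci = c(NA_real_, NA_real_),
                          p = NA_real_,
                          auc = rank_auc(result$adjusted, status),
                          estimable = FALSE), class = "prs_risk"))
  }
  dat <- data.frame(status = status, top = top)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- stats::glm(status ~ ., family = stats::binomial(), data = dat)
  est <- stats::coef(fit)["top"]
  se <- sqrt(diag(stats::vcov(fit))["top"])
  z <- est / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  auc <- rank_auc(result$adjusted, status)
  boundary <- auc >= 1 - 1e-12
  structure(list(or = exp(unname(est)),
                 ci = exp(unname(est) + c(-1, 1) * 1.96 * unname(se)),
                 p = unname(p), auc = auc, estimable = TRUE,
                 separation_flag = boundary),
            class = "prs_risk")
}
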