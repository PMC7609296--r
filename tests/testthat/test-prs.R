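# small deterministic scoring fixture: 6 variants x 8 samples
make_prs_fixture <- function(seed = 71) {
  set.seed(seed)
  n <- 8L
  target <- data.table::data.table(
    contig = "chr1", pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    id = paste0("v", 1:6),
    ref = c("A", "C", "G", "T", "A", "C"),
    alt = c("G", "T", "A", "C", "C", "A"))
  geno <- matrix(sample(0:2, 6 * n, replace = TRUE), nrow = 6,
                 dimnames = list(target$id, paste0("s", 1:n)))
  base <- data.table::data.table(
    contig = "chr1", pos = target$pos,
    effect_allele = c("G", "C", "A", "C", "C", "T"),  # v2 flipped, v6 bogus
    other_allele = c("A", "T", "G", "T", "A", "G"),
    beta = c(0.5, -0.2, 0.1, 0.4, 0.3, 0.9),
    se = 0.01, p = c(1e-10, 1e-12, 1e-9, 1e-7, 1e-20, 1e-15))
  list(target = target, geno = geno, base = base)
}

test_that("harmonization enforces significance, strand and orientation rules", {
  fx <- make_prs_fixture()
  w <- harmonize_base_stats(fx$base, fx$target)
  # v4: p = 1e-7 >= 5e-8 -> excluded
  expect_false("v4" %in% w$id)
  # v3 (G>A base = strand-ambiguous C/G? no: effect A other G -> ambiguous
  # pair A/T? no) kept; v5 is A/C in target and effect C other A -> kept
  # v6 allele pair mismatches the target -> dropped
  expect_false("v6" %in% w$id)
  # v1 effect allele = target alt: beta unchanged
  expect_equal(w[id == "v1", beta], 0.5)
  # v2 effect allele = target ref: beta sign flipped
  expect_equal(w[id == "v2", beta], 0.2)
  tally <- attr(w, "tally")
  expect_equal(tally[step == "input", n], 6)

  # A/T and C/G SNPs are excluded however significant
  at_base <- data.table::data.table(contig = "chr1", pos = 700L,
                                    effect_allele = "A", other_allele = "T",
                                    beta = 1, se = 0.01, p = 1e-20)
  at_target <- data.table::data.table(contig = "chr1", pos = 700L, id = "at",
                                      ref = "T", alt = "A")
  expect_error(harmonize_base_stats(at_base, at_target), "no scorable")
})

test_that("scoring is invariant to allele-orientation relabeling", {
  fx <- make_prs_fixture()
  w <- harmonize_base_stats(fx$base, fx$target)
  covar <- data.table::data.table(sample_id = colnames(fx$geno),
                                  age = c(40, 50, 60, 45, 55, 65, 50, 42),
                                  sex = c(0, 1, 0, 1, 0, 1, 0, 1))
  r1 <- compute_and_adjust_prs(w, fx$geno, covar)
  # flip every target site: ref<->alt, dosage 2-d, beta -> -beta
  target2 <- data.table::copy(fx$target)
  target2[, `:=`(ref = alt, alt = ref)]
  base2 <- data.table::copy(fx$base)
  geno2 <- 2L - fx$geno
  w2 <- harmonize_base_stats(base2, target2)
  r2 <- compute_and_adjust_prs(w2, geno2, covar)
  # raw scores shift by a constant (2 * sum beta); adjusted are identical
  expect_lt(max(abs((r1$raw - mean(r1$raw)) - (r2$raw - mean(r2$raw)))),
            1e-12)
  expect_lt(max(abs(r1$adjusted - r2$adjusted)), 1e-12)
})

test_that("LD clumping keeps the best of correlated variants", {
  set.seed(81)
  n <- 60
  g1 <- sample(0:2, n, replace = TRUE)
  geno <- rbind(v1 = g1, v2 = g1, v3 = sample(0:2, n, replace = TRUE))
  w <- data.table::data.table(contig = "chr1", pos = c(1000L, 2000L, 3000L),
                              id = c("v1", "v2", "v3"),
                              effect_allele = "A",
                              beta = 1, p = c(1e-20, 1e-9, 1e-10))
  kept <- ld_clump(w, geno)
  expect_true("v1" %in% kept$id)    # best p of the duplicated pair
  expect_false("v2" %in% kept$id)
  expect_true("v3" %in% kept$id)    # unlinked survives

  # far-apart duplicates survive (outside the window)
  w2 <- data.table::copy(w)
  w2[id == "v2", pos := 300000000L]
  expect_equal(nrow(ld_clump(w2, geno)), 3L)
})

test_that("clumped sets pass the exhaustive post-scan oracle", {
  set.seed(83)
  m <- 200; n <- 100
  block <- sample(0:2, n, replace = TRUE)
  geno <- t(sapply(seq_len(m), function(i) {
    if (i %% 4 == 0) {
      flip <- runif(n) < 0.05
      ifelse(flip, sample(0:2, n, replace = TRUE), block)
    } else sample(0:2, n, replace = TRUE)
  }))
  rownames(geno) <- paste0("v", seq_len(m))
  w <- data.table::data.table(contig = "chr1",
                              pos = sort(sample(1:500000, m)),
                              id = rownames(geno), effect_allele = "A",
                              beta = 1, p = runif(m))
  kept <- ld_clump(w, geno, r2_threshold = 0.1, window_kb = 250)
  g <- geno[kept$id, ]
  for (i in seq_len(nrow(g) - 1)) {
    for (j in (i + 1):nrow(g)) {
      if (kept$contig[i] == kept$contig[j] &&
          abs(kept$pos[i] - kept$pos[j]) <= 250000) {
        expect_lte(suppressWarnings(cor(g[i, ], g[j, ]))^2, 0.1)
      }
    }
  }
})

test_that("raw scores, imputation and covariate adjustment behave", {
  fx <- make_prs_fixture()
  w1 <- data.table::data.table(id = "v1", beta = 1)
  covar <- data.table::data.table(sample_id = colnames(fx$geno),
                                  age = seq(40, 75, by = 5), sex = rep(0:1, 4))
  r <- compute_and_adjust_prs(w1, fx$geno, covar)
  expect_equal(r$raw, unname(fx$geno["v1", ]))
  # missing dosage mean-imputed at 2*AF
  g2 <- fx$geno
  g2["v1", 1] <- NA
  expect_message(r2 <- compute_and_adjust_prs(w1, g2, covar), "imputed")
  expect_equal(r2$raw[1], 2 * mean(g2["v1", -1]) / 2)
  # residual orthogonality to every covariate
  w <- harmonize_base_stats(fx$base, fx$target)
  set.seed(9)
  big_geno <- matrix(sample(0:2, nrow(w) * 200, replace = TRUE),
                     nrow = nrow(w), dimnames = list(w$id, NULL))
  big_covar <- data.table::data.table(sample_id = sprintf("t%03d", 1:200),
                                      age = sample(35:75, 200, TRUE),
                                      sex = sample(0:1, 200, TRUE),
                                      PC1 = rnorm(200), PC2 = rnorm(200))
  rb <- compute_and_adjust_prs(w, big_geno, big_covar)
  for (v in list(big_covar$age, big_covar$age^2, big_covar$sex,
                 big_covar$PC1, big_covar$PC2)) {
    expect_lt(abs(cor(rb$adjusted, v)), 1e-8)
  }
  # group sizes: top = tail = 10%
  expect_equal(sum(rb$group == "top"), 20L)
  expect_equal(sum(rb$group == "tail"), 20L)
})

test_that("group testing detects signal and is exact under symmetry", {
  set.seed(91)
  res <- data.table::data.table(
    sample_id = sprintf("s%03d", 1:500),
    raw = rnorm(500), adjusted = rnorm(500))
  res[, group := varcohort:::prs_groups(adjusted)]
  st <- stratify_and_test(res, res$adjusted + rnorm(500, 0, 0.05))
  expect_lt(st$p, 1e-6)
  expect_equal(st$direction, 1)
  expect_equal(st$groups[, sum(n)], 500L)

  # identical top/tail trait multisets give t = 0
  trait <- numeric(500)
  trait[res$group == "top"] <- rep(c(0, 1), 25)
  trait[res$group == "tail"] <- rep(c(0, 1), 25)
  st0 <- stratify_and_test(res, trait)
  expect_equal(st0$t, 0)
  expect_error(stratify_and_test(res, c(rep(NA, 100), res$adjusted[-(1:100)])),
               "10%")
})

test_that("AUC equals the Mann-Whitney identity and external oracle", {
  set.seed(93)
  score <- rnorm(300)
  status <- rbinom(300, 1, plogis(score))
  auc <- rank_auc(score, status)
  wt <- wilcox.test(score[status == 1], score[status == 0], exact = FALSE)
  expect_equal(auc,
               unname(wt$statistic) / (sum(status == 1) * sum(status == 0)),
               tolerance = 1e-12)
  expect_equal(auc, as.numeric(suppressMessages(
    pROC::auc(pROC::roc(status, score, quiet = TRUE)))), tolerance = 1e-12)
})

test_that("disease risk metrics flag separation and non-estimable strata", {
  set.seed(95)
  res <- data.table::data.table(sample_id = sprintf("s%03d", 1:400),
                                raw = rnorm(400), adjusted = rnorm(400))
  res[, group := varcohort:::prs_groups(adjusted)]
  status_sep <- as.integer(res$adjusted > quantile(res$adjusted, 0.9))
  dr <- disease_risk_metrics(res, status_sep)
  expect_gt(dr$auc, 0.99)
  status_none <- rep(0L, 400)
  status_none[res$group != "top"][1:30] <- 1L
  expect_message(dr0 <- disease_risk_metrics(res, status_none), "estimable")
  expect_false(dr0$estimable)
})
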