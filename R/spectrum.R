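# cohort_spectrum module: site normalization, QC filters, frequency-class
# spectrum, mutation spectrum and per-sample metrics.

#' Normalize VCF records into biallelic site records
#'
#' Splits multiallelic records into one record per alternate allele
#' (recomputing AC/AN/AF per alt from the genotypes), drops records with
#' more than `max_alts` alternate alleles, drops indel alleles whose
#' ref/alt length difference exceeds `max_indel_len` bp, and minimizes
#' alleles by trimming the shared suffix then the shared prefix (keeping a
#' 1-base anchor). Per-site genotyping rate and the Hardy-Weinberg exact
#' p-value are attached. Malformed genotypes are treated as missing, never
#' fatal.
#'
#' @param cohort a `cohort` from [read_cohort_vcf()] or
#'   [simulate_cohort_variants()].
#' @param max_indel_len maximum ref/alt length difference (default 10).
#' @param max_alts maximum alternate alleles per input record (default 10).
#' @return a `cohort` whose `sites` are biallelic records with columns
#'   multiallelic, genotyping_rate, hwe_p, plus a `dropped` attribute
#'   (data.table: id, reason) tallying removed alleles.
#' @export
normalize_sites <- function(cohort, max_indel_len = 10L, max_alts = 10L) {
  sites <- cohort$sites
  geno <- cohort$geno
  gt_raw <- cohort$gt_raw
  n_alts <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  dropped <- list()

  # fast path: already-biallelic cohort with a dosage matrix (the common
  # case for generator output) — fully vectorized
  if (all(n_alts == 1L) && is.null(gt_raw)) {
    keep <- abs(nchar(sites$ref) - nchar(sites$alt)) <= max_indel_len
    new_sites <- sites[keep]
    new_geno <- if (!is.null(geno)) geno[keep, , drop = FALSE] else NULL
    if (!is.null(new_geno)) {
      called <- !is.na(new_geno)
      an <- 2L * rowSums(called)
      ac <- as.integer(rowSums(new_geno, na.rm = TRUE))
      n0 <- rowSums(new_geno == 0L, na.rm = TRUE)
      n1 <- rowSums(new_geno == 1L, na.rm = TRUE)
      n2 <- rowSums(new_geno == 2L, na.rm = TRUE)
      hwe <- rep(NA_real_, length(an))
      nz <- an > 0L
      if (any(nz)) hwe[nz] <- hwe_exact_test(n0[nz], n1[nz], n2[nz])
      new_sites[, `:=`(ac = ac, an = an,
                       af = ifelse(an > 0, ac / an, NA_real_),
                       genotyping_rate = rowMeans(called),
                       hwe_p = hwe)]
    } else {
      new_sites[, `:=`(genotyping_rate = NA_real_, hwe_p = NA_real_)]
    }
    if (!"is_indel" %in% names(sites)) {
      new_sites[, is_indel := nchar(ref) != nchar(alt)]
    }
    new_sites[, multiallelic := FALSE]
    res <- cohort
    res$sites <- new_sites
    res$geno <- new_geno
    data.table::setattr(res$sites, "dropped", data.table::data.table(
      id = sites$id[!keep], reason = rep("length>10", sum(!keep))))
    return(res)
  }

  keep_rec <- n_alts <= max_alts
  if (any(!keep_rec)) {
    dropped[[length(dropped) + 1L]] <- data.table::data.table(
      id = sites$id[!keep_rec], reason = "alts>10")
  }

  out <- vector("list", nrow(sites))
  out_geno <- vector("list", nrow(sites))
  for (r in which(keep_rec)) {
    alts <- strsplit(sites$alt[r], ",", fixed = TRUE)[[1]]
    multi <- length(alts) > 1L
    if (!multi && !is.null(geno) && is.null(gt_raw)) {
      dos_list <- list(geno[r, ])
    } else if (!is.null(gt_raw)) {
      a1 <- substr(gt_raw[r, ], 1, 1); a2 <- substr(gt_raw[r, ], 3, 3)
      dos_list <- lapply(seq_along(alts), function(k) {
        ok <- a1 %in% as.character(0:9) & a2 %in% as.character(0:9)
        d <- (a1 == as.character(k)) + (a2 == as.character(k))
        d[!ok] <- NA_integer_
        as.integer(d)
      })
    } else if (!is.null(geno)) {
      dos_list <- rep(list(geno[r, ]), length(alts))
    } else {
      dos_list <- rep(list(NULL), length(alts))
    }
    recs <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      al <- minimize_alleles(sites$pos[r], sites$ref[r], alts[k])
      if (abs(nchar(al$ref) - nchar(al$alt)) > max_indel_len) {
        dropped[[length(dropped) + 1L]] <- data.table::data.table(
          id = sites$id[r], reason = "length>10")
        next
      }
      dos <- dos_list[[k]]
      if (!is.null(dos)) {
        an <- 2L * sum(!is.na(dos))
        ac <- sum(dos, na.rm = TRUE)
        rate <- mean(!is.na(dos))
        hwe <- if (an > 0) {
          hwe_exact_test(sum(dos == 0, na.rm = TRUE),
                         sum(dos == 1, na.rm = TRUE),
                         sum(dos == 2, na.rm = TRUE))
        } else NA_real_
      } else {
        an <- sites$an[r]; ac <- sites$ac[r]
        rate <- NA_real_; hwe <- NA_real_
      }
      recs[[k]] <- data.table::data.table(
        contig = sites$contig[r], pos = al$pos,
        id = if (multi) paste0(sites$id[r], "_", k) else sites$id[r],
        ref = al$ref, alt = al$alt, ac = as.integer(ac), an = as.integer(an),
        af = if (an > 0) ac / an else NA_real_,
        true_class = if ("true_class" %in% names(sites)) sites$true_class[r] else NA_character_,
        is_indel = nchar(al$ref) != nchar(al$alt),
        multiallelic = multi, genotyping_rate = rate, hwe_p = hwe)
      out_geno[[r]] <- c(out_geno[[r]], list(dos))
    }
    out[[r]] <- data.table::rbindlist(recs)
  }
  new_sites <- data.table::rbindlist(out)
  gl <- unlist(out_geno, recursive = FALSE)
  new_geno <- if (length(gl) && !is.null(gl[[1]])) do.call(rbind, gl) else NULL
  res <- cohort
  res$sites <- new_sites
  res$geno <- new_geno
  res$gt_raw <- NULL
  data.table::setattr(res$sites, "dropped",
                      data.table::rbindlist(dropped))
  res
}

# Trim shared suffix, then shared prefix keeping a 1-base anchor; adjust pos.
minimize_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1, nchar(ref) - 1)
    alt <- substring(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, 1, 1) == substring(alt, 1, 1)) {
    ref <- substring(ref, 2); alt <- substring(alt, 2)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Apply site-level quality-control filters
#'
#' Filters are applied in a fixed order (genotyping rate, HWE, LCR, hom-AF)
#' and every site is annotated with the set of filters it fails; the pass
#' set is the sites failing none.
#'
#' @param cohort a normalized `cohort`.
#' @param filters named list of enabled filters. Recognized names:
#'   `genotyping_rate` (minimum, default 0.90), `hwe_p` (exclusive minimum,
#'   default 1e-6), `exclude_lcr` (logical, requires `in_lcr` column),
#'   `max_af_hom` (maximum AF for sites whose alt alleles are all
#'   homozygous; off unless given), `median_depth` (minimum, requires a
#'   `median_depth` column). Unknown filter names are rejected.
#' @return list: `cohort` (sites gain `filter_flags`, comma-separated, ""
#'   when passing), `pass` (logical vector), `tally` (data.table: filter,
#'   n_failed).
#' @export
site_qc_filters <- function(cohort,
                            filters = list(genotyping_rate = 0.90,
                                           hwe_p = 1e-6)) {
  known <- c("genotyping_rate", "hwe_p", "exclude_lcr", "max_af_hom",
             "median_depth")
  bad <- setdiff(names(filters), known)
  if (length(bad)) stop("unknown filter name(s): ", paste(bad, collapse = ", "))
  sites <- data.table::copy(cohort$sites)
  fails <- list()
  if (!is.null(filters$genotyping_rate)) {
    fails[["genotyping_rate"]] <-
      !is.na(sites$genotyping_rate) &
      sites$genotyping_rate < filters$genotyping_rate
  }
  if (!is.null(filters$hwe_p)) {
    fails[["hwe"]] <- !is.na(sites$hwe_p) & sites$hwe_p <= filters$hwe_p
  }
  if (isTRUE(filters$exclude_lcr)) {
    if (!"in_lcr" %in% names(sites)) stop("exclude_lcr requires in_lcr column")
    fails[["lcr"]] <- sites$in_lcr
  }
  if (!is.null(filters$max_af_hom)) {
    if (is.null(cohort$geno)) stop("max_af_hom requires genotypes")
    all_hom <- rowSums(cohort$geno == 1L, na.rm = TRUE) == 0 & sites$ac > 0
    fails[["hom_af"]] <- all_hom & sites$af >= filters$max_af_hom
  }
  if (!is.null(filters$median_depth)) {
    if (!"median_depth" %in% names(sites)) {
      stop("median_depth filter requires a median_depth column")
    }
    fails[["median_depth"]] <- sites$median_depth <= filters$median_depth
  }
  flag_mat <- do.call(cbind, fails)
  if (is.null(flag_mat)) {
    sites[, filter_flags := ""]
    pass <- rep(TRUE, nrow(sites))
    tally <- data.table::data.table(filter = character(), n_failed = integer())
  } else {
    flags <- apply(flag_mat, 1, function(z) paste(colnames(flag_mat)[z],
                                                  collapse = ","))
    sites[, filter_flags := flags]
    pass <- !rowSums(flag_mat) > 0
    tally <- data.table::data.table(filter = colnames(flag_mat),
                                    n_failed = colSums(flag_mat))
  }
  res <- cohort
  res$sites <- sites
  list(cohort = res, pass = pass, tally = tally)
}

#' Flag sites inside a low-complexity mask
#'
#' @param cohort a `cohort`.
#' @param lcr data.table of 0-based half-open intervals (contig, start, end).
#' @return the cohort with an `in_lcr` logical column on `sites`.
#' @export
flag_lcr_sites <- function(cohort, lcr) {
  sites <- data.table::copy(cohort$sites)
  sites[, in_lcr := FALSE]
  for (ctg in unique(sites$contig)) {
    m <- lcr[contig == ctg]
    if (nrow(m) == 0) next
    q <- IRanges::IRanges(start = sites[contig == ctg, pos],
                          width = 1L)
    s <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    hit <- IRanges::overlapsAny(q, s)
    sites[contig == ctg, in_lcr := hit]
  }
  res <- cohort
  res$sites <- sites
  res
}

#' Allele-frequency class of each site
#'
#' Singleton (AC = 1) takes precedence; rare = AF < 1% with AC > 1;
#' low-frequency = 1% <= AF <= 5%; common = AF > 5%.
#'
#' @param ac,an,af vectors of allele counts/numbers/frequencies.
#' @return character vector of class labels.
#' @export
af_class <- function(ac, an, af = ac / an) {
  data.table::fcase(
    ac == 1L, "singleton",
    af < 0.01, "rare",
    af <= 0.05, "low_frequency",
    default = "common")
}

#' Cohort variant-spectrum summary
#'
#' Frequency-class counts for SNVs and indels, strand-collapsed substitution
#' spectrum, multiallelic fraction, Ti/Tv (SNVs only) and the private-
#' homozygote tally (AC = 2 carried as a single homozygote, reported
#' separately from singletons).
#'
#' @param cohort a normalized `cohort`.
#' @param pass optional logical vector restricting to pass-filter sites.
#' @return list of class `spectrum_summary`: `class_counts` (data.table:
#'   class x type), `substitution_fractions` (named, sums to 1), `titv`,
#'   `multiallelic_fraction`, `n_private_hom`, `n_sites`.
#' @export
spectrum_summary <- function(cohort, pass = NULL) {
  sites <- cohort$sites
  if (!is.null(pass)) sites <- sites[pass]
  if (nrow(sites) == 0) {
    return(structure(list(
      class_counts = data.table::data.table(class = character(),
                                            type = character(), n = integer()),
      substitution_fractions = numeric(0), titv = NA_real_,
      multiallelic_fraction = NA_real_, n_private_hom = 0L, n_sites = 0L),
      class = "spectrum_summary"))
  }
  cls <- af_class(sites$ac, sites$an, sites$af)
  type <- ifelse(sites$is_indel, "indel", "snv")
  class_counts <- data.table::data.table(class = cls, type = type)[
    , .(n = .N), by = .(class, type)]
  snv <- !sites$is_indel
  sub <- substitution_class(sites$ref[snv], sites$alt[snv])
  sub_tab <- table(sub)
  sub_frac <- as.numeric(sub_tab) / sum(sub_tab)
  names(sub_frac) <- names(sub_tab)
  ti <- sum(is_transition(sites$ref[snv], sites$alt[snv]))
  tv <- sum(snv) - ti
  titv <- if (tv > 0) ti / tv else NA_real_
  multi_frac <- if ("multiallelic" %in% names(sites)) {
    mean(sites$multiallelic)
  } else 0
  n_private <- if (!is.null(cohort$geno)) {
    g <- cohort$geno
    if (!is.null(pass)) g <- g[pass, , drop = FALSE]
    sum(sites$ac == 2L &
          rowSums(g == 2L, na.rm = TRUE) == 1L)
  } else NA_integer_
  structure(list(class_counts = class_counts,
                 substitution_fractions = sub_frac,
                 titv = titv, multiallelic_fraction = multi_frac,
                 n_private_hom = n_private, n_sites = nrow(sites)),
            class = "spectrum_summary")
}

#' Per-sample variant metrics
#'
#' For each sample: number of non-reference SNV and indel genotypes, Ti/Tv
#' over its non-reference SNVs, heterozygous/homozygous-alt ratio (flagged
#' `NA` when the sample has no homozygous-alt site) and the number of
#' cohort singletons it carries (sites with AC = 1 where this sample is the
#' heterozygote).
#'
#' @param cohort a normalized `cohort` with genotypes.
#' @return data.table: sample_id, n_snp, n_indel, titv, het_hom_ratio,
#'   n_singletons.
#' @export
per_sample_metrics <- function(cohort) {
  if (is.null(cohort$geno)) stop("per-sample metrics require genotypes")
  sites <- cohort$sites
  geno <- cohort$geno
  ids <- if (is.data.frame(cohort$samples)) cohort$samples$sample_id else cohort$samples
  if (length(ids) != ncol(geno)) stop("sample id / genotype column mismatch")
  snv <- !sites$is_indel
  ti <- snv & is_transition(sites$ref, sites$alt)
  tv <- snv & !is_transition(sites$ref, sites$alt)
  nonref <- !is.na(geno) & geno > 0L
  het <- !is.na(geno) & geno == 1L
  hom <- !is.na(geno) & geno == 2L
  singleton_site <- sites$ac == 1L
  data.table::data.table(
    sample_id = ids,
    n_snp = colSums(nonref[snv, , drop = FALSE]),
    n_indel = colSums(nonref[!snv, , drop = FALSE]),
    titv = {
      tis <- colSums(nonref[ti, , drop = FALSE])
      tvs <- colSums(nonref[tv, , drop = FALSE])
      ifelse(tvs > 0, tis / tvs, NA_real_)
    },
    het_hom_ratio = {
      h <- colSums(het); m <- colSums(hom)
      ifelse(m > 0, h / m, NA_real_)
    },
    n_singletons = colSums(het[singleton_site, , drop = FALSE]))
}
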