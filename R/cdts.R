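# cdts module: heptamer tolerance table, window scoring (observed -
# expected), percentile ranking and element-family summaries.

#' Qualifying SNP positions for CDTS
#'
#' Biallelic SNVs with AF strictly above the threshold; positions carrying
#' several qualifying alleles count once.
#' @param sites normalized site table (contig, pos, ref, alt, af).
#' @param af_threshold minimum AF, exclusive (default 1e-4).
#' @return data.table: contig, pos (unique).
#' @keywords internal
qualifying_snp_positions <- function(sites, af_threshold = 1e-4) {
  q <- sites[nchar(ref) == 1L & nchar(alt) == 1L & !is.na(af) &
               af > af_threshold, .(contig, pos)]
  unique(q)
}

#' Fit the heptamer tolerance-score table
#'
#' Every genomic position with 3 bp of unambiguous flank on both sides is
#' the center of one heptamer; its occurrence is tallied, and positions
#' carrying at least one qualifying SNP (AF > `af_threshold`) increment the
#' heptamer's variant tally. The tolerance score of a heptamer is
#' variants / occurrences — the per-position probability of observing
#' cohort variation in that 7-bp context. The table is complete over all
#' 4^7 = 16,384 heptamers; zero-occurrence heptamers carry score 0 and a
#' flag.
#'
#' @param reference `synth_reference` (named character vector of contigs).
#' @param sites normalized site table.
#' @param af_threshold qualifying-SNP AF threshold (default 1e-4).
#' @return data.table of class `heptamer_table`: heptamer, occurrence,
#'   variants, score, zero_occurrence — exactly 16,384 rows.
#' @export
fit_heptamer_scores <- function(reference, sites, af_threshold = 1e-4) {
  seqs <- unclass(reference)
  occ <- integer(16384L)
  varc <- integer(16384L)
  qual <- qualifying_snp_positions(sites, af_threshold)
  for (ctg in names(seqs)) {
    seq <- seqs[[ctg]]
    L <- nchar(seq)
    if (L < 7L) next
    n_amb <- L - sum(strsplit(seq, "")[[1]] %in% BASES)
    if (n_amb / L > 0.05) warning("contig ", ctg, " has > 5% ambiguous bases")
    idx <- heptamer_index(seq)               # window start -> heptamer id
    ok <- !is.na(idx)
    occ <- occ + tabulate(idx[ok], nbins = 16384L)
    qp <- qual[contig == ctg, pos]
    qp <- qp[qp >= 4L & qp <= L - 3L]        # need full flanks
    widx <- idx[qp - 3L]                     # heptamer centered at qp
    widx <- widx[!is.na(widx)]
    varc <- varc + tabulate(widx, nbins = 16384L)
  }
  out <- data.table::data.table(
    heptamer = all_heptamers(), occurrence = occ, variants = varc,
    score = ifelse(occ > 0, varc / occ, 0), zero_occurrence = occ == 0L)
  data.table::setattr(out, "class", c("heptamer_table", class(out)))
  out
}

#' Score sliding windows with the CDTS statistic
#'
#' Tiles each contig with windows of `window` bp every `step` bp (windows
#' that would overhang the contig are dropped, not truncated). Per window,
#' observed = number of qualifying SNP positions inside, expected = sum of
#' the tolerance scores of the heptamers centered at each scoreable
#' position, and CDTS = observed - expected (negative = fewer variants than
#' the sequence context predicts = constrained). Windows are ranked by
#' ascending CDTS (ties broken by genomic order) and cut into 100
#' equal-count percentile bins; percentile 1 is the most constrained.
#'
#' @param reference `synth_reference`.
#' @param sites normalized site table.
#' @param table [fit_heptamer_scores()] output.
#' @param window window width in bp (default 550).
#' @param step window stride in bp (default 10).
#' @param af_threshold qualifying-SNP AF threshold (must match the fit).
#' @return data.table of class `cdts_track`: contig, start, end (0-based
#'   half-open), observed, expected, cdts, percentile.
#' @export
score_windows <- function(reference, sites, table, window = 550L,
                          step = 10L, af_threshold = 1e-4) {
  if (window < 7L) stop("window must be >= 7")
  seqs <- unclass(reference)
  qual <- qualifying_snp_positions(sites, af_threshold)
  score <- table$score
  tracks <- list()
  for (ctg in names(seqs)) {
    seq <- seqs[[ctg]]
    L <- nchar(seq)
    if (L < window) {
      warning("contig ", ctg, " shorter than one window; skipped")
      next
    }
    idx <- heptamer_index(seq)
    # per-position expected score: position p (1-based) is scoreable when
    # 4 <= p <= L - 3; its heptamer is the window starting at p - 3
    pos_score <- numeric(L)
    sc <- score[idx]
    sc[is.na(sc)] <- 0
    pos_score[4:(L - 3L)] <- sc
    qvec <- numeric(L)
    qp <- qual[contig == ctg, pos]
    qvec[qp] <- 1
    cs_e <- c(0, cumsum(pos_score))
    cs_o <- c(0, cumsum(qvec))
    starts <- seq.int(0L, L - window, by = step)
    observed <- cs_o[starts + window + 1L] - cs_o[starts + 1L]
    expected <- cs_e[starts + window + 1L] - cs_e[starts + 1L]
    tracks[[ctg]] <- data.table::data.table(
      contig = ctg, start = starts, end = starts + window,
      observed = observed, expected = expected,
      cdts = observed - expected)
  }
  if (!length(tracks)) stop("no contig long enough for one window")
  track <- data.table::rbindlist(tracks)
  ord <- order(track$cdts, track$contig, track$start)
  rank <- integer(nrow(track))
  rank[ord] <- seq_len(nrow(track))
  track[, percentile := as.integer(floor((rank - 1) * 100 / .N) + 1L)]
  data.table::setattr(track, "class", c("cdts_track", class(track)))
  track
}

#' Element-family coverage by CDTS percentile
#'
#' For each percentile slice (the union of its windows' territory), the
#' fraction of slice bp covered by each element family. When families
#' partition the genome the rows sum to 1.
#'
#' @param track [score_windows()] output.
#' @param elements data.table (contig, start, end, family; 0-based
#'   half-open), non-overlapping within family.
#' @return matrix 100 x n_families of coverage fractions.
#' @export
element_coverage_by_percentile <- function(track, elements) {
  if (any(elements$end <= elements$start)) stop("malformed BED interval")
  fams <- sort(unique(elements$family))
  contigs <- unique(track$contig)
  fam_r <- lapply(fams, function(f) {
    lapply(stats::setNames(contigs, contigs), function(ctg) {
      e <- elements[family == f & contig == ctg]
      IRanges::reduce(IRanges::IRanges(start = e$start + 1L, end = e$end))
    })
  })
  names(fam_r) <- fams
  out <- matrix(0, nrow = 100L, ncol = length(fams),
                dimnames = list(NULL, fams))
  for (pct in sort(unique(track$percentile))) {
    w <- track[percentile == pct]
    terr <- 0
    cov <- stats::setNames(numeric(length(fams)), fams)
    for (ctg in contigs) {
      wr <- IRanges::reduce(IRanges::IRanges(
        start = w[contig == ctg, start] + 1L, end = w[contig == ctg, end]))
      terr <- terr + sum(IRanges::width(wr))
      for (f in fams) {
        cov[f] <- cov[f] +
          sum(IRanges::width(IRanges::intersect(wr, fam_r[[f]][[ctg]])))
      }
    }
    if (terr > 0) out[pct, ] <- cov / terr
  }
  out
}

#' Heptamer composition z-scores across element families
#'
#' Per family, the heptamer composition fraction over all windows fully
#' inside its intervals; per heptamer row, the z-score across families.
#' Rows with zero standard deviation emit zeros (flagged in the
#' `zero_sd` attribute). Families with less than 7 bp of territory are
#' excluded with a warning.
#'
#' @param reference `synth_reference`.
#' @param elements element table (contig, start, end, family).
#' @return matrix 16,384 x n_families of z-scores, rownames = heptamers.
#' @export
heptamer_composition_zscores <- function(reference, elements) {
  seqs <- unclass(reference)
  fams <- sort(unique(elements$family))
  comp <- matrix(0, nrow = 16384L, ncol = length(fams),
                 dimnames = list(all_heptamers(), fams))
  keep <- logical(length(fams)); names(keep) <- fams
  for (f in fams) {
    counts <- integer(16384L)
    e <- elements[family == f]
    for (r in seq_len(nrow(e))) {
      if (e$end[r] - e$start[r] < 7L) next
      sub <- substring(seqs[[e$contig[r]]], e$start[r] + 1L, e$end[r])
      idx <- heptamer_index(sub)
      idx <- idx[!is.na(idx)]
      counts <- counts + tabulate(idx, nbins = 16384L)
    }
    if (sum(counts) == 0) {
      warning("family ", f, " has < 7 bp of usable territory; excluded")
      next
    }
    keep[f] <- TRUE
    comp[, f] <- counts / sum(counts)
  }
  if (sum(keep) < 2) stop("need >= 2 element families with territory")
  comp <- comp[, keep, drop = FALSE]
  mu <- rowMeans(comp)
  sdv <- apply(comp, 1, stats::sd)
  z <- (comp - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  attr(z, "zero_sd") <- sdv == 0
  z
}
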