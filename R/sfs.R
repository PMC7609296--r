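# Site-frequency-spectrum construction and the purifying-selection
# fraction estimator.

#' Build a site frequency spectrum for one variant class
#'
#' Counts, for each allele-copy number i = 1..2N-1, the class sites with
#' AC = i. Monomorphic (AC = 0) and fixed (AC = 2N) sites are excluded.
#'
#' @param sites data.table with `ac` and a class column.
#' @param class class label to select (matched against `class_col`).
#' @param n_chrom 2N, the number of sampled chromosomes.
#' @param class_col column holding class labels (default `true_class`).
#' @return object of class `sfs`: list(counts = integer vector indexed
#'   1..2N-1, class, n_chrom).
#' @export
build_sfs <- function(sites, class, n_chrom, class_col = "true_class") {
  ac <- sites[get(class_col) == class, ac]
  if (any(ac > n_chrom)) stop("AC > 2N: inconsistent spectrum input")
  ac <- ac[ac >= 1L & ac <= n_chrom - 1L]
  counts <- tabulate(ac, nbins = n_chrom - 1L)
  structure(list(counts = counts, class = class, n_chrom = n_chrom),
            class = "sfs")
}

#' Fraction of variants under purifying selection
#'
#' Compares a class spectrum against a reference (intron/intergenic)
#' spectrum after normalizing both by their singleton bin — singletons are
#' dominated by new mutations and taken as least affected by selection, so
#' they anchor the mutation-input scale. With
#' \eqn{s(i) = n(i)/n(1)}, the per-bin deficit is
#' \eqn{d(i) = 1 - s_{class}(i)/s_{ref}(i)} and the overall fraction is
#' \deqn{F = 1 - \frac{\sum_{i \ge 2} s_{class}(i)}{\sum_{i \ge 2} s_{ref}(i)}}
#' clipped to [-1, 1] and flagged when negative. A total-mass normalization
#' (`normalization = "total"`) is available as an alternative.
#'
#' @param class_sfs,reference_sfs [build_sfs()] objects on the same 2N.
#' @param normalization `"singleton"` (default) or `"total"`.
#' @return list of class `selection_fraction`: `fraction`, `negative_flag`,
#'   `per_bin` (data.table: i, deficit).
#' @export
fraction_under_selection <- function(class_sfs, reference_sfs,
                                     normalization = c("singleton", "total")) {
  normalization <- match.arg(normalization)
  if (class_sfs$n_chrom != reference_sfs$n_chrom) {
    stop("spectra built on different 2N")
  }
  nc <- class_sfs$counts; nr <- reference_sfs$counts
  if (nc[1] == 0 || nr[1] == 0) stop("singleton bin empty; cannot normalize")
  if (sum(nr[-1]) == 0) stop("reference SFS degenerate: only singletons")
  denom_c <- if (normalization == "singleton") nc[1] else sum(nc)
  denom_r <- if (normalization == "singleton") nr[1] else sum(nr)
  sc <- nc / denom_c
  sr <- nr / denom_r
  i <- seq_along(nc)
  deficit <- ifelse(sr > 0, 1 - sc / sr, NA_real_)
  frac <- 1 - sum(sc[-1]) / sum(sr[-1])
  clipped <- max(min(frac, 1), -1)
  structure(list(fraction = clipped, negative_flag = clipped < 0,
                 per_bin = data.table::data.table(i = i[-1],
                                                  deficit = deficit[-1])),
            class = "selection_fraction")
}
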