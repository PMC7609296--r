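#' Hardy-Weinberg exact test
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of each possible heterozygote count h is
#' \deqn{P(h) \propto 2^h / (n_{hom.ref}! \, h! \, n_{hom.alt}!)}
#' and the two-sided p-value sums the probabilities of all heterozygote
#' counts no more likely than the observed one (plain exact test, no mid-p).
#' The distribution is built by the ratio recurrence
#' \eqn{P(h+2)/P(h) = 4 r a / ((h+1)(h+2))} anchored at the modal
#' heterozygote count, so no factorials are formed.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (equal-length vectors).
#' @return p-values in (0, 1]; monomorphic sites give 1.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  k <- length(n_het)
  stopifnot(length(n_hom_ref) == k, length(n_hom_alt) == k,
            all(n_hom_ref >= 0), all(n_het >= 0), all(n_hom_alt >= 0))
  if (any(n_hom_ref + n_het + n_hom_alt == 0)) stop("no data: all-zero counts")
  vapply(seq_len(k), function(i) {
    hwe_exact_one(n_hom_ref[i], n_het[i], n_hom_alt[i])
  }, numeric(1))
}

hwe_exact_one <- function(r_obs, h_obs, a_obs) {
  N <- r_obs + h_obs + a_obs
  n_alt <- h_obs + 2L * a_obs
  n_rare <- min(n_alt, 2L * N - n_alt)
  if (n_rare == 0L) return(1)
  dist <- hwe_het_distribution(N, n_rare)
  p_obs <- dist$prob[match(h_obs, dist$h)]
  sum(dist$prob[dist$prob <= p_obs * (1 + 1e-7)])
}

# Unnormalized-then-normalized distribution of het counts given N genotypes
# and n_rare copies of the rarer allele. h runs over n_rare, n_rare-2, ..
hwe_het_distribution <- function(N, n_rare) {
  h_min <- if (n_rare %% 2L == 0L) 0L else 1L
  h <- seq.int(h_min, min(n_rare, 2L * N - n_rare), by = 2L)
  # log-space upward recurrence anchored at h_min, then shifted by the max:
  # P(h)/P(h-2) = 4 * hom_common(h-2) * hom_rare(h-2) / (h (h-1))
  if (length(h) > 1L) {
    h_prev <- h[-length(h)]
    a_prev <- (n_rare - h_prev) / 2
    r_prev <- N - h_prev - a_prev
    hh <- h[-1L]
    steps <- log(4 * r_prev * a_prev) - log(hh) - log(hh - 1)
    logu <- c(0, cumsum(steps))
  } else {
    logu <- 0
  }
  logu <- logu - max(logu)
  prob <- exp(logu)
  prob <- prob / sum(prob)
  list(h = h, prob = prob)
}
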