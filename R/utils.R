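# Internal helpers shared across modules.

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

BASES <- c("A", "C", "G", "T")

# Map a DNA string to integer codes A=0, C=1, G=2, T=3 (NA for anything else).
dna_to_code <- function(seq) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt(seq)]
}

# All 4^7 heptamers in lexicographic (base-4, A<C<G<T) order.
all_heptamers <- function() {
  g <- expand.grid(rep(list(BASES), 7), stringsAsFactors = FALSE)
  # expand.grid varies the FIRST factor fastest; lexicographic order needs the
  # last position fastest, so build columns in reverse.
  do.call(paste0, rev(g))
}

# 1-based lexicographic index of the heptamer starting at each position
# 1..(L-6); NA where the window contains a non-ACGT base.
heptamer_index <- function(seq) {
  code <- dna_to_code(seq)
  L <- length(code)
  if (L < 7L) return(integer(0))
  n <- L - 6L
  idx <- numeric(n)
  for (k in 0:6) idx <- idx + code[(1L + k):(n + k)] * 4^(6 - k)
  as.integer(idx + 1)
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

# Strand-collapsed substitution class label, e.g. G>A and C>T both map to
# "C:G>T:A". Pyrimidine (C/T) reference orientation is used as canonical.
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

substitution_class <- function(ref, alt) {
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  paste0(r, ":", COMPLEMENT[r], ">", a, ":", COMPLEMENT[a])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
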