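---
title: "Models and methods behind varcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind varcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`varcohort` re-implements the analytical layer of a population
whole-genome-sequencing study — variant spectrum summaries, loss-of-function
constraint, context-dependent tolerance scoring, pharmacogenomic calling,
polygenic risk stratification and population-structure estimation — on top
of a synthetic-cohort generator. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
cohorts do and do not emulate.

## The synthetic cohort generator

Real cohort-scale genotype data are access-restricted, so every analysis in
the package is exercised on generated data whose *relevant* statistical
structure is controlled:

* **Reference and gene models.** The reference is an i.i.d. uniform
  A/C/G/T sequence (2 Mb, one contig by default), so all 16,384 heptamers
  occur at an expected ~122 copies per megabase-pair-squared of context —
  enough to fit the heptamer tolerance table without empty cells. Genes are
  non-overlapping, plus-strand, single-transcript ORFs (1–4 CDS exons,
  ATG…stop, no premature stops, GT/AG essential splice dinucleotides,
  introns ≥ 20 bp) written into the reference. Restricting the generator to
  the plus strand keeps the consequence engine single-orientation; this is
  a deliberate simplification, documented as a limitation below.
* **Allele-count law.** Site allele counts are drawn directly on AC with
  P(AC = i) ∝ i^(−α) over i = 1..2n−1 (α = 1 by default, the neutral
  constant-size expectation). Genotypes place exactly AC alternate alleles
  uniformly among the 2n chromosomes, so the realized AC is exact (making
  singleton truth labels exact) and founder genotypes are hypergeometric —
  indistinguishable from Hardy–Weinberg at cohort scale. The package's own
  exact test rejects at p < 10⁻⁶ for far fewer than 0.1% of sites.
* **Purifying selection as rejection thinning.** A consequence class with
  deficit d keeps its singletons but drops each non-singleton site with
  probability d. This choice (rather than re-normalizing the AC law) makes
  the deficit visible in *both* signatures a constraint analysis uses: the
  class SFS is skewed toward singletons, and the class's site density
  drops. The singleton-anchored selection-fraction estimator then recovers
  d in expectation, and planted constrained regions become depleted windows
  for CDTS. Defaults (intron/intergenic 0, synonymous 0.1, nonsynonymous
  0.3, LOF 0.5) follow the qualitative ordering seen in population
  cohorts.
* **Relatedness.** Founders are Binomial(2, p) draws at uniform(0.05, 0.5)
  frequencies; children receive one allele per parent per site (a
  heterozygous parent transmits either allele with probability ½);
  duplicates are exact copies. Expected PI_HAT is 1 (duplicate), 0.5
  (parent–offspring and full siblings), 0.25 (half-siblings).
* **Structure.** Two populations draw per-site frequencies from the
  Balding–Nichols Beta(p(1−F)/F, (1−p)(1−F)/F), giving mean p and variance
  F·p(1−p); the Hudson estimator recovers F.
* **Phenotypes.** y = Σβ_j g_j + γ₁·age + γ₂·age² + γ₃·sex + ε with betas
  scaled so Var(Σβg) = h² and Var(ε) = 1 − h²; the binary disease applies a
  liability threshold at the configured prevalence to the same genetic
  component with a fresh residual. GWAS base statistics come from a larger
  independent discovery cohort simulated in HWE at the cohort frequencies
  (restricted to AF ≥ 1% plus the causal sites — the variants a real base
  panel would carry) and regressed one variant at a time.
* **Pharmacogenes.** Each of the 2n haplotypes per gene is assigned one
  star allele by a multinomial over the configured frequencies, so no
  haplotype carries two defining variants and unphased diplotypes are
  unambiguous by construction. Default frequencies are published East Asian
  values (e.g. CYP2C19 *2 = 0.31, *3 = 0.06, *17 = 0.015; ALDH2 rs671
  A = 0.21; VKORC1 rs9923231 A = 0.90).

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (sites are independent, so LD clumping and pruning are
exercised on planted duplicated/correlated columns in tests rather than on
realistic decay curves), sequencing error and depth-dependent genotype
uncertainty, indel-rich low-complexity artifacts, transcript isoform
diversity, and minus-strand genes. Passing tests therefore demonstrate the
correctness of the estimators under their stated models — not robustness to
every artifact of real sequencing data.

## Frequency classes and the exact Hardy–Weinberg test

Classes: singleton (AC = 1, taking precedence), rare (AF < 1%, AC > 1),
low-frequency (1% ≤ AF ≤ 5%), common (AF > 5%). The boundary assignment of
AF exactly 1% and 5% to the low-frequency class is a package convention;
the published ranges are open-ended. A "private homozygote" (AC = 2 carried
by one individual) is *not* a singleton; it is tallied separately by
`spectrum_summary` because "variants seen in only one individual" is
ambiguous between the two readings.

The HWE test is the conditional exact test (no mid-p): heterozygote counts
given allele counts have P(h) ∝ 2^h/(n_AA! h! n_aa!), and the two-sided p
sums outcomes with probability ≤ the observed (a relative tolerance of
1 + 10⁻⁷ guards floating-point ties). The distribution is built with the
ratio recurrence P(h+2)/P(h) = 4·n_AA·n_aa/((h+1)(h+2)) in log space,
anchored at the minimal heterozygote count — no factorials are formed, so
the computation is stable to the cohort sizes used here. The test suite
checks it against an independent lgamma-based enumeration over every
genotype configuration with ≤ 200 individuals at |Δp| < 10⁻¹².

## LOF constraint and the selection fraction

The consequence engine handles single-transcript plus-strand models: CDS
SNVs are translated in frame; any change to the initiator ATG is
start-lost (translation in the oracle deliberately disables alternative
initiation so CTG/TTG do not silently rescue the start); stop-codon
changes to another stop are synonymous; SNVs at intron positions +1/+2 and
−2/−1 are splice-disrupting; CDS indels are frameshift unless the length
change is a multiple of 3. pLOF = stop gained/lost, start lost, splice
disruption, frameshift.

`enumerate_potential_lof` iterates all CDS positions × 3 alternate bases
plus 4 essential splice positions per intron × 3 bases. The OP ratio counts
*distinct alt alleles* (events) in both numerator and denominator, making
them commensurable; a position-level count is kept as an attribute because
the two conventions differ and published gene-level metrics do not always
say which they use. Observed pLOF indels (frameshifts) can in principle
push the event count above the SNV-only denominator, so the ratio is
clipped at 1.

The fraction under purifying selection compares a class SFS against the
intron/intergenic reference after dividing both by their singleton bins:
F = 1 − [Σ_{i≥2} s_class(i)] / [Σ_{i≥2} s_ref(i)]. Singleton anchoring
assumes new mutations are the bin least shaped by selection, so the
singleton ratio estimates relative mutational input. No closed formula for
this quantity is standard across publications; total-mass normalization is
available as an option (`normalization = "total"`), and F is clipped to
[−1, 1] with a flag for negative values (sampling noise under neutrality).
Under the generator's rejection-thinning model the estimator is unbiased
for the planted deficit; the suite recovers deficits of 0.1/0.3/0.5 within
±0.05 and centers neutral-vs-neutral comparisons at |median F| < 0.02.

## CDTS

A heptamer's tolerance score is (positions with a qualifying SNP) /
(occurrences), where a qualifying SNP is a biallelic SNV with AF strictly
above 10⁻⁴ and positions need 3 bp of unambiguous flank. Windows of 550 bp
sliding by 10 bp (both exposed as arguments; the published window is
550 bp and 10 bp is the conventional stride for this score) are scored
observed − expected, where expected sums the central-heptamer scores over
the window. Windows overhanging a contig are dropped rather than truncated
so observed and expected stay commensurable. Ranking is ascending by CDTS
with ties broken by genomic order, cut into 100 equal-count bins (they
differ by at most one window). Because scores are fitted on the same
cohort that is scored, total expected mass equals total observed mass up
to edge positions — the suite requires agreement within 0.5% on an exact
tiling — and the genome-wide mean CDTS is ~0. The score table is always
complete over all 16,384 heptamers; zero-occurrence heptamers carry score
0 with a flag rather than NA so window expectations never propagate
missingness.

## Pharmacogenomics

Diplotypes are called from unphased dosages at the defining variants.
With at most one non-default allele observed the call is exact. Two
heterozygous defining variants are formally ambiguous in unphased data;
the call follows the one-defining-variant-per-haplotype convention
(*2 het + *17 het → *2/*17), flags the ambiguity, and lists the alternative
phasing. SLCO1B1 *15 — a composite of the *1B and *5 defining variants on
one haplotype — is omitted from the bundled table for exactly this reason;
*5 carries the myopathy-relevant decreased-function status either way.
Coordinates in the bundled allele table are synthetic placeholders (the
rsIDs, alleles and functional classes are the real ones).

The warfarin model returns the square root of the *weekly* dose. Age
enters in *decades*: with age in years the polynomial goes negative for
ordinary adults (e.g. 50 years contributes −13.07 where −1.307 is
intended), so the decades convention of the underlying clinical algorithm
is used. The printed form of such algorithms subtracts a "genotype dosing"
term whose coefficients are themselves written with minus signs; applied
literally the two negations would *raise* the dose for VKORC1 A carriers,
the opposite of the pharmacology, so the genotype terms here are added
with their printed (negative) signs. CYP2C9 diplotypes outside the
coefficient table contribute 0; "unknown" uses the dedicated unknown
terms; a non-positive square root is an error naming the inputs.

CYP2C19 classes: two no-function alleles → poor; one → intermediate
(including no-function + increased, per CPIC); *1/*1 normal; *1/*17 rapid;
*17/*17 ultrarapid. The mapping is a pure lookup, property-tested against
a hand-written truth table of all 45 diplotypes over {*1,*2,…,*8,*17}.

## PRS

Harmonization keeps p < 5×10⁻⁸, drops A/T and C/G (strand-ambiguous)
SNPs, matches by position + allele pair and flips beta when the effect
allele is the target REF. Clumping is greedy by ascending p with r²
computed on dosages (defaults r² > 0.1 within 250 kb — conventional values;
the parameters are arguments). Raw scores are Σ beta × dosage with 2·AF
mean imputation for missing dosages; adjusted scores are residuals on age,
age², sex, PC1, PC2; groups are top 10% / tail 10% / median 80% by
adjusted score with ties broken by sample order. Group comparison is a
Welch t-test; disease risk is a logistic regression of status on the
top-decile indicator plus covariates (Wald 95% CI), with AUC computed by
the Mann–Whitney rank identity. Genome-build conversion is out of scope:
base and target must share a coordinate system.

## Population structure and relatedness

Pruning applies MAF ≥ 1%, call rate ≥ 90%, HWE p > 10⁻⁶, then removes the
*later* SNP of every pair with r² ≥ 0.5 within 50-SNP windows sliding by
5 — the deterministic tie-break makes output reproducible. PCA standardizes
dosages by 2p̂ and √(2p̂(1−p̂)), drops monomorphic sites, zero-fills missing
values after centering, and fixes each component's sign so its
largest-magnitude coordinate is positive. Fst is the Hudson estimator as a
ratio of sums (ratio-of-averages), computed from sample frequencies and
haploid sizes; small negative estimates are reported and flagged, not
clipped.

IBD follows the PLINK method of moments: per-pair IBS0/1/2 counts are
inverted against expected IBS-class probabilities given IBD state. The
expectations are computed from cohort allele counts as
without-replacement (factorial-moment) probabilities — e.g.
P(IBS0 | IBD0) = 2·X(X−1)·Y(Y−1)/[T]₄ for X alt and Y ref alleles among T
— which is the finite-sample bias correction that keeps unrelated-pair
PI_HAT centered at 0 even though frequencies are estimated from the same
cohort. Probabilities are clipped to [0,1] and renormalized;
PI_HAT = P2 + P1/2; the unrelated set greedily drops the sample with most
relationships at PI_HAT ≥ 0.1875 until none remain.

## Numerical and testing choices

* All generator randomness flows from one integer seed per entry point;
  identical configuration and seed give byte-identical files. Module seeds
  are small fixed offsets of the config seed so the components are
  independently reproducible.
* Problem sizes in the test suite (2 Mb genomes, 500-sample cohorts, 20k
  SNP panels, 50-seed PRS replicates, 1000 null t-tests) were chosen so
  Monte-Carlo error sits well inside each stated tolerance while the whole
  suite stays in the minutes range on a single core.
* The null-calibration check uses 1000 replicate t-tests: at 200
  replicates the binomial standard error (1.5%) is close to the ±2%
  acceptance band, so more replicates sharpen the estimate without
  loosening the criterion.
* Degenerate inputs fail loudly and early: genomes shorter than a
  heptamer, single-codon ORFs, CDS lengths not divisible by 3 (skipped
  with a warning), all-singleton reference spectra, zero-case strata in
  the OR regression, and non-positive warfarin linear predictors all have
  dedicated errors or flags, covered by tests.

## Known limitations

Plus-strand, single-transcript consequence calling; no LD in the
generator; indel normalization trims shared affixes but does not walk
indels left through repeat tracts (generator alleles are already minimal);
IBS expectations ignore inbreeding; PRS assumes one shared genome build;
the PGx caller resolves two-site heterozygotes by convention rather than
statistical phasing. Each is a documented boundary of the synthetic study
design rather than an accidental gap.
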