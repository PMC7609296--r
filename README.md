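# varcohort

Cohort-scale variant spectrum, constraint and pharmacogenomic analysis in R.

Population whole-genome sequencing studies summarize tens of millions of
variants into a small set of recurring quantities: the allele-frequency
spectrum and its frequency classes, per-sample variant metrics,
loss-of-function constraint per gene, sequence-context tolerance of the
noncoding genome, pharmacogenomic genotype-to-phenotype calls, polygenic
risk stratification, and population structure / relatedness estimates.
`varcohort` implements that analysis layer as a single tested R package,
together with a synthetic-cohort generator that produces every input the
pipeline consumes (reference FASTA, gene models, element/LCR BEDs,
multi-sample VCF, phenotypes, GWAS base summary statistics) with the
statistical structure the analyses assume. Cohort-scale sequencing data are
usually access-restricted; the generator makes the whole pipeline
reproducible and testable on one workstation.

It is aimed at statistical geneticists who want transparent, scriptable
reference implementations of these estimators — each one small enough to
read — rather than a wrapper around external binaries.

## What it computes

**Variant spectrum and QC** (`normalize_sites`, `site_qc_filters`,
`spectrum_summary`, `per_sample_metrics`). Multiallelic splitting with
per-alt AC/AN/AF recomputation, indel length and alt-count limits,
genotyping-rate and Hardy–Weinberg filters; frequency classes (singleton
AC = 1; rare AF < 1%; low-frequency 1–5%; common > 5%), strand-collapsed
mutation spectrum, Ti/Tv, and per-sample SNV/indel counts, het/hom ratio
and cohort-singleton counts.

**Hardy–Weinberg exact test** (`hwe_exact_test`). The conditional exact
test: given allele counts, heterozygote counts are distributed as
P(h) ∝ 2^h / (n_AA! h! n_aa!) and the two-sided p sums all outcomes no more
likely than the observed one.

**LOF constraint** (`annotate_consequence`, `enumerate_potential_lof`,
`gene_constraint_table`, `build_sfs`, `fraction_under_selection`). A
miniature consequence engine (stop gained/lost, start lost, essential
splice ±1/±2, frameshift vs in-frame) feeding the per-gene OP ratio —
observed pLOF alt alleles divided by the exhaustively enumerated potential
pLOF SNV alleles — plus homozygous-knockout detection and pLI-based
intolerance flags. Site-frequency spectra per consequence class give the
fraction of variants under purifying selection,
F = 1 − [Σ_{i≥2} s_class(i)] / [Σ_{i≥2} s_ref(i)], with spectra normalized
by their singleton bins and intron/intergenic sites as the reference class.

**CDTS** (`fit_heptamer_scores`, `score_windows`,
`element_coverage_by_percentile`). The context-dependent tolerance score:
every position is the center of one of 4⁷ = 16,384 heptamers; a heptamer's
tolerance is the fraction of its genomic occurrences carrying a cohort SNP
(AF > 10⁻⁴). Sliding 550-bp windows are scored observed − expected and
ranked into 100 percentile bins; percentile 1 is the most constrained
sequence.

**Pharmacogenomics** (`call_star_diplotype`, `cyp2c19_phenotype`,
`warfarin_dose`, `slco1b1_risk`, `cohort_pgx_summary`). Star-allele
diplotyping from defining variants (CYP2C19 *1–*8, *17; CYP2C9 *2/*3;
SLCO1B1; plus ALDH2/ADH1B/CYP1A2 genotype profiles), CPIC metabolizer
classes, simvastatin myopathy risk, and the pharmacogenetic warfarin
algorithm: √(weekly dose) = 5.6044 − 0.2614·age(decades) + 0.0087·height +
0.0128·weight + genotype terms (VKORC1 −0.8677 A/G, −1.6974 A/A; CYP2C9
−0.5211 *1/*2 … −2.3312 *3/*3).

**PRS** (`harmonize_base_stats`, `ld_clump`, `compute_and_adjust_prs`,
`stratify_and_test`, `disease_risk_metrics`). Genome-wide-significant
(p < 5×10⁻⁸) base variants, strand-ambiguous A/T and C/G SNPs removed,
allele-orientation harmonization, greedy LD clumping (r² > 0.1 within
250 kb), covariate adjustment (age, age², sex, PC1, PC2), top/median/tail
(10/80/10%) stratification with Welch t-tests, and top-decile logistic
odds ratios with rank-statistic AUC.

**Population structure** (`prune_snps`, `run_pca`, `pairwise_fst`,
`estimate_ibd_and_unrelated`). MAF ≥ 1%, call rate ≥ 90%, HWE p > 10⁻⁶ and
windowed LD pruning (r² ≥ 0.5 in 50-SNP windows sliding by 5);
standardized-genotype PCA; Hudson ratio-of-averages Fst; and PLINK-style
method-of-moments IBD with PI_HAT = P(IBD=2) + P(IBD=1)/2 and the 0.1875
unrelated-set cut.

## Worked example

```r
library(varcohort)

cfg    <- sim_config(seed = 7, genome_length = 5e5, n_samples = 200)
ref    <- generate_reference(cfg)
ann    <- generate_annotations(ref, cfg)          # gene models, elements, LCR
cohort <- normalize_sites(simulate_cohort_variants(ann, cfg))

qc   <- site_qc_filters(cohort)
spec <- spectrum_summary(cohort, qc$pass)
spec$class_counts[order(class, type)]
#>            class   type     n
#> 1:        common  indel   461
#> 2:        common    snv  5169
#> 3: low_frequency  indel   267
#> 4: low_frequency    snv  3061
#> 5:          rare  indel   134
#> 6:          rare    snv  1422
#> 7:     singleton  indel   153
#> 8:     singleton    snv  1764
sprintf("Ti/Tv = %.2f", spec$titv)
#> "Ti/Tv = 2.11"

gene_constraint_table(cohort, ann, ann$reference)[1:3]
#>    gene_id observed_lof potential_lof   op_ratio
#> 1: GENE001            3            96 0.03125000
#> 2: GENE002            0            86 0.00000000
#> 3: GENE003            3           129 0.02325581

warfarin_dose(50, 170, 70, vkorc1_gt = "A/A", cyp2c9_diplotype = "*1/*3")$daily_mg
#> 2.33  # mg/day: a VKORC1 A/A, CYP2C9 *1/*3 carrier needs less than half
#>       # the reference-genotype dose (6.36 mg/day)
```

The spectrum is dominated by common variants here only because the
synthetic cohort is small (AN = 400); the singleton and rare classes grow
with cohort size exactly as the allele-count law P(AC = i) ∝ 1/i predicts.
Each gene's OP ratio compares the pLOF alleles seen in the cohort against
every possible single-nucleotide pLOF allele in that gene (~100 for these
toy genes); lower means more constrained.

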