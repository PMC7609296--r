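# pgx module: star-allele diplotyping, CYP2C19 metabolizer phenotypes, the
# warfarin dosing algorithm, SLCO1B1 simvastatin risk and cohort summaries.

#' Warfarin dosing model coefficients
#'
#' The pharmacogenetic dosing polynomial: the linear predictor
#' \deqn{S = 5.6044 - 0.2614 \cdot age/10 + 0.0087 \cdot height_{cm} +
#'   0.0128 \cdot weight_{kg} + VKORC1\ term + CYP2C9\ term}
#' is the square root of the WEEKLY dose in mg. Age enters in decades.
#' Genotype terms (all reductions): VKORC1 rs9923231 A/G -0.8677,
#' A/A -1.6974, unknown -0.4854; CYP2C9 *1/*2 -0.5211, *1/*3 -0.9357,
#' *2/*2 -1.0616, *2/*3 -1.9206, *3/*3 -2.3312, unknown -0.2188. Reference
#' categories (VKORC1 G/G, CYP2C9 *1/*1) contribute 0.
#'
#' @format list with `intercept`, `age_per_decade`, `height`, `weight`,
#'   `vkorc1` (named vector), `cyp2c9` (named vector).
#' @export
warfarin_coefficients <- function() {
  list(intercept = 5.6044, age_per_decade = -0.2614, height = 0.0087,
       weight = 0.0128,
       vkorc1 = c("G/G" = 0, "A/G" = -0.8677, "G/A" = -0.8677,
                  "A/A" = -1.6974, "unknown" = -0.4854),
       cyp2c9 = c("*1/*1" = 0, "*1/*2" = -0.5211, "*1/*3" = -0.9357,
                  "*2/*2" = -1.0616, "*2/*3" = -1.9206, "*3/*3" = -2.3312,
                  "unknown" = -0.2188))
}

# canonical diplotype string: alleles sorted (default allele first)
format_diplotype <- function(a1, a2, default) {
  al <- c(a1, a2)
  ord <- order(al != default, al)
  paste(al[ord], collapse = "/")
}

#' Call a star-allele diplotype from genotypes at the defining sites
#'
#' Each haplotype is assigned the allele whose defining variant it carries,
#' and the default allele otherwise. With unphased data, heterozygosity at
#' two or more defining sites of one gene is formally ambiguous; under the
#' one-defining-variant-per-haplotype convention the call is resolved to
#' the two non-default alleles (e.g. het *2 + het *17 -> *2/*17), flagged
#' `ambiguous = TRUE` with all phasings listed, and a warning is raised.
#' Missing genotypes at any defining site give an `"unknown"` call.
#'
#' @param dosages named integer vector: rsid -> alt dosage (0/1/2, NA
#'   missing) for one sample. rsIDs not in the gene's table are ignored.
#' @param gene gene symbol.
#' @param star_table [read_star_allele_table()] output.
#' @return list: `diplotype` (string), `alleles` (length-2), `ambiguous`,
#'   `candidates` (character of consistent diplotypes).
#' @export
call_star_diplotype <- function(dosages, gene,
                                star_table = read_star_allele_table()) {
  gname <- gene
  defs <- star_table[gene == gname]
  if (nrow(defs) == 0) stop("gene ", gname, " not in allele table")
  default <- pgx_default_allele(gene)
  d <- dosages[defs$rsid]
  names(d) <- defs$rsid
  if (anyNA(d)) {
    return(list(diplotype = "unknown", alleles = c(NA, NA),
                ambiguous = FALSE, candidates = character(0)))
  }
  total <- sum(d)
  carried <- defs$allele[d > 0]
  if (total == 0L) {
    al <- c(default, default)
  } else if (total == 1L) {
    al <- c(default, carried)
  } else if (total == 2L && length(carried) == 1L) {
    al <- c(carried, carried)
  } else if (total == 2L && length(carried) == 2L) {
    # two het defining variants: *X/*Y under the one-variant-per-haplotype
    # convention, but *{X+Y}/default is also consistent with unphased data
    cand <- c(paste(sort(carried), collapse = "/"),
              paste0(default, "/", paste(sort(carried), collapse = "+")))
    warning(gene, ": heterozygous at 2 defining sites; resolved to ",
            cand[1], " by the one-defining-variant-per-haplotype convention")
    return(list(diplotype = cand[1], alleles = sort(carried),
                ambiguous = TRUE, candidates = cand))
  } else {
    return(list(diplotype = "unknown", alleles = c(NA, NA), ambiguous = TRUE,
                candidates = character(0)))
  }
  list(diplotype = format_diplotype(al[1], al[2], default), alleles = al,
       ambiguous = FALSE,
       candidates = format_diplotype(al[1], al[2], default))
}

#' CYP2C19 metabolizer phenotype from a diplotype
#'
#' CPIC mapping over allele functional classes: two no-function alleles ->
#' poor; one no-function allele (with *1 or *17) -> intermediate; *1/*1 ->
#' normal; *1/*17 -> rapid; *17/*17 -> ultrarapid. Unknown alleles give
#' `"indeterminate"`.
#'
#' @param diplotype string like `"*1/*2"`.
#' @param star_table allele table (for functional classes).
#' @return one of poor/intermediate/normal/rapid/ultrarapid/indeterminate.
#' @export
cyp2c19_phenotype <- function(diplotype,
                              star_table = read_star_allele_table()) {
  if (is.na(diplotype) || diplotype == "unknown") return("indeterminate")
  al <- strsplit(diplotype, "/", fixed = TRUE)[[1]]
  if (length(al) != 2) return("indeterminate")
  defs <- star_table[gene == "CYP2C19"]
  fun <- function(a) {
    if (a == "*1") return("normal")
    f <- defs[allele == a, func]
    if (length(f) != 1) return("unknown")
    f
  }
  f1 <- fun(al[1]); f2 <- fun(al[2])
  fs <- sort(c(f1, f2))
  if (any(fs == "unknown")) return("indeterminate")
  n_nofun <- sum(fs == "no_function")
  n_inc <- sum(fs == "increased")
  if (n_nofun == 2L) return("poor")
  if (n_nofun == 1L) return("intermediate")   # incl. no_function + increased
  if (n_inc == 2L) return("ultrarapid")
  if (n_inc == 1L) return("rapid")
  "normal"
}

#' Warfarin weekly and daily dose
#'
#' Evaluates the pharmacogenetic dosing polynomial
#' ([warfarin_coefficients()]); the linear predictor is the square root of
#' the weekly dose (mg), so weekly = S^2 and daily = weekly / 7. Inputs
#' outside the adult ranges (age 18-110, height 120-220 cm, weight
#' 30-200 kg) warn but are still computed; a non-positive S is a
#' model-out-of-range error.
#'
#' @param age_years age in years (enters the model in decades).
#' @param height_cm,weight_kg anthropometrics.
#' @param vkorc1_gt rs9923231 genotype: `"G/G"`, `"A/G"`, `"A/A"` or
#'   `"unknown"`.
#' @param cyp2c9_diplotype CYP2C9 diplotype string; diplotypes outside the
#'   coefficient table contribute 0; `"unknown"` uses the unknown term.
#' @return list: `sqrt_weekly`, `weekly_mg`, `daily_mg`.
#' @export
warfarin_dose <- function(age_years, height_cm, weight_kg, vkorc1_gt,
                          cyp2c9_diplotype) {
  if (age_years < 18 || age_years > 110 || height_cm < 120 ||
      height_cm > 220 || weight_kg < 30 || weight_kg > 200) {
    warning("inputs outside the validated adult ranges; dose still computed")
  }
  co <- warfarin_coefficients()
  vk <- co$vkorc1[vkorc1_gt]
  if (is.na(vk)) vk <- co$vkorc1["unknown"]
  c9 <- if (cyp2c9_diplotype %in% names(co$cyp2c9)) {
    co$cyp2c9[cyp2c9_diplotype]
  } else if (identical(cyp2c9_diplotype, "unknown")) {
    co$cyp2c9["unknown"]
  } else 0
  s <- co$intercept + co$age_per_decade * (age_years / 10) +
    co$height * height_cm + co$weight * weight_kg + unname(vk) + unname(c9)
  if (s <= 0) {
    stop("model out of range (sqrt weekly dose <= 0) for age=", age_years,
         " height=", height_cm, " weight=", weight_kg, " VKORC1=", vkorc1_gt,
         " CYP2C9=", cyp2c9_diplotype)
  }
  list(sqrt_weekly = s, weekly_mg = s^2, daily_mg = s^2 / 7)
}

#' SLCO1B1 simvastatin myopathy risk class
#'
#' Counts decreased-function alleles in the diplotype: 0 -> normal, 1 ->
#' intermediate, 2 -> high. Alleles of unknown function give
#' `"indeterminate"`.
#'
#' @param diplotype e.g. `"*1A/*5"`.
#' @param star_table allele table.
#' @return one of normal/intermediate/high/indeterminate.
#' @export
slco1b1_risk <- function(diplotype, star_table = read_star_allele_table()) {
  if (is.na(diplotype) || diplotype == "unknown") return("indeterminate")
  al <- strsplit(diplotype, "/", fixed = TRUE)[[1]]
  if (length(al) != 2) return("indeterminate")
  defs <- star_table[gene == "SLCO1B1"]
  fun <- function(a) {
    if (a %in% c("*1A", "*1B")) return("normal")
    f <- defs[allele == a, func]
    if (length(f) != 1) return("unknown")
    f
  }
  fs <- c(fun(al[1]), fun(al[2]))
  if (any(fs == "unknown")) return("indeterminate")
  c("normal", "intermediate", "high")[sum(fs == "decreased") + 1L]
}

#' Per-sample pharmacogenomic call set
#'
#' Runs diplotyping, CYP2C19 metabolizer classification, warfarin dosing
#' (using each sample's age/height/weight) and SLCO1B1 risk over a
#' pharmacogene cohort, and reports genotype labels for the profile
#' variants (ALDH2 rs671, ADH1B, CYP1A2).
#'
#' @param pgx a `pgx_cohort` ([generate_pgx_cohort()]) or compatible list
#'   with `geno` (rownames = rsid), `samples`.
#' @param star_table allele table.
#' @return data.table of class `pgx_callset`: one row per sample with
#'   diplotypes, phenotype, doses and risk classes.
#' @export
pgx_call_samples <- function(pgx, star_table = read_star_allele_table()) {
  geno <- pgx$geno
  meta <- pgx$samples
  n <- nrow(meta)
  genes_present <- unique(star_table[rsid %in% rownames(geno), gene])
  calls <- data.table::data.table(sample_id = meta$sample_id)
  dipl <- list()
  for (g in genes_present) {
    dipl[[g]] <- vapply(seq_len(n), function(i) {
      suppressWarnings(
        call_star_diplotype(geno[, i], g, star_table)$diplotype)
    }, character(1))
  }
  if ("CYP2C19" %in% genes_present) {
    calls[, cyp2c19_diplotype := dipl$CYP2C19]
    calls[, cyp2c19_phenotype := vapply(dipl$CYP2C19, cyp2c19_phenotype,
                                        character(1), star_table = star_table)]
  }
  if ("CYP2C9" %in% genes_present) calls[, cyp2c9_diplotype := dipl$CYP2C9]
  if ("VKORC1" %in% genes_present) {
    vk_dos <- geno[star_table[gene == "VKORC1", rsid][1], ]
    calls[, vkorc1_genotype := c("G/G", "A/G", "A/A")[vk_dos + 1L]]
  }
  if (all(c("CYP2C9", "VKORC1") %in% genes_present)) {
    calls[, warfarin_daily_mg := vapply(seq_len(n), function(i) {
      suppressWarnings(warfarin_dose(
        meta$age[i], meta$height[i], meta$weight[i],
        vkorc1_genotype[i], cyp2c9_diplotype[i])$daily_mg)
    }, numeric(1))]
  }
  if ("SLCO1B1" %in% genes_present) {
    calls[, slco1b1_diplotype := dipl$SLCO1B1]
    calls[, slco1b1_risk := vapply(dipl$SLCO1B1, slco1b1_risk, character(1),
                                   star_table = star_table)]
  }
  for (g in intersect(c("ALDH2", "ADH1B", "CYP1A2"), genes_present)) {
    defs <- star_table[gene == g]
    for (r in seq_len(nrow(defs))) {
      dos <- geno[defs$rsid[r], ]
      lab <- paste0(defs$rsid[r], "_genotype")
      gts <- c(paste0(defs$ref[r], "/", defs$ref[r]),
               paste0(defs$ref[r], "/", defs$alt[r]),
               paste0(defs$alt[r], "/", defs$alt[r]))
      calls[, (lab) := gts[dos + 1L]]
    }
  }
  if ("population" %in% names(meta)) calls[, population := meta$population]
  data.table::setattr(calls, "class", c("pgx_callset", class(calls)))
  calls
}

#' Cohort pharmacogenomic frequency summary
#'
#' Counts and fractions of each categorical call, overall and stratified by
#' population label; fractions sum to 1 within each stratum. Also reports
#' the CYP2C19 intermediate + poor metabolizer aggregate (the fraction of
#' samples needing alternative clopidogrel therapy).
#'
#' @param callset [pgx_call_samples()] output.
#' @param by optional stratification column (default `"population"` when
#'   present).
#' @return list of class `pgx_summary`: `tables` (named list of data.tables
#'   category/stratum/n/fraction), `cyp2c19_im_pm_fraction`.
#' @export
cohort_pgx_summary <- function(callset, by = NULL) {
  if (nrow(callset) == 0) stop("empty callset")
  cat_cols <- setdiff(names(callset)[vapply(callset, is.character,
                                            logical(1))],
                      c("sample_id", "population"))
  if (is.null(by) && "population" %in% names(callset)) by <- "population"
  tables <- list()
  for (cc in cat_cols) {
    overall <- callset[, .(n = .N), by = cc][, fraction := n / sum(n)]
    data.table::setnames(overall, cc, "category")
    overall[, stratum := "all"]
    tab <- overall
    if (!is.null(by)) {
      strat <- callset[, .(n = .N), by = c(by, cc)]
      strat[, fraction := n / sum(n), by = by]
      data.table::setnames(strat, c(by, cc), c("stratum", "category"))
      tab <- rbind(overall, strat, use.names = TRUE, fill = TRUE)
    }
    tables[[cc]] <- tab[, .(category, stratum, n, fraction)]
  }
  im_pm <- NA_real_
  if ("cyp2c19_phenotype" %in% names(callset)) {
    im_pm <- mean(callset$cyp2c19_phenotype %in% c("intermediate", "poor"))
  }
  structure(list(tables = tables, cyp2c19_im_pm_fraction = im_pm),
            class = "pgx_summary")
}
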