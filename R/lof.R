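# lof_constraint module: miniature consequence engine, potential-LOF
# enumeration, per-gene OP ratios and rare-variant group files.

PLOF_CLASSES <- c("stop_gained", "stop_lost", "start_lost", "splice_disrupt",
                  "frameshift")

# Precompute per-gene structures the engine needs: CDS genomic positions in
# coding order, the CDS sequence, codon table and essential splice positions.
build_gene_index <- function(gene_models, reference) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  seqs <- unclass(reference)
  idx <- vector("list", nrow(genes))
  names(idx) <- genes$gene_id
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ex <- exons[gene_id == gid][order(exon_rank)]
    cds_pos <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
    if (length(cds_pos) %% 3L != 0L) {
      warning("gene ", gid, " has CDS length not divisible by 3; skipped")
      next
    }
    seq <- seqs[[genes$contig[i]]]
    cds <- paste(substring(seq, cds_pos, cds_pos), collapse = "")
    n_codons <- nchar(cds) / 3L
    codons <- substring(cds, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
    splice <- integer(0)
    if (nrow(ex) > 1) {
      for (e in seq_len(nrow(ex) - 1L)) {
        splice <- c(splice, ex$end[e] + 1L, ex$end[e] + 2L,
                    ex$start[e + 1L] - 2L, ex$start[e + 1L] - 1L)
      }
    }
    idx[[gid]] <- list(
      gene_id = gid, contig = genes$contig[i],
      start = genes$start[i], end = genes$end[i],
      cds_pos = cds_pos, cds = cds, codons = codons, aa = unname(code[codons]),
      n_codons = n_codons, splice_pos = splice)
  }
  idx[!vapply(idx, is.null, logical(1))]
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

classify_snv_in_gene <- function(g, pos, ref, alt) {
  if (pos %in% g$splice_pos) return("splice_disrupt")
  k <- match(pos, g$cds_pos)
  if (is.na(k)) return("noncoding")
  codon_i <- (k - 1L) %/% 3L + 1L
  phase <- (k - 1L) %% 3L + 1L
  codon <- g$codons[codon_i]
  if (substring(codon, phase, phase) != ref) {
    warning("reference base mismatch at ", g$contig, ":", pos)
  }
  new_codon <- codon
  substring(new_codon, phase, phase) <- alt
  aa_ref <- g$aa[codon_i]
  aa_alt <- translate_codon(new_codon)
  if (codon_i == 1L) {
    if (new_codon == codon) return("synonymous")
    return("start_lost")
  }
  if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
  if (aa_ref != "*" && aa_alt == "*") return("stop_gained")
  if (aa_ref == aa_alt) return("synonymous")
  "missense"
}

#' Annotate the consequence of a variant against the gene models
#'
#' Single-transcript, plus-strand consequence calls: SNVs in CDS are
#' translated in frame (stop_gained / stop_lost / start_lost / synonymous /
#' missense), SNVs at the four essential splice positions of each intron
#' (donor +1/+2, acceptor -2/-1) are splice_disrupt, CDS-overlapping indels
#' are frameshift when the length change is not a multiple of 3 and
#' inframe_indel otherwise; everything else is noncoding. pLOF =
#' stop_gained, stop_lost, start_lost, splice_disrupt or frameshift.
#'
#' @param sites data.table with contig, pos, ref, alt (one alt per row).
#' @param gene_models list with `genes`/`exons` tables (a
#'   `synth_annotations` works directly).
#' @param reference `synth_reference`.
#' @param gene_index optional precomputed [build_gene_index()] output.
#' @return data.table: the input columns plus gene_id, class, is_plof.
#' @export
annotate_consequence <- function(sites, gene_models, reference,
                                 gene_index = NULL) {
  gi <- gene_index %||% build_gene_index(gene_models, reference)
  out <- data.table::copy(data.table::as.data.table(sites))
  out[, `:=`(gene_id = NA_character_, class = "noncoding")]
  if (length(gi)) {
    starts <- vapply(gi, `[[`, numeric(1), "start")
    ends <- vapply(gi, `[[`, numeric(1), "end")
    contigs <- vapply(gi, `[[`, character(1), "contig")
    for (r in seq_len(nrow(out))) {
      hit <- which(contigs == out$contig[r] & starts <= out$pos[r] &
                     ends >= out$pos[r])
      if (!length(hit)) next
      g <- gi[[hit[1]]]
      ref <- out$ref[r]; alt <- out$alt[r]
      cls <- if (nchar(ref) == nchar(alt) && nchar(ref) == 1L) {
        classify_snv_in_gene(g, out$pos[r], ref, alt)
      } else {
        # indel: affected reference footprint is pos..pos+nchar(ref)-1
        span <- out$pos[r]:(out$pos[r] + nchar(ref) - 1L)
        if (any(span %in% g$cds_pos)) {
          if (abs(nchar(ref) - nchar(alt)) %% 3L != 0L) "frameshift"
          else "inframe_indel"
        } else if (any(span %in% g$splice_pos)) {
          "splice_disrupt"
        } else "noncoding"
      }
      data.table::set(out, r, "gene_id", g$gene_id)
      data.table::set(out, r, "class", cls)
    }
  }
  out[, is_plof := class %in% PLOF_CLASSES]
  out[]
}

#' Enumerate potential loss-of-function SNV alleles of a gene
#'
#' Iterates every CDS position x 3 alternative bases plus the 4 essential
#' splice positions per intron x 3 bases, and counts the alternate alleles
#' whose consequence is pLOF. Deterministic; the alt-allele (event) count is
#' returned, with the position-level count as an attribute.
#'
#' @param gene a single-gene index entry ([build_gene_index()]) or a gene id
#'   present in `gene_models`.
#' @param gene_models,reference used when `gene` is an id.
#' @return integer count of potential pLOF alt alleles; attributes
#'   `n_positions` (distinct positions with >= 1 pLOF alt) and `by_class`.
#' @export
enumerate_potential_lof <- function(gene, gene_models = NULL,
                                    reference = NULL) {
  g <- if (is.character(gene)) {
    build_gene_index(gene_models, reference)[[gene]]
  } else gene
  if (is.null(g)) stop("unknown or skipped gene")
  if (g$n_codons < 3L) stop("gene too short: no internal codons")
  code <- Biostrings::GENETIC_CODE
  n <- g$n_codons
  counts <- c(stop_gained = 0L, stop_lost = 0L, start_lost = 0L,
              splice_disrupt = 3L * length(g$splice_pos))
  # vectorize over the 9 (phase, alt-base) substitutions applied to all codons
  codons <- g$codons
  aa_ref <- g$aa
  pos_hit <- character(0)
  for (phase in 1:3) {
    ref_base <- substring(codons, phase, phase)
    for (b in BASES) {
      valid <- ref_base != b
      new_codons <- codons
      substring(new_codons, phase, phase) <- b
      aa_alt <- unname(code[new_codons])
      is_start <- seq_len(n) == 1L
      plof <- valid & (
        is_start |                                   # any start-codon change
        (aa_ref == "*" & aa_alt != "*") |            # stop_lost
        (aa_ref != "*" & aa_alt == "*" & !is_start)) # stop_gained
      counts["start_lost"] <- counts["start_lost"] + sum(plof & is_start)
      counts["stop_lost"] <- counts["stop_lost"] +
        sum(plof & !is_start & aa_ref == "*")
      counts["stop_gained"] <- counts["stop_gained"] +
        sum(plof & !is_start & aa_ref != "*")
      if (any(plof)) {
        ci <- which(plof)
        pos_hit <- c(pos_hit, paste0(g$cds_pos[3L * (ci - 1L) + phase]))
      }
    }
  }
  total <- as.integer(sum(counts))
  structure(total,
            n_positions = length(unique(pos_hit)) + length(g$splice_pos),
            by_class = counts)
}

#' Per-gene constraint table (observed / potential LOF, knockouts)
#'
#' Counts, per gene, the distinct pLOF alternate alleles observed in the
#' cohort, the potential pLOF SNV alleles
#' ([enumerate_potential_lof()]), their ratio (the OP ratio), whether any
#' sample is homozygous for a rare (AF < `af_threshold`) pLOF allele
#' ("human knockout"), and the externally annotated pLI with the
#' LOF-intolerant call (pLI >= 0.9).
#'
#' @param cohort a normalized `cohort` with genotypes.
#' @param gene_models gene models (`synth_annotations` or list).
#' @param reference `synth_reference`.
#' @param pli_annotations optional data.table (gene_id, pli); genes absent
#'   get `NA` pLI and are not LOF-intolerant.
#' @param af_threshold rare-variant AF cutoff (default 0.01).
#' @param annotated optional precomputed [annotate_consequence()] output.
#' @return data.table: gene_id, observed_lof, potential_lof, op_ratio,
#'   has_hom_rare_plof, pli, is_lof_intolerant.
#' @export
gene_constraint_table <- function(cohort, gene_models, reference,
                                  pli_annotations = NULL,
                                  af_threshold = 0.01, annotated = NULL) {
  gi <- build_gene_index(gene_models, reference)
  if (anyDuplicated(names(gi))) stop("duplicate gene ids")
  ann <- annotated %||% annotate_consequence(cohort$sites, gene_models,
                                             reference, gene_index = gi)
  res <- data.table::data.table(gene_id = names(gi))
  pot <- vapply(gi, function(g) as.integer(enumerate_potential_lof(g)),
                integer(1))
  res[, potential_lof := pot[gene_id]]
  obs_tab <- ann[is_plof == TRUE & !is.na(gene_id),
                 .(observed_lof = data.table::uniqueN(paste(pos, alt))),
                 by = gene_id]
  res <- merge(res, obs_tab, by = "gene_id", all.x = TRUE)
  res[is.na(observed_lof), observed_lof := 0L]
  res[, op_ratio := pmin(observed_lof / potential_lof, 1)]
  # human knockouts: homozygous rare pLOF in >= 1 sample
  res[, has_hom_rare_plof := FALSE]
  if (!is.null(cohort$geno)) {
    rare_plof <- which(ann$is_plof & !is.na(ann$gene_id) &
                         cohort$sites$af < af_threshold)
    if (length(rare_plof)) {
      hom_any <- rowSums(cohort$geno[rare_plof, , drop = FALSE] == 2L,
                         na.rm = TRUE) > 0
      ko_genes <- unique(ann$gene_id[rare_plof[hom_any]])
      res[gene_id %in% ko_genes, has_hom_rare_plof := TRUE]
    }
  }
  if (!is.null(pli_annotations)) {
    res <- merge(res, pli_annotations[, .(gene_id, pli)], by = "gene_id",
                 all.x = TRUE)
  } else {
    res[, pli := NA_real_]
  }
  res[, is_lof_intolerant := !is.na(pli) & pli >= 0.9]
  data.table::setcolorder(res, c("gene_id", "observed_lof", "potential_lof",
                                 "op_ratio", "has_hom_rare_plof", "pli",
                                 "is_lof_intolerant"))
  res[]
}

#' Gene-based multiple-testing significance threshold
#'
#' Bonferroni-style genome-wide gene-test threshold, alpha divided by the
#' number of protein-coding genes tested (0.05 / 20,000 = 2.5e-6 by
#' default).
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_genes number of genes tested (default 20,000).
#' @return the per-test significance threshold.
#' @export
gene_test_threshold <- function(alpha = 0.05, n_genes = 20000L) {
  stopifnot(alpha > 0, alpha < 1, n_genes >= 1)
  alpha / n_genes
}

#' Rare-variant groups for burden/kernel association tests
#'
#' Per gene, the set of variants with MAF below `maf_threshold` that are
#' either pLOF or flagged deleterious by external predictions (supplied as
#' input annotations). Genes with empty sets are omitted.
#'
#' @param annotated [annotate_consequence()] output carrying af and id.
#' @param deleterious_flags optional data.table (contig, pos, ref, alt,
#'   flag); rows referencing unknown sites are skipped with a warning.
#' @param maf_threshold MAF cutoff (default 0.01).
#' @return named list gene_id -> character vector of variant ids.
#' @export
build_rare_variant_groups <- function(annotated, deleterious_flags = NULL,
                                      maf_threshold = 0.01) {
  ann <- data.table::copy(annotated)
  ann[, maf := pmin(af, 1 - af)]
  ann[, deleterious := FALSE]
  if (!is.null(deleterious_flags) && nrow(deleterious_flags)) {
    key <- paste(ann$contig, ann$pos, ann$ref, ann$alt)
    fkey <- paste(deleterious_flags$contig, deleterious_flags$pos,
                  deleterious_flags$ref, deleterious_flags$alt)
    miss <- !(fkey %in% key)
    if (any(miss)) {
      warning(sum(miss), " deleterious flags reference unknown sites; skipped")
    }
    flagged <- key %in% fkey[deleterious_flags$flag & !miss]
    ann[, deleterious := flagged]
  }
  sel <- ann[!is.na(gene_id) & maf < maf_threshold & (is_plof | deleterious)]
  if (nrow(sel) == 0) return(list())
  split(sel$id, sel$gene_id)
}

#' Write rare-variant groups to a group file
#'
#' One gene per line: gene id followed by its variant ids, tab-separated —
#' the layout burden/SKAT drivers consume.
#'
#' @param groups [build_rare_variant_groups()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_group_file <- function(groups, path) {
  lines <- vapply(names(groups), function(g) {
    paste(c(g, groups[[g]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
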