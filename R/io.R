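# Text-format writers for the synthetic cohort, and a VCF reader.
# FASTA goes through Biostrings (see sim-reference.R); the VCF writer is a
# minimal GT-only VCFv4.2 emitter (INFO AC/AN/AF/TRUE_CLASS).

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features (1-based closed coordinates) for the
#' single-transcript synthetic gene models.
#'
#' @param annotations a `synth_annotations` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(annotations, path) {
  genes <- annotations$genes
  exons <- annotations$exons
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    lines <- c(lines,
      sprintf("%s\tvarcohort\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              genes$contig[i], genes$start[i], genes$end[i],
              genes$strand[i], gid),
      sprintf("%s\tvarcohort\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              genes$contig[i], genes$start[i], genes$end[i],
              genes$strand[i], gid, gid))
    ex <- exons[gene_id == gid][order(exon_rank)]
    # phase of CDS piece k = (3 - cumulative CDS length before k) mod 3
    before <- cumsum(c(0L, ex$end - ex$start + 1L))[seq_len(nrow(ex))]
    phase <- (3L - before %% 3L) %% 3L
    lines <- c(lines, sprintf(
      "%s\tvarcohort\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
      genes$contig[i], ex$start, ex$end, genes$strand[i], phase, gid, gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read synthetic gene models from GFF3
#'
#' Parses the gene/CDS features written by [write_gene_models_gff3()] back
#' into the `genes`/`exons` tables the consequence engine consumes.
#'
#' @param path GFF3 file.
#' @return list with `genes` and `exons` data.tables.
#' @export
read_gene_models_gff3 <- function(path) {
  raw <- data.table::fread(text = grep("^[^#]", readLines(path), value = TRUE),
                           sep = "\t", header = FALSE,
                           col.names = c("contig", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attr"))
  gid <- function(a) sub("^.*ID=([^;.]+).*$", "\\1", a)
  genes <- raw[type == "gene",
               .(gene_id = gid(attr), contig, strand, start, end)]
  exons <- raw[type == "CDS", .(gene_id = gid(attr), start, end)]
  data.table::setorder(exons, gene_id, start)
  exons[, exon_rank := seq_len(.N), by = gene_id]
  list(genes = genes, exons = exons[, .(gene_id, exon_rank, start, end)])
}

#' Write intervals to BED
#'
#' @param intervals data.table with contig, start, end (0-based half-open)
#'   and optionally further columns (e.g. `family`), written as BED name
#'   column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("contig", "start", "end", "family"), names(intervals))
  utils::write.table(intervals[, cols, with = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#' @param path BED file (3+ columns; 4th column taken as `family`).
#' @return data.table: contig, start, end (0-based half-open) and `family`
#'   when present.
#' @export
read_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE)
  names(bed)[1:3] <- c("contig", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "family"
  bed
}

#' Write a cohort to a multi-sample VCFv4.2
#'
#' GT-only FORMAT; INFO carries AC, AN, AF and (when present) the generator
#' truth label TRUE_CLASS. Genotypes are emitted unphased from the dosage
#' matrix (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.).
#'
#' @param cohort a `cohort` (or compatible list with sites/geno/samples).
#' @param path output file.
#' @param reference optional `synth_reference` for contig headers.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, reference = NULL) {
  sites <- cohort$sites
  geno <- cohort$geno
  ids <- if (is.data.frame(cohort$samples)) cohort$samples$sample_id else cohort$samples
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=varcohort",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called allele number\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
    "##INFO=<ID=TRUE_CLASS,Number=1,Type=String,Description=\"Simulated consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(reference)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(reference), nchar(unclass(reference))))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", ids),
                            collapse = "\t"))
  info <- sprintf("AC=%d;AN=%d;AF=%s", sites$ac, sites$an,
                  formatC(sites$af, format = "g", digits = 6))
  if ("true_class" %in% names(sites)) {
    info <- paste0(info, ";TRUE_CLASS=", sites$true_class)
  }
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(sites), ncol = length(ids))
  ok <- !is.na(geno)
  gt[ok] <- gt_code[geno[ok] + 1L]
  body <- paste(sites$contig, sites$pos, sites$id, sites$ref, sites$alt,
                ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a cohort
#'
#' Parses with \pkg{vcfR}; genotypes are converted to alt-allele dosages
#' (multiallelic records keep their ALT string for [normalize_sites()] to
#' split). INFO TRUE_CLASS is recovered when present.
#'
#' @param path VCF file.
#' @return a `cohort` list (sites, geno, samples).
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- data.table::data.table(
    contig = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT)
  tc <- vcfR::extract.info(v, "TRUE_CLASS")
  if (!all(is.na(tc))) sites[, true_class := tc]
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage of the FIRST alt allele; other alleles handled by normalize_sites
  # via the raw allele strings
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  num <- a1 %in% as.character(0:9) & a2 %in% as.character(0:9)
  dos[num] <- (a1[num] == "1") + (a2[num] == "1")
  gt_alleles <- matrix(paste(a1, a2, sep = "/"), nrow = nrow(gt))
  an <- 2L * rowSums(num & !is.na(gt))
  dim(an) <- NULL
  sites[, `:=`(an = as.integer(an))]
  ac <- rowSums(dos, na.rm = TRUE)
  sites[, `:=`(ac = as.integer(ac), af = ifelse(an > 0, ac / an, NA_real_))]
  sites[, is_indel := nchar(ref) != 1L | nchar(alt) != 1L]
  samples <- data.table::data.table(sample_id = colnames(gt))
  structure(list(sites = sites, geno = dos, gt_raw = gt_alleles,
                 samples = samples),
            class = "cohort")
}

#' Write a complete synthetic cohort to a directory
#'
#' Emits reference FASTA, gene models GFF3, element and LCR BEDs, the
#' multi-sample VCF and the sample-metadata TSV — every input the
#' downstream pipeline consumes.
#'
#' @param annotations a `synth_annotations`.
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @return named character vector of the paths written.
#' @export
write_synthetic_cohort <- function(annotations, cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "reference.fa"),
    gff = file.path(dir, "genes.gff3"),
    elements = file.path(dir, "elements.bed"),
    lcr = file.path(dir, "lcr.bed"),
    vcf = file.path(dir, "cohort.vcf"),
    meta = file.path(dir, "samples.tsv"))
  write_reference_fasta(annotations$reference, paths["fasta"])
  write_gene_models_gff3(annotations, paths["gff"])
  write_bed(annotations$elements, paths["elements"])
  write_bed(annotations$lcr, paths["lcr"])
  write_cohort_vcf(cohort, paths["vcf"], reference = annotations$reference)
  utils::write.table(cohort$samples, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
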