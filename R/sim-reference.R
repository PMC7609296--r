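#' Generate a random reference genome
#'
#' Draws an i.i.d. uniform A/C/G/T sequence of `config$genome_length` bp on a
#' single contig. At the 2 Mb default length the expected occurrence of each
#' of the 16,384 heptamers is ~122, so the heptamer tolerance table can be
#' fitted with every context observed many times.
#'
#' @param config a [sim_config()] object.
#' @param contig contig name (default `"chr1"`).
#' @return object of class `synth_reference`: named character vector of
#'   contig sequences.
#' @export
generate_reference <- function(config, contig = "chr1") {
  if (config$genome_length < 7) stop("degenerate config: genome shorter than one heptamer")
  seqs <- with_seed(config$seed, {
    paste(sample(BASES, config$genome_length, replace = TRUE), collapse = "")
  })
  names(seqs) <- contig
  structure(seqs, class = "synth_reference")
}

#' Write a reference to FASTA (60-column wrapping)
#'
#' @param reference `synth_reference` (named character vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  dna <- Biostrings::DNAStringSet(unclass(reference))
  Biostrings::writeXStringSet(dna, path, width = 60L)
  invisible(path)
}

#' Read a FASTA reference
#'
#' @param path FASTA file.
#' @return `synth_reference` named character vector.
#' @export
read_reference_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dna)
  names(seqs) <- sub("\\s.*$", "", names(dna))
  structure(seqs, class = "synth_reference")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# sample n sense (non-stop) codons
sample_sense_codons <- function(n) {
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  sample(sense, n, replace = TRUE)
}

#' Generate gene models, element annotation and an LCR mask
#'
#' Places `config$n_genes` non-overlapping plus-strand single-transcript
#' genes (1-4 CDS exons, in-frame ATG...stop open reading frame, GT/AG
#' essential splice sites, introns >= 20 bp) and rewrites the reference so
#' that every gene is a valid ORF. Genomic element families (promoter,
#' enhancer, exon, intron, others, intergenic) partition the genome without
#' overlap; a low-complexity (LCR) mask covers `config$lcr_fraction` of it.
#'
#' @param reference output of [generate_reference()].
#' @param config a [sim_config()].
#' @return list of class `synth_annotations` with elements `reference` (the
#'   edited reference), `genes` (data.table: gene_id, contig, strand, start,
#'   end — 1-based closed), `exons` (gene_id, exon_rank, start, end — CDS
#'   exons), `elements` (contig, start, end, family — 0-based half-open) and
#'   `lcr` (contig, start, end — 0-based half-open).
#' @export
generate_annotations <- function(reference, config) {
  contig <- names(reference)[1]
  seq <- unclass(reference)[[1]]
  L <- nchar(seq)
  n_genes <- config$n_genes
  block <- L %/% n_genes
  # worst case gene footprint: 200 codons + 3 introns of 200 bp + promoter
  if (block < 2600) stop("genome too short to place ", n_genes, " genes")

  with_seed(config$seed + 1L, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      n_codons <- sample(30:200, 1)
      cds_len <- 3L * n_codons
      n_exons <- sample(1:4, 1)
      # split CDS into n_exons chunks of >= 3 bp
      if (n_exons > 1) {
        cuts <- sort(sample(seq(3, cds_len - 3, by = 3), n_exons - 1))
        exon_len <- diff(c(0, cuts, cds_len))
      } else {
        exon_len <- cds_len
      }
      intron_len <- if (n_exons > 1) sample(20:200, n_exons - 1, replace = TRUE) else integer(0)
      span <- cds_len + sum(intron_len)
      lo <- (g - 1L) * block + 600L            # leave room for the promoter
      hi <- g * block - span - 50L
      start <- sample(lo:hi, 1)
      # exon coordinates
      ex_start <- integer(n_exons); ex_end <- integer(n_exons)
      pos <- start
      for (e in seq_len(n_exons)) {
        ex_start[e] <- pos
        ex_end[e] <- pos + exon_len[e] - 1L
        pos <- ex_end[e] + 1L
        if (e < n_exons) pos <- pos + intron_len[e]
      }
      gene_end <- ex_end[n_exons]
      # write ORF: ATG + sense codons + stop
      orf <- paste0("ATG", paste(sample_sense_codons(n_codons - 2L), collapse = ""),
                    sample(STOP_CODONS, 1))
      orf_chars <- strsplit(orf, "", fixed = TRUE)[[1]]
      cds_pos <- unlist(mapply(seq.int, ex_start, ex_end, SIMPLIFY = FALSE))
      chars[cds_pos] <- orf_chars
      # essential splice sites
      for (e in seq_len(n_exons - 1L)) {
        don <- ex_end[e] + 1L
        acc <- ex_start[e + 1L] - 2L
        chars[don] <- "G"; chars[don + 1L] <- "T"
        chars[acc] <- "A"; chars[acc + 1L] <- "G"
      }
      genes[[g]] <- data.table::data.table(
        gene_id = sprintf("GENE%03d", g), contig = contig, strand = "+",
        start = start, end = gene_end)
      exons[[g]] <- data.table::data.table(
        gene_id = sprintf("GENE%03d", g), exon_rank = seq_len(n_exons),
        start = ex_start, end = ex_end)
    }
    genes <- data.table::rbindlist(genes)
    exons <- data.table::rbindlist(exons)
    seq2 <- paste(chars, collapse = "")

    elements <- build_element_partition(contig, L, genes, exons)
    lcr <- build_lcr_mask(contig, L, config$lcr_fraction)

    ref2 <- structure(stats::setNames(seq2, contig), class = "synth_reference")
    structure(list(reference = ref2, genes = genes, exons = exons,
                   elements = elements, lcr = lcr),
              class = "synth_annotations")
  })
}

# Partition [0, L) into element families (BED, 0-based half-open):
# exon = CDS exons; intron = gene body minus exons; promoter = 500 bp
# upstream of each gene; enhancer/others carved from intergenic space;
# intergenic = remainder.
build_element_partition <- function(contig, L, genes, exons) {
  ir <- function(s, e) IRanges::IRanges(start = s, end = e)   # 1-based closed
  exon_r <- IRanges::reduce(ir(exons$start, exons$end))
  gene_r <- IRanges::reduce(ir(genes$start, genes$end))
  intron_r <- IRanges::setdiff(gene_r, exon_r)
  prom_r <- IRanges::reduce(ir(pmax(genes$start - 500L, 1L), genes$start - 1L))
  prom_r <- IRanges::setdiff(prom_r, gene_r)
  used <- IRanges::reduce(c(exon_r, intron_r, prom_r))
  inter_r <- IRanges::setdiff(ir(1L, L), used)
  # enhancers: a 400 bp slice at the start of each intergenic gap >= 2000 bp;
  # "others": a 300 bp slice at its end
  big <- inter_r[IRanges::width(inter_r) >= 2000L]
  enh_r <- IRanges::narrow(big, start = 301L, end = 700L)
  oth_r <- IRanges::narrow(big, start = IRanges::width(big) - 399L,
                           end = IRanges::width(big) - 100L)
  inter_r <- IRanges::setdiff(inter_r, IRanges::reduce(c(enh_r, oth_r)))
  fam <- function(r, f) {
    if (length(r) == 0) return(NULL)
    data.table::data.table(contig = contig, start = IRanges::start(r) - 1L,
                           end = IRanges::end(r), family = f)
  }
  out <- data.table::rbindlist(list(
    fam(prom_r, "promoter"), fam(enh_r, "enhancer"), fam(exon_r, "exon"),
    fam(intron_r, "intron"), fam(oth_r, "others"), fam(inter_r, "intergenic")))
  data.table::setorder(out, start)
  out[]
}

# Evenly spaced fixed-width LCR intervals covering `fraction` of the genome.
build_lcr_mask <- function(contig, L, fraction) {
  if (fraction <= 0) {
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer()))
  }
  width <- 500L
  n <- max(1L, round(fraction * L / width))
  if (n * width > L) stop("lcr_fraction too large for genome length")
  block <- L / n
  start0 <- floor((seq_len(n) - 1) * block + (block - width) / 2)
  data.table::data.table(contig = contig, start = as.integer(start0),
                         end = as.integer(start0 + width))
}
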