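vcf_header <- function(sample = NULL, contigs = NULL) {
  h <- c(
    "##fileformat=VCFv4.2",
    "##source=editscan",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), unname(contigs))
    },
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand bias\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">"
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample)) cols <- c(cols, "FORMAT", sample)
  c(h, paste(cols, collapse = "\t"))
}

#' Write variant observations of one sample to a VCF file
#'
#' Restores the VCF convention (1-based positions); the inverse of
#' [read_variant_vcf()] for single-sample tables.
#'
#' @param obs Observation tibble for a single sample (`chrom`, `pos`, `ref`,
#'   `alt`, `ref_reads`, `alt_reads`, `fs`, `qd`).
#' @param path Output path.
#' @param sample_id Sample column name; defaults to the table's `sample_id`.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(obs, path, sample_id = NULL, contigs = NULL) {
  sample_id <- sample_id %||% unique(obs$sample_id)
  check_that(length(sample_id) == 1, "write_variant_vcf() takes one sample")
  obs <- obs[order(obs$chrom, obs$pos, obs$alt), , drop = FALSE]
  info <- paste0(
    ifelse(is.na(obs$fs), "", sprintf("FS=%.3g", obs$fs)),
    ifelse(is.na(obs$fs) | is.na(obs$qd), "", ";"),
    ifelse(is.na(obs$qd), "", sprintf("QD=%.3g", obs$qd))
  )
  info[info == ""] <- "."
  lines <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:AD\t0/1:%d,%d",
    obs$chrom, obs$pos + 1L, obs$ref, obs$alt, info,
    obs$ref_reads, obs$alt_reads
  )
  writeLines(c(vcf_header(sample_id, contigs), lines), path)
  invisible(path)
}

#' Write a sites-only VCF of positions (e.g. known SNPs)
#'
#' @param snps Tibble with `chrom`, `pos` (0-based), optionally `ref`, `alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  ref <- if ("ref" %in% names(snps)) snps$ref else rep("N", nrow(snps))
  alt <- if ("alt" %in% names(snps)) snps$alt else rep(".", nrow(snps))
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                   snps$chrom, snps$pos + 1L, ref, alt)
  writeLines(c(vcf_header(), lines), path)
  invisible(path)
}

#' Write gene models to an Ensembl-style GTF file
#'
#' @param models Gene-model tibble as returned by [read_gene_models()]
#'   (intron rows are skipped: introns are derived, not stored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  m <- dplyr::filter(models, .data$feature != "intron")
  type_map <- c(exon = "exon", cds = "CDS",
                utr5 = "five_prime_utr", utr3 = "three_prime_utr")
  lines <- sprintf(
    "%s\teditscan\t%s\t%d\t%d\t.\t%s\t%s\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\"; gene_biotype \"%s\";",
    m$chrom, unname(type_map[m$feature]), m$start + 1L, m$end, m$strand,
    ifelse(is.na(m$frame), ".", as.character(m$frame)),
    m$gene_id, m$transcript_id, m$gene_name, m$gene_type
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param rna Write in the RNA alphabet (T converted back to U).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  s <- if (rna) chartr("T", "U", seqs) else seqs
  writeLines(paste0(">", names(s), "\n", unname(s)), path)
  invisible(path)
}

#' Write editing sites to a BED6 file
#'
#' BED is natively 0-based half-open, matching the internal convention.
#'
#' @param sites Site tibble with `chrom`, `pos`, `site_id`, optionally
#'   `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  strand <- sites$strand %||% rep(".", nrow(sites))
  strand[is.na(strand) | strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   sites$chrom, sites$pos, sites$pos + 1L,
                   sites$site_id, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write an expression matrix to TSV
#'
#' @param counts Gene-by-sample integer matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(counts, path) {
  df <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}
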