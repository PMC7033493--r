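#' Classify a substitution and call A-to-I status
#'
#' The reference-strand label (e.g. `"A-to-G"`) is always produced; the
#' A-to-I flag is strand-aware: true iff ref A / alt G on a `+` strand
#' gene or ref T / alt C on a `-` strand gene. Unknown strand (intergenic)
#' gives a false flag, since the edit cannot be oriented.
#'
#' @param ref,alt Single-nucleotide alleles (reference strand).
#' @param strand Gene strand: `"+"`, `"-"` or `NA`.
#' @return Tibble with `variant_type` and `is_a_to_i`.
#' @export
#' @examples
#' classify_variant_type("A", "G", "+")
#' classify_variant_type("T", "C", "-")
classify_variant_type <- function(ref, alt, strand) {
  check_that(all(is_snv(ref, alt)), "alleles must be single nucleotides")
  tibble(
    variant_type = paste0(ref, "-to-", alt),
    is_a_to_i = (!is.na(strand)) &
      ((ref == "A" & alt == "G" & strand == "+") |
       (ref == "T" & alt == "C" & strand == "-"))
  )
}

FEATURE_PRECEDENCE <- c("cds", "utr3", "utr5", "intron", "exonic")

#' Assign each site its gene and genomic feature
#'
#' When a site maps to multiple features of a gene across isoforms, the
#' fixed precedence CDS > 3'UTR > 5'UTR > intron applies (exonic
#' non-coding last); a site outside all genes is intergenic.
#'
#' @param sites Tibble with `chrom`, `pos` (0-based).
#' @param gene_models Gene-model tibble from [read_gene_models()].
#' @return `sites` with `gene_id`, `gene_name`, `gene_type`,
#'   `gene_strand`, `transcript_id` (a transcript carrying the winning
#'   feature), `feature` columns; intergenic sites carry `NA` gene fields
#'   and feature `"intergenic"`.
#' @export
assign_feature <- function(sites, gene_models) {
  gm <- dplyr::filter(gene_models, .data$feature %in% FEATURE_PRECEDENCE |
                        .data$feature == "exon")
  gr_s <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L, width = 1L))
  gr_f <- GenomicRanges::GRanges(gm$chrom,
                                 IRanges::IRanges(gm$start + 1L, gm$end))
  hits <- GenomicRanges::findOverlaps(gr_s, gr_f, ignore.strand = TRUE)
  ann <- tibble(
    si = S4Vectors::queryHits(hits),
    gene_id = gm$gene_id[S4Vectors::subjectHits(hits)],
    gene_name = gm$gene_name[S4Vectors::subjectHits(hits)],
    gene_type = gm$gene_type[S4Vectors::subjectHits(hits)],
    gene_strand = gm$strand[S4Vectors::subjectHits(hits)],
    transcript_id = gm$transcript_id[S4Vectors::subjectHits(hits)],
    feature = gm$feature[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::mutate(feature = ifelse(.data$feature == "exon", "exonic",
                                   .data$feature),
                  rank = match(.data$feature, FEATURE_PRECEDENCE)) |>
    dplyr::group_by(.data$si) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  out <- dplyr::mutate(sites,
    gene_id = NA_character_, gene_name = NA_character_,
    gene_type = NA_character_, gene_strand = NA_character_,
    transcript_id = NA_character_, feature = "intergenic")
  out$gene_id[ann$si] <- ann$gene_id
  out$gene_name[ann$si] <- ann$gene_name
  out$gene_type[ann$si] <- ann$gene_type
  out$gene_strand[ann$si] <- ann$gene_strand
  out$transcript_id[ann$si] <- ann$transcript_id
  out$feature[ann$si] <- ann$feature
  out
}

# spliced CDS sequence of a transcript in sense orientation, together with
# the transcript-order CDS intervals used to map genomic positions
transcript_cds <- function(gene_models, transcript_id, genome) {
  cds <- gene_models |>
    dplyr::filter(.data$transcript_id == !!transcript_id,
                  .data$feature == "cds") |>
    dplyr::arrange(.data$start)
  if (nrow(cds) == 0) return(NULL)
  minus <- cds$strand[[1]] == "-"
  if (minus) cds <- cds[rev(seq_len(nrow(cds))), ]
  pieces <- purrr::map_chr(seq_len(nrow(cds)), function(i) {
    s <- substr(genome[[cds$chrom[[i]]]], cds$start[[i]] + 1L, cds$end[[i]])
    if (minus) revcomp(s) else s
  })
  list(seq = paste(pieces, collapse = ""), intervals = cds, minus = minus)
}

# 0-based position within the spliced CDS, or NA if not in the CDS
cds_offset <- function(cds, pos) {
  off <- 0L
  for (i in seq_len(nrow(cds$intervals))) {
    iv <- cds$intervals[i, ]
    if (pos >= iv$start && pos < iv$end) {
      within <- if (cds$minus) iv$end - 1L - pos else pos - iv$start
      return(off + within)
    }
    off <- off + (iv$end - iv$start)
  }
  NA_integer_
}

#' Coding or splicing consequence of an editing site
#'
#' For a site in the CDS of a complete transcript, the edited codon is
#' translated with the standard genetic code and compared to the
#' reference codon: same amino acid gives `"synonymous"`, a different one
#' `"non-synonymous"`, an introduced stop `"stop_gain"`, a removed stop
#' `"stop_loss"`. Intronic sites within 2 bp of an exon boundary (the
#' canonical donor/acceptor dinucleotides) give `"splicing"`. Incomplete
#' transcripts or a CDS whose length is not divisible by 3 give
#' `"unknown"`; anything else is `"not_applicable"`.
#'
#' @param site One-row tibble (or list) with `chrom`, `pos`, `ref`, `alt`,
#'   `feature`, `transcript_id`.
#' @param gene_models Gene-model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @return Tibble with `coding_consequence` and `aa_change` (e.g.
#'   `"S367G"`, `NA` when not applicable).
#' @export
coding_consequence <- function(site, gene_models, genome) {
  none <- function(cons) tibble(coding_consequence = cons,
                                aa_change = NA_character_)
  if (is.na(site$transcript_id)) return(none("not_applicable"))
  tx <- dplyr::filter(gene_models,
                      .data$transcript_id == site$transcript_id)
  if (site$feature == "intron") {
    exons <- dplyr::filter(tx, .data$feature == "exon")
    near <- any(site$pos < exons$start & site$pos >= exons$start - 2L) ||
      any(site$pos >= exons$end & site$pos < exons$end + 2L)
    return(none(if (near) "splicing" else "not_applicable"))
  }
  if (site$feature != "cds") return(none("not_applicable"))
  if (!all(tx$complete)) return(none("unknown"))
  cds <- transcript_cds(gene_models, site$transcript_id, genome)
  if (is.null(cds) || nchar(cds$seq) %% 3L != 0L) return(none("unknown"))
  off <- cds_offset(cds, site$pos)
  if (is.na(off)) return(none("unknown"))
  minus <- cds$minus
  ref_t <- if (minus) complement_base(site$ref) else site$ref
  alt_t <- if (minus) complement_base(site$alt) else site$alt
  if (substr(cds$seq, off + 1L, off + 1L) != ref_t) return(none("unknown"))
  codon_i <- off %/% 3L
  codon <- substr(cds$seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  codon_pos <- off %% 3L + 1L
  edited <- codon
  substr(edited, codon_pos, codon_pos) <- alt_t
  aa_ref <- GENETIC_CODE_TABLE[[codon]]
  aa_alt <- GENETIC_CODE_TABLE[[edited]]
  cons <- if (aa_ref == aa_alt) {
    "synonymous"
  } else if (aa_alt == "*") {
    "stop_gain"
  } else if (aa_ref == "*") {
    "stop_loss"
  } else {
    "non-synonymous"
  }
  tibble(coding_consequence = cons,
         aa_change = paste0(aa_ref, codon_i + 1L, aa_alt))
}

GENETIC_CODE_TABLE <- local({
  gc <- as.list(Biostrings::GENETIC_CODE)
  gc
})

#' Annotate an editing-site catalog
#'
#' Adds variant type, A-to-I status, gene assignment, feature class and
#' coding/splicing consequence to every site of a catalog.
#'
#' @param catalog An `"editing_catalog"` or a site tibble with `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param gene_models Gene-model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @return The site tibble with annotation columns appended.
#' @export
annotate_sites <- function(catalog, gene_models, genome) {
  sites <- if (inherits(catalog, "editing_catalog")) catalog$sites else catalog
  sites <- assign_feature(sites, gene_models)
  vt <- classify_variant_type(sites$ref, sites$alt, sites$gene_strand)
  sites$variant_type <- vt$variant_type
  sites$is_a_to_i <- vt$is_a_to_i
  cons <- purrr::map(seq_len(nrow(sites)), function(i) {
    coding_consequence(sites[i, ], gene_models, genome)
  }) |> dplyr::bind_rows()
  dplyr::bind_cols(sites, cons)
}
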