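#' Read per-sample variant observations from a VCF file
#'
#' Parses a VCF v4.2 file into a tibble of candidate variant observations,
#' one row per sample x alternate allele. Positions are converted to the
#' package-internal 0-based half-open convention, multi-allelic records are
#' split into one observation per alternate allele, and the `FS` / `QD`
#' quality annotations are carried through (`NA` when absent from INFO --
#' absent is recorded, never coerced to zero). Allele depths are taken from
#' the `AD` FORMAT field.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier to assign when the VCF carries a single
#'   unnamed sample column; defaults to the VCF sample name.
#' @return A tibble with columns `sample_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `ref_reads`, `alt_reads`, `fs`, `qd`.
#' @export
read_variant_vcf <- function(path, sample_id = NULL) {
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(),
      ref_reads = integer(), alt_reads = integer(),
      fs = double(), qd = double()
    ))
  }
  fs <- suppressWarnings(as.numeric(vcfR::extract.info(v, "FS")))
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  if (length(samples) == 1 && !is.null(sample_id)) samples <- sample_id

  base <- tibble(
    chrom = normalize_chrom(fix$CHROM),
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt_field = fix$ALT,
    fs = fs,
    qd = qd
  )
  out <- purrr::map(seq_along(samples), function(j) {
    dplyr::mutate(base, sample_id = samples[[j]], ad = unname(ad[, j]))
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::filter(out, !is.na(.data$ad))

  # split multi-allelic records: ALT "G,T" with AD "7,3,1" becomes two
  # observations sharing ref_reads = 7
  alt_list <- stringr::str_split(out$alt_field, ",")
  ad_list <- stringr::str_split(out$ad, ",")
  n_alt <- lengths(alt_list)
  idx <- rep.int(seq_len(nrow(out)), n_alt)
  which_alt <- sequence(n_alt)
  res <- tibble(
    sample_id = out$sample_id[idx],
    chrom = out$chrom[idx],
    pos = out$pos[idx],
    ref = out$ref[idx],
    alt = unlist(alt_list),
    ref_reads = as.integer(purrr::map_chr(ad_list, 1))[idx],
    alt_reads = as.integer(unlist(purrr::map2(ad_list, n_alt, function(a, k) a[2:(k + 1)]))),
    fs = out$fs[idx],
    qd = out$qd[idx]
  )
  res[order(res$chrom, res$pos, res$alt), , drop = FALSE]
}

validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    nf <- length(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (nf < 8) {
      abort(sprintf("malformed VCF line %d in %s: %d fields (>= 8 required)",
                    i, path, nf))
    }
  }
  invisible(TRUE)
}

#' Read SNP positions from a sites-only VCF
#'
#' @param path Path to a VCF of known polymorphic positions (e.g. a dbSNP
#'   extract). Only positions are used; exclusion downstream is
#'   position-based, not allele-matched.
#' @return A tibble with columns `chrom`, `pos` (0-based).
#' @export
read_snp_positions <- function(path) {
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  dplyr::distinct(tibble(
    chrom = normalize_chrom(fix$CHROM),
    pos = as.integer(fix$POS) - 1L
  ))
}

#' Read per-sample somatic mutations from a tab-separated table
#'
#' @param path TSV with columns `sample_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @return Tibble with `pos` converted to 0-based.
#' @export
read_mutations <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  check_that(all(c("sample_id", "chrom", "pos") %in% names(x)),
             "mutation table must have sample_id, chrom, pos columns")
  dplyr::mutate(as_tibble(x),
                chrom = normalize_chrom(.data$chrom),
                pos = as.integer(.data$pos) - 1L)
}

#' Read gene models from a GTF file
#'
#' Assembles one record per transcript feature from an Ensembl-style GTF
#' (`exon`, `CDS`, `five_prime_utr`, `three_prime_utr` features with
#' `gene_id`, `gene_name`, `gene_biotype`, `transcript_id` attributes), and
#' derives intron intervals as the within-transcript complement of the
#' exons. Coordinates are converted to 0-based half-open.
#'
#' A CDS feature without a frame (phase) triggers a warning and marks the
#' transcript incomplete; coding consequences for incomplete transcripts are
#' reported as `"unknown"` downstream.
#'
#' @param path Path to a GTF file.
#' @return A tibble of gene-model features with columns `gene_id`,
#'   `gene_name`, `gene_type`, `chrom`, `strand`, `transcript_id`,
#'   `feature` (`exon`, `cds`, `utr5`, `utr3`, `intron`), `start`, `end`
#'   (0-based half-open), `frame`, `complete` (transcript-level flag).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  feature_map <- c(exon = "exon", CDS = "cds",
                   five_prime_utr = "utr5", three_prime_utr = "utr3")
  df <- dplyr::filter(df, .data$type %in% names(feature_map))
  gene_type <- df$gene_biotype %||% df$gene_type
  out <- tibble(
    gene_id = df$gene_id,
    gene_name = df$gene_name %||% df$gene_id,
    gene_type = dplyr::case_when(
      gene_type == "protein_coding" ~ "protein_coding",
      gene_type %in% c("lncRNA", "lincRNA") ~ "lncRNA",
      TRUE ~ "other"
    ),
    chrom = normalize_chrom(as.character(df$seqnames)),
    strand = as.character(df$strand),
    transcript_id = df$transcript_id,
    feature = unname(feature_map[as.character(df$type)]),
    start = df$start - 1L,
    end = df$end,
    frame = if ("phase" %in% names(df)) as.integer(df$phase) else NA_integer_
  )
  # transcripts whose CDS lacks a frame are incomplete
  bad <- out |>
    dplyr::filter(.data$feature == "cds", is.na(.data$frame)) |>
    dplyr::pull(.data$transcript_id) |>
    unique()
  if (length(bad) > 0) {
    warn(sprintf("%d transcript(s) have CDS without frame; marked incomplete",
                 length(bad)))
  }
  out$complete <- !(out$transcript_id %in% bad)
  dplyr::bind_rows(out, derive_introns(out)) |>
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start)
}

derive_introns <- function(models) {
  exons <- dplyr::filter(models, .data$feature == "exon")
  exons |>
    dplyr::group_by(.data$gene_id, .data$gene_name, .data$gene_type,
                    .data$chrom, .data$strand, .data$transcript_id,
                    .data$complete) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      istart = list(utils::head(.data$end, -1)),
      iend = list(utils::tail(.data$start, -1)),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("istart", "iend")) |>
    dplyr::rename(start = "istart", end = "iend") |>
    dplyr::filter(.data$end > .data$start) |>
    dplyr::mutate(feature = "intron", frame = NA_integer_)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and, for RNA inputs, `U` is converted to `T` at
#' read time; the original alphabet is recorded in the `"alphabet"`
#' attribute (`"DNA"` or `"RNA"`).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences with an `"alphabet"`
#'   attribute.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- names(ss)
  nm <- sub("\\s.*$", "", nm)
  if (anyDuplicated(nm)) abort("duplicate sequence names in FASTA")
  seqs <- str_to_upper(as.character(ss))
  alphabet <- ifelse(grepl("U", seqs, fixed = TRUE), "RNA", "DNA")
  out <- setNames(chartr("U", "T", seqs), nm)
  attr(out, "alphabet") <- setNames(alphabet, nm)
  out
}

#' Read MSigDB-style GMT gene-set collections
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set name -> gene names).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read a gene-by-sample raw-count expression matrix
#'
#' @param path TSV whose first column is the gene id and remaining columns
#'   are per-sample non-negative integer counts.
#' @return Integer matrix with genes as rows and samples as columns.
#' @export
read_expression_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- dplyr::pull(x, 1)
  m <- as.matrix(x[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)) || anyDuplicated(genes)) {
    abort("duplicate sample or gene ids in expression matrix")
  }
  if (any(m < 0) || any(m != round(m))) {
    abort("expression counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Read a clinical table
#'
#' @param path TSV with columns `sample_id`, `time` (days), `event` (0/1),
#'   `gender`, `age`, `bmi`, `grade` (G1--G4), `stage` (T1--T4) and
#'   etiology flags (`hbv_hcv`, `alcohol`, `nafld`).
#' @return Tibble of clinical records.
#' @export
read_clinical <- function(path) {
  x <- as_tibble(readr::read_tsv(path, show_col_types = FALSE))
  check_that(all(c("sample_id", "time", "event") %in% names(x)),
             "clinical table must have sample_id, time, event columns")
  check_that(all(x$time > 0), "survival times must be positive")
  check_that(all(x$event %in% c(0, 1)), "event indicator must be 0/1")
  x
}
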