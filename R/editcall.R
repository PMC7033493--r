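#' Editing degree of a site in a sample
#'
#' The fraction of edited (alternate-allele) reads among all mapped reads
#' at a site.
#'
#' @param alt_reads Integer vector of edited-read counts.
#' @param total_reads Integer vector of total read counts (must be > 0).
#' @return Numeric vector of degrees in `[0, 1]`.
#' @export
#' @examples
#' editing_degree(3, 12) # 0.25
editing_degree <- function(alt_reads, total_reads) {
  check_that(all(total_reads > 0), "editing degree undefined at zero coverage")
  check_that(all(alt_reads <= total_reads), "alt_reads exceeds total_reads")
  alt_reads / total_reads
}

#' Filter step (i): remove per-sample DNA mutation positions
#'
#' An observation is dropped iff the *same sample* carries a DNA mutation
#' at that position; other samples' observations at the position survive.
#'
#' @param obs Variant-observation tibble.
#' @param mutations Tibble with `sample_id`, `chrom`, `pos` (0-based).
#' @return Filtered observation tibble.
#' @export
remove_sample_mutations <- function(obs, mutations) {
  dplyr::anti_join(obs, dplyr::select(mutations, "sample_id", "chrom", "pos"),
                   by = c("sample_id", "chrom", "pos"))
}

#' Filter step (ii): remove known SNP positions and indels
#'
#' All observations at a known polymorphic position are removed cohort-wide
#' (position-based, not allele-matched), and every non-SNV (insertion or
#' deletion) observation is removed.
#'
#' @param obs Variant-observation tibble.
#' @param snps Tibble with `chrom`, `pos` (0-based).
#' @return Filtered observation tibble.
#' @export
remove_known_snps_and_indels <- function(obs, snps) {
  obs |>
    dplyr::filter(is_snv(.data$ref, .data$alt)) |>
    dplyr::anti_join(dplyr::distinct(snps, .data$chrom, .data$pos),
                     by = c("chrom", "pos"))
}

#' Filter step (iii), per-observation part: quality and coverage thresholds
#'
#' Removes an observation iff FS > 20, or QD < 2, or fewer than 2 edited
#' reads, or total coverage below 10 reads. All comparisons are strict as
#' printed (FS = 20 survives, coverage = 10 survives). Observations with
#' absent FS or QD pass those two checks; the number of such observations
#' is reported in the `"n_missing_info"` attribute rather than silently
#' deleting data.
#'
#' @param obs Variant-observation tibble.
#' @param max_fs,min_qd,min_alt_reads,min_coverage Thresholds.
#' @return Filtered observation tibble.
#' @export
quality_filter <- function(obs, max_fs = 20, min_qd = 2,
                           min_alt_reads = 2, min_coverage = 10) {
  n_missing <- sum(is.na(obs$fs) | is.na(obs$qd))
  keep <- !(
    (!is.na(obs$fs) & obs$fs > max_fs) |
    (!is.na(obs$qd) & obs$qd < min_qd) |
    obs$alt_reads < min_alt_reads |
    (obs$ref_reads + obs$alt_reads) < min_coverage
  )
  out <- obs[keep, , drop = FALSE]
  attr(out, "n_missing_info") <- n_missing
  out
}

#' Filter step (iv): remove 100%-degree observations
#'
#' A sample's observation with editing degree exactly 1 is dropped as a
#' homozygous-like artifact; the site survives if other samples'
#' observations remain (per-observation mode, the default). In
#' `mode = "site"` the whole site is removed if any sample shows degree 1.
#'
#' @param obs Variant-observation tibble.
#' @param mode `"observation"` (default) or `"site"`.
#' @return Filtered observation tibble.
#' @export
remove_full_degree <- function(obs, mode = c("observation", "site")) {
  mode <- match.arg(mode)
  full <- obs$alt_reads == (obs$ref_reads + obs$alt_reads)
  if (mode == "observation") {
    return(obs[!full, , drop = FALSE])
  }
  bad <- dplyr::distinct(obs[full, c("chrom", "pos", "ref", "alt")])
  dplyr::anti_join(obs, bad, by = c("chrom", "pos", "ref", "alt"))
}

#' Filter step (iii), site-level part: editing-degree spread across samples
#'
#' Keeps a site iff the difference between the 90% and 10% quantiles of
#' its editing degrees across the full cohort is at least `min_spread`.
#' Samples without an observation contribute degree 0; quantiles use
#' linear interpolation on the sorted vector (type 7).
#'
#' @param degrees Numeric vector of degrees for samples with an
#'   observation at the site.
#' @param n_samples Total cohort size (zeros appended for the rest).
#' @param min_spread Minimum Q90 - Q10 (default 0.10).
#' @return Logical: keep the site?
#' @export
quantile_spread_keep <- function(degrees, n_samples, min_spread = 0.10) {
  check_that(n_samples >= length(degrees),
             "n_samples smaller than number of observed degrees")
  v <- c(degrees, rep(0, n_samples - length(degrees)))
  q <- stats::quantile(v, c(0.1, 0.9), names = FALSE, type = 7)
  (q[2] - q[1]) >= min_spread
}

#' Filter step (v): recurrence across the cohort
#'
#' Keeps a site iff it is edited in at least 1% of the samples (ceiling of
#' 1% of the full tumor + normal cohort), so that rare variants are
#' excluded.
#'
#' @param n_edited Number of samples with an observation (degree > 0).
#' @param n_samples Total cohort size.
#' @param min_frac Recurrence fraction (default 0.01).
#' @return Logical: keep the site?
#' @export
recurrence_keep <- function(n_edited, n_samples, min_frac = 0.01) {
  n_edited >= ceiling(min_frac * n_samples)
}

#' Final restriction: canonical chromosomes and single-strand gene context
#'
#' Removes sites outside the canonical chromosome set and sites that map
#' simultaneously to annotated genes on both strands, then groups the
#' surviving observations into an editing-site catalog.
#'
#' @param obs Filtered observation tibble.
#' @param gene_models Gene-model tibble from [read_gene_models()].
#' @param canonical_chroms Character vector of allowed chromosome names.
#' @return Observation tibble restricted to canonical, single-strand sites,
#'   with a `strand` column (the overlapping gene's strand, `NA` for
#'   intergenic).
#' @export
finalize_sites <- function(obs, gene_models, canonical_chroms) {
  obs <- dplyr::filter(obs, .data$chrom %in% canonical_chroms)
  if (nrow(obs) == 0) return(dplyr::mutate(obs, strand = NA_character_))
  spans <- gene_models |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  pos_tbl <- dplyr::distinct(obs, .data$chrom, .data$pos)
  gr_pos <- GenomicRanges::GRanges(pos_tbl$chrom,
                                   IRanges::IRanges(pos_tbl$pos + 1L, width = 1L))
  gr_gene <- GenomicRanges::GRanges(spans$chrom,
                                    IRanges::IRanges(spans$start + 1L, spans$end))
  hits <- GenomicRanges::findOverlaps(gr_pos, gr_gene, ignore.strand = TRUE)
  ov <- tibble(pi = S4Vectors::queryHits(hits),
               strand = spans$strand[S4Vectors::subjectHits(hits)]) |>
    dplyr::group_by(.data$pi) |>
    dplyr::summarise(n_strand = dplyr::n_distinct(.data$strand),
                     strand = dplyr::first(.data$strand), .groups = "drop")
  pos_tbl$strand <- NA_character_
  pos_tbl$dual <- FALSE
  pos_tbl$strand[ov$pi] <- ov$strand
  pos_tbl$dual[ov$pi] <- ov$n_strand > 1
  obs |>
    dplyr::inner_join(dplyr::filter(pos_tbl, !.data$dual),
                      by = c("chrom", "pos")) |>
    dplyr::select(-"dual")
}

#' Apply the full editing-site filter cascade
#'
#' Runs the five-step cascade on raw variant observations: (i) per-sample
#' DNA-mutation removal, (ii) cohort-wide known-SNP and indel removal,
#' (iii) quality/coverage thresholds and the 10% editing-degree spread
#' rule, (iv) 100%-degree removal, (v) 1% recurrence, then restricts to
#' canonical chromosomes and removes dual-strand gene context, returning
#' the editing-site catalog with per-sample editing degrees.
#'
#' @param obs Raw variant-observation tibble (all samples pooled).
#' @param mutations Per-sample somatic mutation tibble.
#' @param snps Known-SNP position tibble.
#' @param gene_models Gene-model tibble.
#' @param samples Sample tibble (`sample_id`, `role`); defines the cohort
#'   size used by the spread and recurrence rules.
#' @param canonical_chroms Allowed chromosome names.
#' @param full_degree_mode Passed to [remove_full_degree()].
#' @return A list of class `"editing_catalog"`: `sites` (one row per site
#'   with edited-sample counts per group), `degrees` (long site x sample
#'   degree/coverage table) and `samples`.
#' @export
call_editing_sites <- function(obs, mutations, snps, gene_models, samples,
                               canonical_chroms,
                               full_degree_mode = "observation") {
  n_samples <- nrow(samples)
  x <- obs |>
    remove_sample_mutations(mutations) |>
    remove_known_snps_and_indels(snps) |>
    quality_filter() |>
    remove_full_degree(mode = full_degree_mode) |>
    finalize_sites(gene_models, canonical_chroms)
  x <- dplyr::mutate(x,
    degree = editing_degree(.data$alt_reads,
                            .data$ref_reads + .data$alt_reads),
    site_id = site_key(.data$chrom, .data$pos, .data$ref, .data$alt))

  site_stats <- x |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(keep = quantile_spread_keep(.data$degree, n_samples) &&
                       recurrence_keep(sum(.data$degree > 0), n_samples),
                     .groups = "drop")
  x <- dplyr::semi_join(x, dplyr::filter(site_stats, .data$keep),
                        by = "site_id")

  roles <- dplyr::select(samples, "sample_id", "role")
  degrees <- x |>
    dplyr::left_join(roles, by = "sample_id") |>
    dplyr::select("site_id", "sample_id", "role", "degree",
                  "ref_reads", "alt_reads")
  sites <- x |>
    dplyr::left_join(roles, by = "sample_id") |>
    dplyr::group_by(.data$site_id, .data$chrom, .data$pos, .data$ref,
                    .data$alt, .data$strand) |>
    dplyr::summarise(
      n_edited = sum(.data$degree > 0),
      n_tumor_edited = sum(.data$degree > 0 & .data$role == "tumor"),
      n_normal_edited = sum(.data$degree > 0 & .data$role == "normal"),
      mean_degree = mean(.data$degree),
      .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  structure(list(sites = sites, degrees = degrees, samples = samples),
            class = "editing_catalog")
}

#' @export
print.editing_catalog <- function(x, ...) {
  cat(sprintf("<editing_catalog> %d sites across %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  print(x$sites, n = 5)
  invisible(x)
}

#' @rdname call_editing_sites
#' @param x An `"editing_catalog"`.
#' @param ... Unused.
#' @export
tidy.editing_catalog <- function(x, ...) x$sites
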