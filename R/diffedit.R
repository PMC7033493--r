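#' Fisher screen for tumor-gain and tumor-loss editing sites
#'
#' For every site, a two-sided Fisher exact test on the 2x2 table of
#' edited / not-edited samples by tumor / normal group, Benjamini-Hochberg
#' corrected across all sites. A site is a *gain* call when the adjusted p
#' is below `alpha` and the edited fraction among normals is at most
#' `max_other_frac`; a *loss* call when the adjusted p is below `alpha`
#' and the edited fraction among tumors is at most `max_other_frac`. The
#' two fraction restrictions make the classes mutually exclusive.
#'
#' @param sites Site tibble with `site_id`, `n_tumor_edited`,
#'   `n_normal_edited`.
#' @param n_tumor,n_normal Group sizes.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param max_other_frac Maximum edited fraction in the complementary
#'   group (default 0.05).
#' @return Tibble with `site_id`, `tumor_frac`, `normal_frac`, `fisher_p`,
#'   `fisher_p_adj`, `class` (`gain` / `loss` / `none`).
#' @export
fisher_gain_loss <- function(sites, n_tumor, n_normal,
                             alpha = 0.05, max_other_frac = 0.05) {
  p <- purrr::map_dbl(seq_len(nrow(sites)), function(i) {
    a <- sites$n_tumor_edited[[i]]
    b <- sites$n_normal_edited[[i]]
    tab <- matrix(c(a, n_tumor - a, b, n_normal - b), nrow = 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) return(1)
    stats::fisher.test(tab)$p.value
  })
  out <- tibble(
    site_id = sites$site_id,
    tumor_frac = sites$n_tumor_edited / n_tumor,
    normal_frac = sites$n_normal_edited / n_normal,
    fisher_p = p,
    fisher_p_adj = p.adjust(p, method = "BH")
  )
  dplyr::mutate(out, class = dplyr::case_when(
    .data$fisher_p_adj < alpha & .data$normal_frac <= max_other_frac &
      .data$tumor_frac > .data$normal_frac ~ "gain",
    .data$fisher_p_adj < alpha & .data$tumor_frac <= max_other_frac &
      .data$normal_frac > .data$tumor_frac ~ "loss",
    TRUE ~ "none"
  ))
}

#' Paired screen for dys-edited sites
#'
#' Paired Student's t-test on the per-pair tumor-minus-normal editing
#' degree differences (absent observations count as degree 0), BH
#' corrected across sites. A site is called dys-edited iff the adjusted p
#' is below `alpha_adj` AND the raw p is below `alpha_raw` AND at least
#' `min_pairs` pairs show an absolute degree change above `min_change`
#' sharing the sign of the mean difference. Direction is `"hyper"` for a
#' positive mean difference, `"hypo"` for negative. Zero-variance
#' difference vectors are degenerate (t undefined): no call, counted in
#' the `"n_degenerate"` attribute.
#'
#' @param degrees Long degree tibble (`site_id`, `sample_id`, `degree`).
#' @param pairs Tibble with `pair_id`, `tumor`, `normal` sample ids.
#' @param alpha_adj,alpha_raw Dual p thresholds (defaults 0.2 / 0.01),
#'   combined with AND when `combine = "and"` (default) or OR.
#' @param min_change,min_pairs The degree-change rule (defaults 0.25 / 2).
#' @param combine `"and"` (default) or `"or"` for the two p thresholds.
#' @return Tibble with `site_id`, `n_pairs`, `t_p`, `t_p_adj`,
#'   `mean_diff`, `n_big_change`, `direction`, `dys` (logical).
#' @export
paired_dys_edit <- function(degrees, pairs, alpha_adj = 0.2,
                            alpha_raw = 0.01, min_change = 0.25,
                            min_pairs = 2L, combine = c("and", "or")) {
  combine <- match.arg(combine)
  check_that(nrow(pairs) >= 2, "need at least 2 tumor/normal pairs")
  deg_of <- degrees |>
    dplyr::select("site_id", "sample_id", "degree")
  grid <- tidyr::expand_grid(site_id = unique(degrees$site_id),
                             pairs[, c("pair_id", "tumor", "normal")])
  d <- grid |>
    dplyr::left_join(deg_of, by = c("site_id", tumor = "sample_id")) |>
    dplyr::rename(deg_tumor = "degree") |>
    dplyr::left_join(deg_of, by = c("site_id", normal = "sample_id")) |>
    dplyr::rename(deg_normal = "degree") |>
    dplyr::mutate(diff = dplyr::coalesce(.data$deg_tumor, 0) -
                    dplyr::coalesce(.data$deg_normal, 0))
  res <- d |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_diff = mean(.data$diff),
      sd_diff = sd(.data$diff),
      n_big_change = sum(abs(.data$diff) > min_change &
                           sign(.data$diff) == sign(mean(.data$diff))),
      .groups = "drop")
  degenerate <- res$sd_diff == 0
  res$t_p <- NA_real_
  ok <- which(!degenerate)
  tp <- purrr::map_dbl(ok, function(i) {
    diffs <- d$diff[d$site_id == res$site_id[[i]]]
    stats::t.test(diffs)$p.value
  })
  res$t_p[ok] <- tp
  res$t_p_adj <- p.adjust(res$t_p, method = "BH")
  pass_p <- if (combine == "and") {
    !is.na(res$t_p) & res$t_p_adj < alpha_adj & res$t_p < alpha_raw
  } else {
    !is.na(res$t_p) & (res$t_p_adj < alpha_adj | res$t_p < alpha_raw)
  }
  out <- res |>
    dplyr::mutate(
      direction = ifelse(.data$mean_diff > 0, "hyper", "hypo"),
      dys = pass_p & .data$n_big_change >= min_pairs) |>
    dplyr::select("site_id", "n_pairs", "t_p", "t_p_adj", "mean_diff",
                  "n_big_change", "direction", "dys")
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Classify every catalog site as gain, loss, dys-edited or none
#'
#' Combines the Fisher screen over the full cohort with the paired screen
#' over the paired subcohort. Dys-edit testing is restricted to sites
#' detected in the paired subcohort. A site already called gain or loss
#' keeps that label; a dys call on an unlabelled site yields `dys_edit`.
#'
#' @param catalog An `"editing_catalog"`.
#' @return Tibble with one row per site: the Fisher columns, the paired
#'   columns (NA when untested) and the final `class`.
#' @export
classify_differential <- function(catalog) {
  samples <- catalog$samples
  n_tumor <- sum(samples$role == "tumor")
  n_normal <- sum(samples$role == "normal")
  fis <- fisher_gain_loss(catalog$sites, n_tumor, n_normal)

  pairs <- samples |>
    dplyr::filter(!is.na(.data$pair_id)) |>
    dplyr::select("sample_id", "role", "pair_id") |>
    tidyr::pivot_wider(names_from = "role", values_from = "sample_id")
  out <- dplyr::left_join(
    dplyr::select(catalog$sites, "site_id", "chrom", "pos", "ref", "alt"),
    fis, by = "site_id")
  if (nrow(pairs) >= 2) {
    paired_ids <- c(pairs$tumor, pairs$normal)
    deg_sub <- dplyr::filter(catalog$degrees,
                             .data$sample_id %in% paired_ids)
    dys <- paired_dys_edit(deg_sub, pairs)
    out <- dplyr::left_join(out, dys, by = "site_id")
    out$class[is.na(out$class)] <- "none"
    out$class[out$class == "none" & !is.na(out$dys) & out$dys] <- "dys_edit"
  }
  out
}

#' Hypergeometric gene-set enrichment of edited genes
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' (genes carrying called sites) and each collection term, against the
#' universe of all genes carrying any surviving editing site; BH across
#' terms.
#'
#' @param query Character vector of gene names of interest.
#' @param collections Named list of gene-name sets (e.g. [read_gmt()]).
#' @param universe Character vector: all genes carrying editing sites.
#' @param alpha BH threshold used for the `significant` flag.
#' @return Tibble with `term`, `n_term`, `n_overlap`, `p`, `p_adj`,
#'   `significant`, sorted by p.
#' @export
enrich_gene_sets <- function(query, collections, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty gene universe")
  query <- intersect(unique(query), universe)
  res <- purrr::map(names(collections), function(nm) {
    term_genes <- intersect(collections[[nm]], universe)
    ov <- length(intersect(term_genes, query))
    p <- phyper(ov - 1, length(term_genes),
                length(universe) - length(term_genes),
                length(query), lower.tail = FALSE)
    tibble(term = nm, n_term = length(term_genes), n_overlap = ov, p = p)
  }) |> dplyr::bind_rows()
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  dplyr::arrange(res, .data$p)
}
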