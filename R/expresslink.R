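#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples, computed over genes with a
#' nonzero count in every sample. Multiplying one sample's counts by a
#' constant multiplies only its factor by that constant.
#'
#' @param counts Gene-by-sample matrix of non-negative raw counts.
#' @param pseudo_reference Fall back to genes with a positive geometric
#'   mean over the samples where they are observed, when no gene is
#'   nonzero everywhere (off by default: the condition is reported as an
#'   error instead of silently changing the estimator).
#' @return Named numeric vector of positive per-sample factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 20, 40), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' size_factors(m) # s2 has twice the library size of s1
size_factors <- function(counts, pseudo_reference = FALSE) {
  check_that(all(counts >= 0), "counts must be non-negative")
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero) && !pseudo_reference) {
    abort(paste("no gene has nonzero counts in every sample;",
                "consider pseudo_reference = TRUE"))
  }
  if (any(all_nonzero)) {
    sub <- counts[all_nonzero, , drop = FALSE]
    log_geo <- rowMeans(log(sub))
    f <- apply(sub, 2, function(col) exp(median(log(col) - log_geo)))
  } else {
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    log_geo <- rowMeans(logc, na.rm = TRUE)
    f <- apply(logc, 2, function(col) {
      exp(median(col - log_geo, na.rm = TRUE))
    })
  }
  check_that(all(f > 0), "size factors must be positive")
  f
}

#' Normalize raw counts by size factors
#'
#' @param counts Gene-by-sample count matrix.
#' @param factors Size factors from [size_factors()] (computed when
#'   omitted).
#' @param log2 Return `log2(x + 1)` of the normalized counts.
#' @return Numeric matrix of normalized expression.
#' @export
normalize_counts <- function(counts, factors = NULL, log2 = FALSE) {
  factors <- factors %||% size_factors(counts)
  out <- sweep(counts, 2, factors, "/")
  if (log2) out <- log2(out + 1)
  out
}

#' Editing-degree vs expression correlation per site
#'
#' For each site located in a gene, the Pearson correlation between the
#' site's editing degree and the normalized expression of that gene,
#' restricted to samples where the editing degree is nonzero and
#' expression is measured; at least `min_n` such samples are required.
#' Two-sided p from the t transform, BH across all tested sites. Sites
#' with constant degree or constant expression are skipped (r undefined)
#' and counted in the `"n_skipped"` attribute.
#'
#' @param degrees Long degree tibble (`site_id`, `sample_id`, `degree`).
#' @param site_genes Tibble mapping `site_id` to `gene_id` (intergenic
#'   sites absent or `NA` are skipped).
#' @param norm_expr Normalized gene-by-sample expression matrix.
#' @param min_n Minimum number of usable samples (default 3).
#' @param alpha BH threshold for the `significant` flag (default 0.05).
#' @return Tibble with `site_id`, `gene_id`, `n`, `r`, `p`, `p_adj`,
#'   `significant`.
#' @export
correlate_editing_expression <- function(degrees, site_genes, norm_expr,
                                         min_n = 3L, alpha = 0.05) {
  d <- degrees |>
    dplyr::filter(.data$degree > 0) |>
    dplyr::inner_join(dplyr::filter(site_genes, !is.na(.data$gene_id)),
                      by = "site_id") |>
    dplyr::filter(.data$gene_id %in% rownames(norm_expr),
                  .data$sample_id %in% colnames(norm_expr))
  n_skipped <- 0L
  res <- d |>
    dplyr::group_by(.data$site_id, .data$gene_id) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < min_n) return(NULL)
      expr <- norm_expr[key$gene_id, g$sample_id]
      if (sd(g$degree) == 0 || sd(expr) == 0) {
        n_skipped <<- n_skipped + 1L
        return(NULL)
      }
      ct <- stats::cor.test(g$degree, expr, method = "pearson")
      tibble(site_id = key$site_id, gene_id = key$gene_id,
             n = nrow(g), r = unname(ct$estimate), p = ct$p.value)
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) {
    res <- tibble(site_id = character(), gene_id = character(),
                  n = integer(), r = double(), p = double())
  }
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  attr(res, "n_skipped") <- n_skipped
  res
}
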