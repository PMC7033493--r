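#' Run the full editing analysis pipeline on a cohort
#'
#' Chains every stage: editing-site calling (five-step filter cascade),
#' annotation (variant type, feature, coding consequence), differential
#' classification (gain / loss / dys-edited), miRNA-target rewiring of
#' 3'UTR sites, expression normalization and editing-expression
#' correlation, and -- when qualifying sites exist -- the editing risk
#' score with median-split survival comparison and multivariate
#' adjustment. Inter-stage invariants (degrees in (0,1), recurrence bound,
#' non-increasing KM curves) are asserted along the way.
#'
#' A site carries a *functional consequence* when its coding consequence
#' is a protein change (non-synonymous, stop gain/loss, splicing, or
#' unknown for incomplete transcripts), when its edit rewires more than
#' the threshold number of miRNA-target regulations, or when its editing
#' degree correlates with its gene's expression (BH-adjusted p < 0.05).
#' The risk model uses sites that are HCC-related AND consequence-bearing
#' AND located in a gene region.
#'
#' @param cohort A `"synthetic_cohort"` (or a list with the same
#'   elements: `observations`, `mutations`, `snps`, `genes`, `samples`,
#'   `canonical_chroms`, `genome`, `mirnas`, `expression`, `clinical`).
#' @param rewire_scope `"hcc"` (default: only differential sites are
#'   scored for miRNA rewiring, the ones the risk model can use) or
#'   `"all"` 3'UTR sites.
#' @param duplex [duplex_params()].
#' @return A list of class `"editscan_analysis"` with elements `catalog`,
#'   `annotated`, `differential`, `rewiring`, `size_factors`,
#'   `expression_cor`, `consequence`, `risk_model`, `scores`,
#'   `grade_stage`, `survival`, `multivariate`.
#' @export
run_pipeline <- function(cohort, rewire_scope = c("hcc", "all"),
                         duplex = duplex_params()) {
  rewire_scope <- match.arg(rewire_scope)

  catalog <- call_editing_sites(cohort$observations, cohort$mutations,
                                cohort$snps, cohort$genes, cohort$samples,
                                cohort$canonical_chroms)
  check_that(all(catalog$degrees$degree > 0 & catalog$degrees$degree < 1),
             "catalog degrees must lie strictly in (0, 1)")
  min_rec <- ceiling(0.01 * nrow(cohort$samples))
  check_that(all(catalog$sites$n_edited >= min_rec),
             "recurrence bound violated in catalog")

  annotated <- annotate_sites(catalog, cohort$genes, cohort$genome)
  differential <- classify_differential(catalog)
  hcc_ids <- differential$site_id[differential$class != "none"]
  check_that(all(hcc_ids %in% catalog$sites$site_id),
             "differential calls must come from the catalog")

  rew_sites <- if (rewire_scope == "hcc") {
    dplyr::filter(annotated, .data$site_id %in% hcc_ids)
  } else {
    annotated
  }
  rewiring <- rewire_sites(rew_sites, cohort$genes, cohort$genome,
                           cohort$mirnas, duplex)

  sf <- size_factors(cohort$expression)
  norm_expr <- normalize_counts(cohort$expression, sf)
  expression_cor <- correlate_editing_expression(
    catalog$degrees,
    dplyr::select(annotated, "site_id", "gene_id"),
    norm_expr)

  coding_flag <- annotated$coding_consequence %in%
    c("non-synonymous", "stop_gain", "stop_loss", "splicing", "unknown") &
    annotated$feature %in% c("cds", "intron")
  mirna_flag <- annotated$site_id %in%
    rewiring$consequence$site_id[rewiring$consequence$mirna_consequence]
  expr_flag <- annotated$site_id %in%
    expression_cor$site_id[expression_cor$significant]
  consequence <- tibble(
    site_id = annotated$site_id,
    coding = coding_flag, mirna = mirna_flag, expression = expr_flag,
    any = coding_flag | mirna_flag | expr_flag
  )

  qualifying <- annotated |>
    dplyr::filter(.data$site_id %in% hcc_ids,
                  !is.na(.data$gene_id),
                  .data$site_id %in% consequence$site_id[consequence$any])

  out <- list(
    catalog = catalog, annotated = annotated, differential = differential,
    rewiring = rewiring, size_factors = sf,
    expression_cor = expression_cor, consequence = consequence,
    risk_model = NULL, scores = NULL, grade_stage = NULL,
    survival = NULL, multivariate = NULL
  )
  clin <- cohort$clinical
  if (nrow(qualifying) >= 2 && !is.null(clin) && nrow(clin) >= 20) {
    tumor_deg <- dplyr::filter(catalog$degrees,
                               .data$sample_id %in% clin$sample_id)
    model <- fit_risk_model(
      dplyr::select(qualifying, "site_id", "gene_id"), tumor_deg, clin)
    if (nrow(model$sites) >= 2) {
      scores <- risk_scores(model, tumor_deg, norm_expr, clin$sample_id)
      surv <- km_logrank(scores, clin)
      check_that(all(diff(surv$km$survival[surv$km$group == "high"]) <= 1e-12) &&
                   all(diff(surv$km$survival[surv$km$group == "low"]) <= 1e-12),
                 "KM curves must be non-increasing")
      out$risk_model <- model
      out$scores <- scores
      out$grade_stage <- grade_stage_association(scores, clin)
      out$survival <- surv
      out$multivariate <- multivariate_adjustment(scores, clin)
    }
  }
  structure(out, class = "editscan_analysis")
}

#' @export
print.editscan_analysis <- function(x, ...) {
  cls <- dplyr::count(x$differential, .data$class)
  cat(sprintf("<editscan_analysis> %d editing sites\n", nrow(x$catalog$sites)))
  print(cls)
  if (!is.null(x$survival)) {
    cat(sprintf("risk model: %d sites; log-rank p = %.3g\n",
                nrow(x$risk_model$sites), x$survival$logrank_p))
  }
  invisible(x)
}
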