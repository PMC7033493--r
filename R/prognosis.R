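#' Sign of the univariate survival association of one editing site
#'
#' Proportional-hazards partial-likelihood fit (Efron ties) of overall
#' survival on the site's editing degree as the single covariate. The
#' returned weight is the sign of the fitted coefficient: +1 for risky
#' editing (higher degree, higher hazard), -1 for protective editing.
#'
#' @param degree Numeric vector of per-patient editing degrees (0 when
#'   unedited).
#' @param time,event Survival time and event indicator, aligned with
#'   `degree`.
#' @return A list with `sign` (+1/-1), `coef`, `p`; `NULL` when the fit
#'   does not converge or separates (the site is excluded upstream).
#' @export
univariate_sign <- function(degree, time, event) {
  check_that(length(unique(event)) > 1 || sum(event) > 0,
             "no event variation in survival data")
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ degree, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  b <- unname(coef(fit))
  if (!is.finite(b) || abs(b) > 20) return(NULL)  # separation-like fit
  p <- summary(fit)$coefficients[1, "Pr(>|z|)"]
  list(sign = if (b >= 0) 1 else -1, coef = b, p = p)
}

#' Fit the editing risk-score model
#'
#' For each candidate site (HCC-related, consequence-bearing, located in
#' a gene region), fits the univariate survival sign and keeps the site
#' with weight beta in {+1, -1}. Sites whose fit fails are excluded and
#' counted in the `"n_excluded"` attribute.
#'
#' @param sites Tibble with `site_id` and `gene_id` of qualifying sites.
#' @param degrees Long degree tibble over patients (`site_id`,
#'   `sample_id`, `degree`).
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`).
#' @return A list of class `"risk_model"`: `sites` tibble with `site_id`,
#'   `gene_id`, `sign`, `coef`, `p`.
#' @export
fit_risk_model <- function(sites, degrees, clinical) {
  check_that(nrow(clinical) >= 10, "need at least 10 patients")
  fits <- purrr::map(seq_len(nrow(sites)), function(i) {
    d <- degrees |>
      dplyr::filter(.data$site_id == sites$site_id[[i]]) |>
      dplyr::select("sample_id", "degree")
    x <- clinical |>
      dplyr::left_join(d, by = "sample_id") |>
      dplyr::mutate(degree = dplyr::coalesce(.data$degree, 0))
    u <- univariate_sign(x$degree, x$time, x$event)
    if (is.null(u)) return(NULL)
    tibble(site_id = sites$site_id[[i]], gene_id = sites$gene_id[[i]],
           sign = u$sign, coef = u$coef, p = u$p)
  })
  kept <- dplyr::bind_rows(purrr::compact(fits))
  out <- structure(list(sites = kept), class = "risk_model")
  attr(out, "n_excluded") <- nrow(sites) - nrow(kept)
  out
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d sites (%d risky, %d protective)\n",
              nrow(x$sites), sum(x$sites$sign > 0), sum(x$sites$sign < 0)))
  invisible(x)
}

#' @rdname fit_risk_model
#' @param x A `"risk_model"`.
#' @param ... Unused.
#' @export
tidy.risk_model <- function(x, ...) x$sites

#' @rdname fit_risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble(n_sites = nrow(x$sites),
         n_risky = sum(x$sites$sign > 0),
         n_protective = sum(x$sites$sign < 0),
         n_excluded = attr(x, "n_excluded") %||% 0L)
}

#' Per-patient editing risk scores
#'
#' The risk score of a patient is the sum over the model's sites that are
#' edited in that patient (degree > 0) of
#' `sign_i x expression(gene_i) x degree_i`, with expression the
#' size-factor-normalized count of the gene carrying the site. Patients
#' with no qualifying site score 0 (counted in `"n_zero"`).
#'
#' @param model A `"risk_model"`.
#' @param degrees Long degree tibble (`site_id`, `sample_id`, `degree`).
#' @param norm_expr Normalized gene-by-sample expression matrix.
#' @param patients Character vector of patient ids to score.
#' @return Tibble with `sample_id`, `risk_score`, `n_sites_used`.
#' @export
risk_scores <- function(model, degrees, norm_expr, patients) {
  d <- degrees |>
    dplyr::filter(.data$degree > 0, .data$sample_id %in% patients) |>
    dplyr::inner_join(model$sites, by = "site_id") |>
    dplyr::filter(.data$gene_id %in% rownames(norm_expr))
  expr <- purrr::map_dbl(seq_len(nrow(d)), function(i) {
    norm_expr[d$gene_id[[i]], d$sample_id[[i]]]
  })
  contrib <- dplyr::mutate(d, term = .data$sign * expr * .data$degree) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(risk_score = sum(.data$term),
                     n_sites_used = dplyr::n(), .groups = "drop")
  out <- tibble(sample_id = patients) |>
    dplyr::left_join(contrib, by = "sample_id") |>
    dplyr::mutate(risk_score = dplyr::coalesce(.data$risk_score, 0),
                  n_sites_used = dplyr::coalesce(.data$n_sites_used, 0L))
  attr(out, "n_zero") <- sum(out$n_sites_used == 0)
  out
}

collapse_grade <- function(x, prefix) {
  y <- as.character(x)
  y[y %in% paste0(prefix, c("3", "4"))] <- paste0(prefix, "3plus")
  y
}

#' Association of risk scores with tumor grade and stage
#'
#' Grades G3/G4 are collapsed to "G3plus" and stages T3/T4 to "T3plus"
#' (the highest categories are too small to test alone); two-sided
#' Wilcoxon rank-sum tests compare adjacent ordinal groups (exact p for
#' small untied groups, normal approximation with tie correction
#' otherwise). Empty groups skip their contrast.
#'
#' @param scores Tibble from [risk_scores()].
#' @param clinical Clinical tibble with `grade` and `stage`.
#' @return Tibble with `variable`, `group1`, `group2`, `n1`, `n2`,
#'   `median1`, `median2`, `p`.
#' @export
grade_stage_association <- function(scores, clinical) {
  x <- dplyr::inner_join(scores, clinical, by = "sample_id")
  one <- function(variable, prefix) {
    g <- collapse_grade(x[[variable]], prefix)
    levels <- paste0(prefix, c("1", "2", "3plus"))
    purrr::map(seq_len(length(levels) - 1), function(i) {
      a <- x$risk_score[g == levels[[i]]]
      b <- x$risk_score[g == levels[[i + 1]]]
      if (length(a) == 0 || length(b) == 0) return(NULL)
      w <- suppressWarnings(stats::wilcox.test(a, b))
      tibble(variable = variable, group1 = levels[[i]],
             group2 = levels[[i + 1]], n1 = length(a), n2 = length(b),
             median1 = median(a), median2 = median(b), p = w$p.value)
    }) |> dplyr::bind_rows()
  }
  dplyr::bind_rows(one("grade", "G"), one("stage", "T"))
}

#' Median-split Kaplan-Meier comparison of risk groups
#'
#' Patients are split at the cohort median risk score (patients exactly
#' at the median go to the low-risk group), Kaplan-Meier product-limit
#' curves are estimated per group, and the two groups are compared by the
#' log-rank test.
#'
#' @param scores Tibble from [risk_scores()].
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`).
#' @return A list of class `"survival_comparison"`: `groups` (per-patient
#'   labels), `km` (tidy product-limit table), `logrank_chisq`,
#'   `logrank_p`, `fit` (the survfit object).
#' @export
km_logrank <- function(scores, clinical) {
  x <- dplyr::inner_join(scores, clinical, by = "sample_id")
  check_that(nrow(x) >= 20, "need at least 20 patients for a median split")
  med <- median(x$risk_score)
  x$group <- ifelse(x$risk_score > med, "high", "low")
  if (length(unique(x$group)) < 2) {
    abort("median split degenerate: all scores on one side")
  }
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group, data = x)
  chisq <- sdf$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  if (any(tapply(x$event, x$group, sum) == 0)) {
    warn("a risk group has zero events")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = x)
  km <- tibble(
    group = rep(sub("group=", "", names(fit$strata)), fit$strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv, lower = fit$lower, upper = fit$upper
  )
  structure(list(
    groups = dplyr::select(x, "sample_id", "risk_score", "group"),
    km = km, logrank_chisq = chisq, logrank_p = p, fit = fit
  ), class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<survival_comparison> high %d / low %d, log-rank chisq = %.2f, p = %.3g\n",
              sum(x$groups$group == "high"), sum(x$groups$group == "low"),
              x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `"survival_comparison"`.
#' @param ... Unused.
#' @export
tidy.survival_comparison <- function(x, ...) x$km

#' @rdname km_logrank
#' @export
glance.survival_comparison <- function(x, ...) {
  tibble(n = nrow(x$groups), logrank_chisq = x$logrank_chisq,
         logrank_p = x$logrank_p)
}

#' Multivariate survival adjustment of the risk score
#'
#' Proportional-hazards fit (Efron ties) of overall survival on the risk
#' score together with gender, age, BMI, grade and stage (grade/stage
#' dummy-coded against the G1/T1 reference), on complete cases.
#' Covariates that are constant (or collinear, reported by the fit as NA
#' coefficients) are dropped with a message.
#'
#' @param scores Tibble from [risk_scores()].
#' @param clinical Clinical tibble with `time`, `event`, `gender`, `age`,
#'   `bmi`, `grade`, `stage`.
#' @return Tibble with `term`, `hr`, `conf_low`, `conf_high`, `p`.
#' @export
multivariate_adjustment <- function(scores, clinical) {
  x <- dplyr::inner_join(scores, clinical, by = "sample_id")
  covars <- c("risk_score", "gender", "age", "bmi", "grade", "stage")
  covars <- covars[covars %in% names(x)]
  x <- x[complete.cases(x[, c("time", "event", covars)]), ]
  keep <- purrr::keep(covars, function(v) length(unique(x[[v]])) > 1)
  dropped <- setdiff(covars, keep)
  if (length(dropped) > 0) {
    inform(paste("dropping constant covariate(s):",
                 paste(dropped, collapse = ", ")))
  }
  for (v in intersect(c("gender", "grade", "stage"), keep)) {
    x[[v]] <- factor(x[[v]])
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(keep, collapse = " + ")))
  fit <- survival::coxph(fml, data = x, ties = "efron")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- tibble(
    term = rownames(co),
    hr = unname(co[, "exp(coef)"]),
    conf_low = unname(ci[, "lower .95"]),
    conf_high = unname(ci[, "upper .95"]),
    p = unname(co[, "Pr(>|z|)"])
  )
  nac <- is.na(coef(fit))
  if (any(nac)) {
    inform(paste("dropping collinear term(s):",
                 paste(names(coef(fit))[nac], collapse = ", ")))
    out <- dplyr::filter(out, !.data$term %in% names(coef(fit))[nac])
  }
  out
}

#' Prognosis on a restricted site list and clinical subset
#'
#' Re-runs the risk-score -> median-split -> log-rank pipeline using only
#' the given sites (e.g. those with univariate Cox p < 0.05) on the
#' patients selected by an etiology filter.
#'
#' @param model A `"risk_model"`.
#' @param site_ids Sites to keep (must leave at least 2).
#' @param degrees,norm_expr As for [risk_scores()].
#' @param clinical Clinical tibble.
#' @param subset_filter Optional predicate taking the clinical tibble and
#'   returning a logical vector (e.g. `~ .x$hbv_hcv == 1`); `NULL` keeps
#'   everyone.
#' @return A `"survival_comparison"`.
#' @export
subset_prognosis <- function(model, site_ids, degrees, norm_expr, clinical,
                             subset_filter = NULL) {
  sub_model <- model
  sub_model$sites <- dplyr::filter(model$sites,
                                   .data$site_id %in% site_ids)
  if (nrow(sub_model$sites) < 2) {
    abort("site subset smaller than 2 sites: refusing to fit a risk score")
  }
  clin <- clinical
  if (!is.null(subset_filter)) {
    keep <- rlang::as_function(subset_filter)(clin)
    clin <- clin[keep, , drop = FALSE]
  }
  if (nrow(clin) < 20) {
    abort(sprintf("clinical subset has %d patients (< 20): refusing",
                  nrow(clin)))
  }
  sc <- risk_scores(sub_model, degrees, norm_expr, clin$sample_id)
  km_logrank(sc, clin)
}
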