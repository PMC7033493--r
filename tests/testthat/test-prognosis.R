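sim_surv <- function(n, beta, degree = NULL, seed = 1) {
  set.seed(seed)
  degree <- degree %||% runif(n, 0, 0.8)
  rate <- 0.001 * exp(beta * degree)
  t_ev <- rexp(n, rate)
  cens <- runif(n, 200, 4000)
  tibble::tibble(
    sample_id = paste0("p", seq_len(n)), degree = degree,
    time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
}

test_that("univariate Cox signs recover planted hazard directions", {
  d <- sim_surv(200, beta = 1.0, seed = 5)
  u <- univariate_sign(d$degree, d$time, d$event)
  expect_equal(u$sign, 1)
  # antisymmetry: negated degrees flip the sign
  u2 <- univariate_sign(-d$degree, d$time, d$event)
  expect_equal(u2$sign, -1)
  expect_equal(u2$coef, -u$coef, tolerance = 1e-6)
})

test_that("risk scores follow the sign x expression x degree formula", {
  model <- structure(list(sites = tibble::tibble(
    site_id = c("s1", "s2"), gene_id = c("g1", "g2"),
    sign = c(1, -1), coef = c(0.5, -0.5), p = c(0.01, 0.02))),
    class = "risk_model")
  degrees <- tibble::tibble(site_id = c("s1", "s2"),
                            sample_id = "p1", degree = c(0.5, 0.2))
  expr <- matrix(c(2, 3), nrow = 2, dimnames = list(c("g1", "g2"), "p1"))
  sc <- risk_scores(model, degrees, expr, "p1")
  expect_equal(sc$risk_score, 1 * 2 * 0.5 + (-1) * 3 * 0.2)  # 0.4
  # all degrees zero: score 0, logged
  sc0 <- risk_scores(model, degrees[0, ], expr, "p1")
  expect_equal(sc0$risk_score, 0)
  expect_equal(attr(sc0, "n_zero"), 1)
  # homogeneity: doubling expression doubles the score
  sc2 <- risk_scores(model, degrees, expr * 2, "p1")
  expect_equal(sc2$risk_score, 2 * sc$risk_score)
  # linearity in degree
  degrees2 <- dplyr::mutate(degrees, degree = degree * 3)
  sc3 <- risk_scores(model, degrees2, expr, "p1")
  expect_equal(sc3$risk_score, 3 * sc$risk_score)
})

test_that("rank-sum association matches full enumeration and collapses G4/T4", {
  clin <- tibble::tibble(
    sample_id = paste0("p", 1:6),
    grade = c("G1", "G1", "G1", "G2", "G2", "G2"),
    stage = c("T1", "T1", "T1", "T3", "T4", "T4"))
  scores <- tibble::tibble(sample_id = paste0("p", 1:6),
                           risk_score = c(1, 2, 3, 4, 5, 6),
                           n_sites_used = 1L)
  out <- grade_stage_association(scores, clin)
  g12 <- out[out$variable == "grade" & out$group1 == "G1", ]
  expect_equal(g12$p, ranksum_enum_oracle(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-9)
  expect_equal(g12$p, 0.1)
  # T3/T4 collapse into one group; the T2 contrast is skipped (empty)
  t_rows <- out[out$variable == "stage", ]
  expect_false(any(t_rows$group1 == "T1" & t_rows$group2 == "T2"))
  # identical distributions: p near 1
  clin2 <- tibble::tibble(sample_id = paste0("p", 1:20),
                          grade = rep(c("G1", "G2"), each = 10),
                          stage = rep(c("T1", "T2"), each = 10))
  scores2 <- tibble::tibble(sample_id = paste0("p", 1:20),
                            risk_score = rep(1:10, 2), n_sites_used = 1L)
  out2 <- grade_stage_association(scores2, clin2)
  expect_gt(min(out2$p), 0.9)
})

test_that("median-split KM collapses to the empirical survival function", {
  n <- 40
  set.seed(6)
  clin <- tibble::tibble(sample_id = paste0("p", 1:n),
                         time = sample(100:2000, n), event = 1L)
  scores <- tibble::tibble(sample_id = clin$sample_id,
                           risk_score = rnorm(n), n_sites_used = 1L)
  cmp <- km_logrank(scores, clin)
  for (g in c("high", "low")) {
    km <- cmp$km[cmp$km$group == g, ]
    ids <- cmp$groups$sample_id[cmp$groups$group == g]
    times <- clin$time[clin$sample_id %in% ids]
    emp <- vapply(km$time, function(t) mean(times > t), numeric(1))
    expect_equal(km$survival, emp, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
  }
  # patients exactly at the median go to the low-risk group
  scores_tied <- scores
  scores_tied$risk_score <- rep(c(1, 2), each = n / 2)
  cmp2 <- km_logrank(scores_tied, clin)
  med <- median(scores_tied$risk_score)
  at_median <- scores_tied$sample_id[scores_tied$risk_score == med]
  expect_true(all(cmp2$groups$group[cmp2$groups$sample_id %in% at_median] ==
                    "low"))
})

test_that("log-rank is invariant under group-label swap and null on identical groups", {
  n <- 30
  clin <- tibble::tibble(
    sample_id = paste0("p", 1:(2 * n)),
    time = rep(seq(100, 2000, length.out = n), 2),
    event = rep(rep(c(1L, 0L), length.out = n), 2))
  scores <- tibble::tibble(sample_id = clin$sample_id,
                           risk_score = rep(c(0, 1), each = n),
                           n_sites_used = 1L)
  cmp <- km_logrank(scores, clin)
  expect_equal(cmp$logrank_p, 1, tolerance = 1e-9)   # identical groups
  flipped <- dplyr::mutate(scores, risk_score = -risk_score)
  cmp2 <- km_logrank(flipped, clin)
  expect_equal(cmp2$logrank_chisq, cmp$logrank_chisq, tolerance = 1e-9)
})

test_that("a planted high-risk group is separated by the log-rank test", {
  set.seed(7)
  n <- 200
  score <- rnorm(n)
  high <- score > median(score)
  rate <- 0.0005 * ifelse(high, 2, 1)       # hazard ratio 2
  t_ev <- rexp(n, rate)
  cens <- runif(n, 500, 6000)
  clin <- tibble::tibble(sample_id = paste0("p", 1:n),
                         time = pmin(t_ev, cens),
                         event = as.integer(t_ev <= cens))
  scores <- tibble::tibble(sample_id = clin$sample_id, risk_score = score,
                           n_sites_used = 1L)
  cmp <- km_logrank(scores, clin)
  expect_lt(cmp$logrank_p, 0.01)
})

test_that("multivariate adjustment recovers coefficients and drops constants", {
  set.seed(8)
  n <- 200
  score <- rnorm(n)
  age <- round(rnorm(n, 60, 10))
  rate <- 0.0008 * exp(0.5 * score)
  t_ev <- rexp(n, rate)
  cens <- runif(n, 500, 6000)
  clin <- tibble::tibble(
    sample_id = paste0("p", 1:n), time = pmin(t_ev, cens),
    event = as.integer(t_ev <= cens),
    gender = sample(c("male", "female"), n, TRUE), age = age,
    bmi = rep(25, n),                                # constant: dropped
    grade = sample(paste0("G", 1:4), n, TRUE),
    stage = sample(paste0("T", 1:4), n, TRUE))
  scores <- tibble::tibble(sample_id = clin$sample_id, risk_score = score,
                           n_sites_used = 1L)
  expect_message(out <- multivariate_adjustment(scores, clin),
                 "constant")
  expect_false(any(out$term == "bmi"))
  row <- out[out$term == "risk_score", ]
  expect_gt(exp(0.5), row$conf_low)
  expect_lt(exp(0.5), row$conf_high)
  # grade/stage reference-coded against G1/T1
  expect_true(all(c("gradeG2", "gradeG3", "gradeG4",
                    "stageT2", "stageT3", "stageT4") %in% out$term))
})

test_that("subset prognosis honours identity filters and refuses tiny inputs", {
  set.seed(9)
  n <- 60
  model <- structure(list(sites = tibble::tibble(
    site_id = c("s1", "s2", "s3"), gene_id = c("g1", "g2", "g3"),
    sign = c(1, 1, -1), coef = c(1, 1, -1), p = c(0.01, 0.02, 0.03))),
    class = "risk_model")
  patients <- paste0("p", 1:n)
  degrees <- tidyr::expand_grid(site_id = model$sites$site_id,
                                sample_id = patients) |>
    dplyr::mutate(degree = runif(dplyr::n(), 0.05, 0.6))
  expr <- matrix(runif(3 * n, 50, 150), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), patients))
  clin <- tibble::tibble(sample_id = patients,
                         time = sample(100:3000, n),
                         event = rbinom(n, 1, 0.6),
                         hbv_hcv = rep(c(1L, 0L), each = n / 2))
  full <- km_logrank(risk_scores(model, degrees, expr, patients), clin)
  ident <- subset_prognosis(model, model$sites$site_id, degrees, expr, clin,
                            subset_filter = function(x) rep(TRUE, nrow(x)))
  expect_equal(ident$logrank_chisq, full$logrank_chisq)
  expect_error(
    subset_prognosis(model, "s1", degrees, expr, clin),
    "smaller than 2")
  expect_error(
    subset_prognosis(model, model$sites$site_id, degrees, expr, clin,
                     subset_filter = function(x) x$hbv_hcv == 2),
    "refusing")
})

test_that("an effect concentrated in one etiology subgroup is found there only", {
  set.seed(10)
  n <- 120
  patients <- paste0("p", 1:n)
  hbv <- rep(c(1L, 0L), each = n / 2)
  score <- rnorm(n)
  # hazard tracks the score only for HBV/HCV patients
  rate <- 0.0006 * exp(ifelse(hbv == 1, 1.2, 0) * score)
  t_ev <- rexp(n, rate)
  cens <- runif(n, 500, 8000)
  clin <- tibble::tibble(sample_id = patients, time = pmin(t_ev, cens),
                         event = as.integer(t_ev <= cens), hbv_hcv = hbv)
  model <- structure(list(sites = tibble::tibble(
    site_id = c("s1", "s2"), gene_id = c("g1", "g2"),
    sign = c(1, 1), coef = c(1, 1), p = c(0.01, 0.01))),
    class = "risk_model")
  degrees <- tibble::tibble(site_id = "s1", sample_id = patients,
                            degree = plogis(score))   # monotone in score
  expr <- matrix(100, nrow = 2, ncol = n,
                 dimnames = list(c("g1", "g2"), patients))
  in_group <- subset_prognosis(model, c("s1", "s2"), degrees, expr, clin,
                               subset_filter = function(x) x$hbv_hcv == 1)
  out_group <- subset_prognosis(model, c("s1", "s2"), degrees, expr, clin,
                                subset_filter = function(x) x$hbv_hcv == 0)
  expect_lt(in_group$logrank_p, 0.05)
  expect_gt(out_group$logrank_p, in_group$logrank_p)
})
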