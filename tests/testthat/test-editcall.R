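obs_row <- function(sample_id = "S1", chrom = "chr1", pos = 100L,
                    ref = "A", alt = "G", ref_reads = 20L, alt_reads = 8L,
                    fs = 1, qd = 10) {
  tibble::tibble(sample_id, chrom, pos, ref, alt, ref_reads, alt_reads,
                 fs, qd)
}

test_that("editing degree is edited reads over total reads", {
  expect_equal(editing_degree(3, 12), 0.25)
  expect_equal(editing_degree(0, 10), 0)
  expect_equal(editing_degree(10, 10), 1)
  expect_error(editing_degree(1, 0), "zero coverage")
  expect_error(editing_degree(5, 3), "exceeds")
})

test_that("mutation removal is per sample, not per site", {
  obs <- dplyr::bind_rows(obs_row("S1", pos = 500L), obs_row("S2", pos = 500L),
                          obs_row("S1", pos = 900L))
  muts <- tibble::tibble(sample_id = "S1", chrom = "chr1", pos = 500L)
  out <- remove_sample_mutations(obs, muts)
  expect_equal(nrow(out), 2)
  expect_true(any(out$sample_id == "S2" & out$pos == 500))   # S2 survives
  expect_false(any(out$sample_id == "S1" & out$pos == 500))
  expect_true(any(out$pos == 900))                            # untouched site
})

test_that("SNP positions are removed cohort-wide and indels always", {
  obs <- dplyr::bind_rows(
    obs_row("S1", pos = 10L), obs_row("S2", pos = 10L),
    obs_row("S1", pos = 20L),
    obs_row("S1", pos = 30L, alt = "GT"))    # insertion
  snps <- tibble::tibble(chrom = "chr1", pos = 10L)
  out <- remove_known_snps_and_indels(obs, snps)
  expect_equal(out$pos, 20L)
})

test_that("quality thresholds are strict as printed and absent metadata passes", {
  cases <- dplyr::bind_rows(
    obs_row(fs = 25, qd = 5, alt_reads = 3L, ref_reads = 27L),   # FS > 20
    obs_row(fs = 0, qd = 5, alt_reads = 2L, ref_reads = 8L),     # boundary
    obs_row(fs = 1, qd = 1.9, alt_reads = 5L, ref_reads = 20L),  # QD < 2
    obs_row(fs = 20, qd = 2, alt_reads = 2L, ref_reads = 8L),    # boundaries
    obs_row(fs = NA, qd = NA, alt_reads = 5L, ref_reads = 20L),  # absent
    obs_row(fs = 1, qd = 10, alt_reads = 1L, ref_reads = 30L),   # < 2 alt
    obs_row(fs = 1, qd = 10, alt_reads = 4L, ref_reads = 5L))    # cov < 10
  out <- quality_filter(cases)
  expect_equal(out$fs, c(0, 20, NA))
  expect_equal(attr(out, "n_missing_info"), 1)
})

test_that("100%-degree removal is per observation by default, per site on request", {
  obs <- dplyr::bind_rows(
    obs_row("S1", pos = 5L, ref_reads = 0L, alt_reads = 12L),
    obs_row("S2", pos = 5L, ref_reads = 6L, alt_reads = 6L))
  per_obs <- remove_full_degree(obs)
  expect_equal(per_obs$sample_id, "S2")     # site survives via S2
  per_site <- remove_full_degree(obs, mode = "site")
  expect_equal(nrow(per_site), 0)
})

test_that("the quantile-spread rule matches an independent interpolation oracle", {
  expect_false(quantile_spread_keep(rep(0.30, 50), 50))   # constant vector
  deg <- rep(0.5, 10)
  v <- c(deg, rep(0, 90))
  oracle <- (quantile_oracle(v, 0.9) - quantile_oracle(v, 0.1)) >= 0.10
  expect_equal(quantile_spread_keep(deg, 100), oracle)
  expect_true(quantile_spread_keep(seq(0, 0.9, by = 0.1), 10))
  # randomized agreement with the oracle
  set.seed(42)
  for (i in 1:50) {
    k <- sample(0:30, 1)
    deg <- runif(k, 0, 0.6)
    n <- k + sample(0:100, 1)
    v <- c(deg, rep(0, n - k))
    expect_equal(quantile_spread_keep(deg, n),
                 (quantile_oracle(v, 0.9) - quantile_oracle(v, 0.1)) >= 0.10)
  }
})

test_that("recurrence uses the ceiling of 1% of the cohort", {
  expect_false(recurrence_keep(4, 423))   # 4 < ceil(4.23) = 5
  expect_true(recurrence_keep(5, 423))
  expect_true(recurrence_keep(1, 100))    # ceil(1.0) = 1
})

test_that("finalize removes non-canonical chromosomes and dual-strand context", {
  gm <- toy_gene_models()
  overlap_gene <- tibble::tibble(
    gene_id = "GA", gene_name = "GA", gene_type = "lncRNA", chrom = "chr1",
    strand = "-", transcript_id = "TA", feature = "exon",
    start = 10L, end = 100L, frame = NA_integer_, complete = TRUE)
  gm2 <- dplyr::bind_rows(gm, overlap_gene)
  obs <- dplyr::bind_rows(
    obs_row(pos = 50L),                      # inside GP(+) and GA(-): dual
    obs_row(pos = 250L),                     # single + strand gene
    obs_row(pos = 450L),                     # single - strand gene
    obs_row(chrom = "chrUn_x", pos = 50L))   # unplaced contig
  out <- finalize_sites(obs, gm2, canonical_chroms = "chr1")
  expect_equal(sort(out$pos), c(250L, 450L))
  expect_equal(out$strand[out$pos == 450], "-")
})

test_that("the cascade equals a single-pass brute-force filter on a mixed batch", {
  set.seed(7)
  n <- 2000
  samples <- tibble::tibble(sample_id = sprintf("S%02d", 1:40),
                            role = rep(c("tumor", "normal"), c(30, 10)))
  obs <- tibble::tibble(
    sample_id = sample(samples$sample_id, n, TRUE),
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    pos = sample(1:300, n, TRUE),
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T", "AT"), n, TRUE,
                 prob = c(rep(0.23, 4), 0.08)),
    ref_reads = rpois(n, 20),
    alt_reads = rpois(n, 6),
    fs = ifelse(runif(n) < 0.1, runif(n, 20, 40), runif(n, 0, 19)),
    qd = ifelse(runif(n) < 0.1, runif(n, 0, 2), runif(n, 2, 30)))
  obs$fs[runif(n) < 0.05] <- NA
  obs$qd[runif(n) < 0.05] <- NA
  obs <- dplyr::distinct(obs, sample_id, chrom, pos, .keep_all = TRUE)
  muts <- dplyr::slice_sample(obs, n = 60)[, c("sample_id", "chrom", "pos")]
  snps <- dplyr::distinct(dplyr::slice_sample(obs, n = 50), chrom, pos)

  pipeline <- obs |>
    remove_sample_mutations(muts) |>
    remove_known_snps_and_indels(snps) |>
    quality_filter() |>
    remove_full_degree()
  keep_site <- pipeline |>
    dplyr::mutate(degree = alt_reads / (ref_reads + alt_reads),
                  key = paste(chrom, pos, ref, alt)) |>
    dplyr::group_by(key) |>
    dplyr::summarise(keep = quantile_spread_keep(degree, nrow(samples)) &&
                       recurrence_keep(sum(degree > 0), nrow(samples)))
  survivors <- pipeline |>
    dplyr::mutate(key = paste(chrom, pos, ref, alt)) |>
    dplyr::semi_join(dplyr::filter(keep_site, keep), by = "key")

  oracle <- brute_force_filter(obs, muts, snps, nrow(samples))
  key_of <- function(d) sort(paste(d$sample_id, d$chrom, d$pos, d$alt))
  expect_identical(key_of(survivors), key_of(oracle))
})

test_that("per-observation filter steps commute", {
  co <- simulate_cohort(small_config(seed = 13))
  a <- co$observations |>
    remove_sample_mutations(co$mutations) |>
    remove_known_snps_and_indels(co$snps) |>
    quality_filter() |> remove_full_degree()
  b <- co$observations |>
    quality_filter() |> remove_full_degree() |>
    remove_known_snps_and_indels(co$snps) |>
    remove_sample_mutations(co$mutations)
  key_of <- function(d) sort(paste(d$sample_id, d$chrom, d$pos, d$alt))
  expect_identical(key_of(a), key_of(b))
})

test_that("tightening a threshold never enlarges the surviving set", {
  co <- simulate_cohort(small_config(seed = 13))
  loose <- quality_filter(co$observations)
  tight <- quality_filter(co$observations, min_coverage = 15)
  key_of <- function(d) paste(d$sample_id, d$chrom, d$pos, d$alt)
  expect_true(all(key_of(tight) %in% key_of(loose)))
  tight_fs <- quality_filter(co$observations, max_fs = 10)
  expect_true(all(key_of(tight_fs) %in% key_of(loose)))
})

test_that("injected mutation overlaps are removed exactly per ground truth", {
  co <- simulate_cohort(small_config(seed = 9))
  out <- remove_sample_mutations(co$observations, co$mutations)
  mut_keys <- paste(co$mutations$sample_id, co$mutations$chrom,
                    co$mutations$pos)
  obs_keys <- paste(co$observations$sample_id, co$observations$chrom,
                    co$observations$pos)
  removed <- setdiff(obs_keys, paste(out$sample_id, out$chrom, out$pos))
  expect_setequal(removed, intersect(obs_keys, mut_keys))
  # non-carrier edited samples at overlapped sites survive
  mut_sites <- co$truth$sites[co$truth$sites$is_mut_overlap, ]
  deg <- dplyr::inner_join(co$truth$degrees, mut_sites[, c("site_id", "chrom", "pos")],
                           by = "site_id")
  non_carrier <- setdiff(paste(deg$sample_id, deg$chrom, deg$pos), mut_keys)
  expect_true(all(non_carrier %in% paste(out$sample_id, out$chrom, out$pos)))
})

test_that("catalog invariants hold on a simulated cohort", {
  co <- simulate_cohort(small_config(seed = 9))
  catalog <- call_editing_sites(co$observations, co$mutations, co$snps,
                                co$genes, co$samples, co$canonical_chroms)
  expect_true(all(catalog$degrees$degree > 0 & catalog$degrees$degree < 1))
  min_rec <- ceiling(0.01 * nrow(co$samples))
  expect_true(all(catalog$sites$n_edited >= min_rec))
  expect_equal(catalog$sites$n_edited,
               catalog$sites$n_tumor_edited + catalog$sites$n_normal_edited)
  # artifacts and confounders never reach the catalog
  bad <- co$truth$sites[co$truth$sites$is_snp_overlap |
                          co$truth$sites$is_dual_strand |
                          co$truth$sites$is_nonstandard, ]
  expect_false(any(bad$site_id %in% catalog$sites$site_id))
})
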