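test_that("a perfect 22-nt duplex scores above threshold with low free energy", {
  set.seed(4)
  core <- paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = "")
  window <- paste0("AAAAAA", core, "AAAAAA")
  mirna <- revcomp(core)
  h <- score_duplex(mirna, window)
  # 7 seed positions at 10 + 15 at 5, scaled by 1.25
  expect_gte(h$score, (7 * 10 + 15 * 5) * 1.25 - 1e-9)
  expect_lt(h$dg, -14)
  expect_true(h$hit)
  # poly-A window offers nothing to a natural miRNA
  h2 <- score_duplex(mirna, strrep("A", 60))
  expect_false(h2$hit)
  expect_error(score_duplex("ACGTACGTACGT", window), "shorter than 15")
})

test_that("a seed mismatch costs more than a 3' mismatch", {
  core <- "GCTGCAGTCGCAGTCGGCATCA"
  window <- paste0("CCCCCC", core, "CCCCCC")
  mirna <- revcomp(core)
  perfect <- score_duplex(mirna, window)$score
  # miRNA position 5 (seed): pairs core base 18; position 15: core base 8
  seed_mm <- mirna
  substr(seed_mm, 5, 5) <- "A"   # was complementary, now mismatched
  m1 <- score_duplex(seed_mm, window)$score
  tail_mm <- mirna
  substr(tail_mm, 15, 15) <- "C"   # C vs T: mismatch, not wobble
  m2 <- score_duplex(tail_mm, window)$score
  expect_lt(m1, perfect)
  expect_lt(m2, perfect)
  expect_lt(m1, m2)              # seed weighting doubles the cost
})

test_that("the DP scorer agrees with alignment oracles on short pairs", {
  # (a) with uniform position weights the scorer must reproduce a
  # reference affine local alignment (independent implementation)
  uni <- duplex_params(seed_mult = 1, scale = 1)
  mat <- matrix(uni$mismatch, 4, 4,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  mat["A", "T"] <- mat["T", "A"] <- mat["C", "G"] <- mat["G", "C"] <- uni$wc
  mat["G", "T"] <- mat["T", "G"] <- uni$wobble
  set.seed(8)
  for (i in 1:30) {
    nm <- sample(15:22, 1)
    nw <- sample(18:30, 1)
    mirna <- paste(sample(c("A", "C", "G", "T"), nm, TRUE), collapse = "")
    window <- paste(sample(c("A", "C", "G", "T"), nw, TRUE), collapse = "")
    got <- score_duplex(mirna, window, uni)$score
    rev_m <- paste(rev(strsplit(mirna, "")[[1]]), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      rev_m, window, type = "local", substitutionMatrix = mat,
      gapOpening = 4, gapExtension = 9, scoreOnly = TRUE)
    expect_equal(got, max(0, ref), tolerance = 1e-9,
                 label = paste("uniform case", i))
  }
  # (b) with seed weighting, the ungapped-offset + single-gap oracle is a
  # lower bound, and exact on constructed complementary cases
  set.seed(9)
  for (i in 1:15) {
    nm <- sample(15:22, 1)
    nw <- sample(18:30, 1)
    mirna <- paste(sample(c("A", "C", "G", "T"), nm, TRUE), collapse = "")
    window <- paste(sample(c("A", "C", "G", "T"), nw, TRUE), collapse = "")
    expect_gte(score_duplex(mirna, window)$score,
               duplex_oracle_score(mirna, window) - 1e-9)
  }
  for (i in 1:10) {
    nm <- sample(16:22, 1)
    mirna <- paste(sample(c("A", "C", "G", "T"), nm, TRUE), collapse = "")
    window <- paste0("AAAA", revcomp(substr(mirna, 3, nm - 2)), "AAAA")
    window <- gsub("AAAAA", "AACAA", window)  # avoid accidental A-runs pairing
    got <- score_duplex(mirna, window)$score
    expect_equal(got, duplex_oracle_score(mirna, window),
                 tolerance = 1e-9, label = paste("comp case", i))
  }
})

test_that("free energy of a perfect duplex matches the independent stack sum", {
  core <- "GCTGCAGTCGCAGTCG"
  window <- paste0("AAAAAA", core, "AAAAAA")
  mirna <- paste0(revcomp(core), "CCCCCC")
  h <- score_duplex(mirna, window)
  expect_equal(h$dg, perfect_duplex_dg_oracle(core), tolerance = 1e-9)
})

test_that("window construction truncates at transcript ends and maps strand", {
  gm <- toy_gene_models()
  genome <- toy_genome()
  # + strand: GP utr3 is [281, 350); transcript end at 350
  site <- tibble::tibble(chrom = "chr1", pos = 319L,
                         ref = substr(genome[["chr1"]], 320, 320), alt = "G")
  if (site$ref == "G") site$alt <- "C"
  w <- build_windows(site, gm, genome)
  expect_equal(nrow(w), 1)
  # 30 bp to the transcript 3' end: window is 50 + 1 + 30 long
  expect_equal(nchar(w$ref_window), 81)
  expect_equal(substr(w$ref_window, w$center + 1, w$center + 1), site$ref)
  expect_equal(substr(w$edited_window, w$center + 1, w$center + 1), site$alt)
  # windows differ at exactly the center position
  diffs <- which(strsplit(w$ref_window, "")[[1]] !=
                   strsplit(w$edited_window, "")[[1]])
  expect_equal(diffs, w$center + 1)
})

test_that("minus-strand windows are the reverse complement construction", {
  gm <- toy_gene_models()
  genome <- toy_genome()
  # GM utr3 [400, 430), - strand; genomic T>C must appear as A>G in window
  pos <- 414L
  g <- genome
  s <- g[["chr1"]]
  substr(s, pos + 1, pos + 1) <- "T"
  g[["chr1"]] <- s
  site <- tibble::tibble(chrom = "chr1", pos = pos, ref = "T", alt = "C")
  w <- build_windows(site, gm, g)
  expect_equal(substr(w$ref_window, w$center + 1, w$center + 1), "A")
  expect_equal(substr(w$edited_window, w$center + 1, w$center + 1), "G")
  # the window equals the revcomp of the genomic region around the site
  utr_len <- 430 - 400
  tx <- revcomp(substr(g[["chr1"]], 401, 580))  # spliced = single exon here
  expect_true(grepl(w$ref_window, tx, fixed = TRUE))
})

test_that("regulation changes classify gains, losses and energy shifts", {
  hits <- function(ids, dgs) tibble::tibble(mirna_id = ids, score = 150,
                                            dg = dgs)
  # identical windows: no changes
  expect_equal(nrow(classify_regulation_change(hits("m1", -20), hits("m1", -20))), 0)
  ch <- classify_regulation_change(
    ref_hits = hits(c("lost", "both", "shift"), c(-20, -16, -16)),
    edited_hits = hits(c("gained", "both", "shift"), c(-18, -17, -31)))
  expect_equal(ch$kind[ch$mirna_id == "lost"], "edited_loss")
  expect_equal(ch$kind[ch$mirna_id == "gained"], "edited_gain")
  expect_equal(ch$kind[ch$mirna_id == "shift"], "edited_change")
  expect_equal(ch$ddg[ch$mirna_id == "shift"], 15)
  expect_false("both" %in% ch$mirna_id)          # |ddG| = 1 <= 14
  # ddG = 13 stays below the strict threshold
  ch13 <- classify_regulation_change(hits("m", -16), hits("m", -29))
  expect_equal(nrow(ch13), 0)
  # swapping windows maps gains to losses and keeps changes
  sw <- classify_regulation_change(
    ref_hits = hits(c("gained", "shift"), c(-18, -31)),
    edited_hits = hits(c("lost", "shift"), c(-20, -16)))
  expect_equal(sw$kind[sw$mirna_id == "gained"], "edited_loss")
  expect_equal(sw$kind[sw$mirna_id == "lost"], "edited_gain")
  expect_equal(sw$kind[sw$mirna_id == "shift"], "edited_change")
})

test_that("the consequence flag requires strictly more than 10 changes", {
  ch <- function(n) tibble::tibble(mirna_id = sprintf("m%02d", seq_len(n)),
                                   kind = "edited_gain", ddg = NA_real_)
  expect_true(call_mirna_consequence(ch(11)))
  expect_false(call_mirna_consequence(ch(10)))
  expect_false(call_mirna_consequence(ch(0)))
  # duplicated miRNA-kind records do not inflate the count
  dup <- dplyr::bind_rows(ch(10), ch(1))
  expect_false(call_mirna_consequence(dup))
})

test_that("designed edits in the simulated cohort rewire as recorded", {
  co <- simulate_cohort(small_config(seed = 9))
  truth <- co$truth$rewire
  sites <- dplyr::inner_join(co$truth$sites,
                             dplyr::distinct(truth, site_id), by = "site_id")
  sites$feature <- "utr3"
  rew <- rewire_sites(sites, co$genes, co$genome, co$mirnas)
  got <- dplyr::inner_join(rew$changes, truth,
                           by = c("site_id", "mirna_id"))
  expect_equal(nrow(got), nrow(truth))
  expect_equal(got$kind, got$expected_kind)
})
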