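# Independent oracle implementations used to pin the pipeline's behaviour.
# These deliberately avoid the package's own code paths: plain base-R
# loops, closed forms and exhaustive enumeration.

# type-7 quantile by hand: sorted-vector linear interpolation
quantile_oracle <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of all table probabilities not exceeding the observed one
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# one-sample t-test p by the textbook formula
ttest_oracle <- function(x) {
  n <- length(x)
  t <- mean(x) / (sd(x) / sqrt(n))
  2 * pt(-abs(t), df = n - 1)
}

# hypergeometric upper-tail p by direct enumeration
hyper_tail_oracle <- function(overlap, n_term, n_universe, n_query) {
  xs <- overlap:min(n_term, n_query)
  sum(dhyper(xs, n_term, n_universe - n_term, n_query))
}

# exact two-sided rank-sum p by enumerating all group labelings
ranksum_enum_oracle <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  idx <- utils::combn(n, length(x))
  w_obs <- sum(rank(all_v)[seq_along(x)])
  ws <- apply(idx, 2, function(ii) sum(rank(all_v)[ii]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# single-pass brute-force filter cascade: per-observation predicates as one
# boolean, then the site-level spread/recurrence rules computed naively
brute_force_filter <- function(obs, mutations, snps, n_samples) {
  mut_keys <- paste(mutations$sample_id, mutations$chrom, mutations$pos)
  snp_keys <- paste(snps$chrom, snps$pos)
  keep <- logical(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    o <- obs[i, ]
    cov <- o$ref_reads + o$alt_reads
    keep[i] <-
      !(paste(o$sample_id, o$chrom, o$pos) %in% mut_keys) &&
      (nchar(o$ref) == 1 && nchar(o$alt) == 1 &&
         o$ref %in% c("A", "C", "G", "T") && o$alt %in% c("A", "C", "G", "T")) &&
      !(paste(o$chrom, o$pos) %in% snp_keys) &&
      !(!is.na(o$fs) && o$fs > 20) &&
      !(!is.na(o$qd) && o$qd < 2) &&
      o$alt_reads >= 2 &&
      cov >= 10 &&
      o$alt_reads < cov        # 100%-degree observations removed
  }
  surv <- obs[keep, , drop = FALSE]
  if (nrow(surv) == 0) return(surv)
  surv$key <- paste(surv$chrom, surv$pos, surv$ref, surv$alt)
  keys <- unique(surv$key)
  site_keep <- logical(length(keys))
  for (k in seq_along(keys)) {
    rows <- surv[surv$key == keys[[k]], ]
    deg <- rows$alt_reads / (rows$ref_reads + rows$alt_reads)
    v <- c(deg, rep(0, n_samples - length(deg)))
    spread <- quantile_oracle(v, 0.9) - quantile_oracle(v, 0.1)
    site_keep[k] <- spread >= 0.10 && sum(deg > 0) >= ceiling(0.01 * n_samples)
  }
  out <- surv[surv$key %in% keys[site_keep], , drop = FALSE]
  out$key <- NULL
  out
}

# classify a coding consequence by translating the WHOLE edited CDS and
# diffing the protein against the reference protein
translate_consequence_oracle <- function(cds_seq, off, alt_base) {
  edited <- cds_seq
  substr(edited, off + 1, off + 1) <- alt_base
  p_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq), no.init.codon = TRUE))
  p_alt <- as.character(Biostrings::translate(
    Biostrings::DNAString(edited), no.init.codon = TRUE))
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(i) == 0) return(list(consequence = "synonymous", aa = NA))
  a <- substr(p_ref, i, i)
  b <- substr(p_alt, i, i)
  cons <- if (b == "*") "stop_gain" else if (a == "*") "stop_loss" else
    "non-synonymous"
  list(consequence = cons, aa = paste0(a, i, b))
}

# exhaustive duplex-alignment oracle: all ungapped offsets of the reversed
# miRNA against the window, plus all placements of one gap (length 1-3) in
# either sequence; every contiguous sub-alignment of each arrangement is
# considered via max-subarray over per-position scores
duplex_oracle_score <- function(mirna, window, params = duplex_params()) {
  m <- rev(strsplit(mirna, "")[[1]])
  w <- strsplit(window, "")[[1]]
  nm <- length(m); nw <- length(w)
  orig_pos <- nm:1
  pair_score <- function(a, b, pos) {
    wc <- (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "C" && b == "G") || (a == "G" && b == "C")
    wob <- (a == "G" && b == "T") || (a == "T" && b == "G")
    s <- if (wc) params$wc else if (wob) params$wobble else params$mismatch
    if (pos >= params$seed_from && pos <= params$seed_to) s <- s * params$seed_mult
    s
  }
  best_sub <- function(scores) {
    best <- 0; cur <- 0
    for (s in scores) {
      cur <- max(0, cur + s)
      best <- max(best, cur)
    }
    best
  }
  best <- 0
  # ungapped offsets
  for (off in (-nm + 1):(nw - 1)) {
    idx_m <- which(seq_len(nm) + off >= 1 & seq_len(nm) + off <= nw)
    if (length(idx_m) == 0) next
    scores <- vapply(idx_m, function(i) {
      pair_score(m[[i]], w[[i + off]], orig_pos[[i]])
    }, numeric(1))
    best <- max(best, best_sub(scores))
  }
  gap_cost <- function(L) params$gap_open + L * params$gap_extend
  # one gap of length L in the window (miRNA bases skip L window bases)
  for (L in 1:3) {
    for (off in (-nm + 1):(nw - 1)) {
      for (g in 2:nm) {  # gap between miRNA positions g-1 and g
        scores <- numeric(0)
        ok <- TRUE
        for (i in seq_len(nm)) {
          j <- i + off + if (i >= g) L else 0
          if (j < 1 || j > nw) { scores <- c(scores, NA); next }
          scores <- c(scores, pair_score(m[[i]], w[[j]], orig_pos[[i]]))
        }
        # contiguous runs must bridge the gap to pay its cost; enumerate
        # sub-alignments that either stay on one side or cross it
        left <- scores[seq_len(g - 1)]
        right <- scores[g:nm]
        left <- left[!is.na(left)]
        right <- right[!is.na(right)]
        if (length(left) && length(right)) {
          # best suffix of left + gap + best prefix of right
          suf <- max(0, max(cumsum(rev(left))))
          pre <- max(0, max(cumsum(right)))
          if (suf > 0 && pre > 0) {
            best <- max(best, suf + gap_cost(L) + pre)
          }
        }
      }
    }
    # one gap of length L in the miRNA (window bases skip L miRNA bases)
    for (off in (-nm + 1 - L):(nw - 1)) {
      for (g in 2:nm) {
        left_idx <- seq_len(g - 1)
        right_idx <- g:nm
        lscore <- numeric(0); rscore <- numeric(0)
        for (i in left_idx) {
          j <- i + off
          lscore <- c(lscore, if (j >= 1 && j <= nw)
            pair_score(m[[i]], w[[j]], orig_pos[[i]]) else NA)
        }
        for (i in right_idx) {
          j <- i + off + L
          rscore <- c(rscore, if (j >= 1 && j <= nw)
            pair_score(m[[i]], w[[j]], orig_pos[[i]]) else NA)
        }
        lscore <- lscore[!is.na(lscore)]
        rscore <- rscore[!is.na(rscore)]
        if (length(lscore) && length(rscore)) {
          suf <- max(0, max(cumsum(rev(lscore))))
          pre <- max(0, max(cumsum(rscore)))
          if (suf > 0 && pre > 0) {
            best <- max(best, suf + gap_cost(L) + pre)
          }
        }
      }
    }
  }
  best * params$scale
}

# nearest-neighbor stack sum for a perfectly complementary contiguous
# duplex, recomputed independently from the exported table logic
perfect_duplex_dg_oracle <- function(target_seq, initiation = 4.1) {
  stacks <- c(
    AA = -0.93, AT = -1.10, AC = -2.24, AG = -2.08,
    TA = -1.33, TT = -0.93, TG = -2.11, TC = -2.35,
    CA = -2.11, CT = -2.08, CG = -2.36, CC = -3.26,
    GA = -2.35, GT = -2.24, GG = -3.26, GC = -3.42
  )
  b <- strsplit(target_seq, "")[[1]]
  dg <- initiation
  for (i in seq_len(length(b) - 1)) {
    dg <- dg + stacks[[paste0(b[[i]], b[[i + 1]])]]
  }
  dg
}

# small, fast cohort configuration for module tests
small_config <- function(...) {
  simulation_config(
    n_tumor = 30L, n_normal = 16L, n_paired = 10L,
    n_genes = 30L, n_sites = 400L,
    n_gain = 12L, n_loss = 12L, n_dys = 8L,
    n_expression = 8L, n_survival = 4L,
    n_snp_overlap = 20L, n_snp_extra = 20L,
    n_mut_overlap = 10L, n_full_degree_artifact = 8L,
    n_lowcov_artifact = 8L, n_dual_strand = 4L, n_nonstandard = 4L,
    n_indel = 6L, n_mirna = 12L, n_rewire_gain = 2L, n_rewire_loss = 2L,
    ...
  )
}

# hand-built two-gene toy annotation on a 600-bp chromosome
toy_gene_models <- function() {
  plus <- tibble::tibble(
    gene_id = "GP", gene_name = "GP", gene_type = "protein_coding",
    chrom = "chr1", strand = "+", transcript_id = "TP",
    feature = c("exon", "exon", "utr5", "cds", "cds", "utr3"),
    start = c(10L, 200L, 10L, 40L, 200L, 281L),
    end = c(100L, 350L, 40L, 100L, 281L, 350L),
    frame = c(NA, NA, NA, 0L, 0L, NA),
    complete = TRUE
  )
  minus <- tibble::tibble(
    gene_id = "GM", gene_name = "GM", gene_type = "protein_coding",
    chrom = "chr1", strand = "-", transcript_id = "TM",
    feature = c("exon", "utr3", "cds", "utr5"),
    start = c(400L, 400L, 430L, 550L),
    end = c(580L, 430L, 550L, 580L),
    frame = c(NA, NA, 0L, NA),
    complete = TRUE
  )
  m <- dplyr::bind_rows(plus, minus)
  dplyr::bind_rows(m, editscan:::derive_introns(m))
}

toy_genome <- function(seed = 42) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
             collapse = "")
  c(chr1 = s)
}

# shared default-scale analysis for acceptance tests (computed once)
.analysis_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 101L) {
  key <- paste0("cohort_", seed)
  if (is.null(.analysis_cache[[key]])) {
    .analysis_cache[[key]] <- simulate_cohort(simulation_config(seed = seed))
  }
  .analysis_cache[[key]]
}
default_analysis <- function(seed = 101L) {
  key <- paste0("analysis_", seed)
  if (is.null(.analysis_cache[[key]])) {
    .analysis_cache[[key]] <- run_pipeline(default_cohort(seed))
  }
  .analysis_cache[[key]]
}
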