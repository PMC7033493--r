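#' Configuration for the synthetic cohort generator
#'
#' Returns the default study conditions for a desk-scale tumor/normal RNA
#' editing cohort: 80 tumor and 30 normal samples (20 paired) on a
#' 2 x 100 kb genome with 60 genes and 2,000 candidate editing sites, a
#' stand-in for a full-size cohort of hundreds of patients. Planted effects
#' (gain, loss, dys-edited, expression-linked and survival-linked sites)
#' and confounders (known SNPs, per-sample somatic mutations, 100%-degree
#' and low-coverage artifacts, strand-bias/quality violations) are recorded
#' as ground truth so every downstream stage can be scored.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `"simulation_config"`.
#' @details Key defaults: background editing degrees are Beta(2.5, 7.5)
#'   (mode in the 20--30% range), per-site background prevalence is
#'   Beta(1.5, 8) (most sites edited in a minority of samples), read
#'   coverage is negative binomial with mean 50 and dispersion size 5.
#'   Gain sites are edited in 40% of tumors and 0% of normals (loss sites
#'   are the mirror image), dys-edited sites shift by 0.3 within pairs,
#'   expression-linked sites target a Pearson correlation of -0.6, and
#'   survival-linked sites drive an exponential hazard with log-HR 1.2 per
#'   standard deviation of the true linear predictor.
#' @export
simulation_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_tumor = 80L, n_normal = 30L, n_paired = 20L,
    n_chrom = 2L, chrom_len = 100000L,
    n_genes = 60L, n_sites = 2000L,
    n_gain = 50L, n_loss = 50L, n_dys = 20L,
    n_expression = 30L, n_survival = 10L,
    degree_shape1 = 2.5, degree_shape2 = 7.5,
    prevalence_shape1 = 1.5, prevalence_shape2 = 8,
    coverage_mean = 50, coverage_size = 5,
    gain_tumor_frac = 0.4, gain_normal_frac = 0.0,
    loss_normal_frac = 0.7, loss_tumor_frac = 0.0,
    dys_shift = 0.3, dys_n_hypo = 5L,
    expression_target_r = -0.6, expression_noise_sd = 0.4,
    surv_log_hr = 1.5, baseline_median_days = 1100,
    censor_min = 500, censor_max = 3000,
    n_snp_overlap = 100L, n_snp_extra = 100L,
    n_mut_overlap = 50L, n_mut_overlap_samples = 4L, n_mut_per_sample = 3L,
    n_full_degree_artifact = 30L, n_lowcov_artifact = 30L,
    n_dual_strand = 10L, n_nonstandard = 10L, n_indel = 20L,
    frac_fs_violate = 0.02, frac_qd_violate = 0.02, frac_info_missing = 0.01,
    a2i_frac = 0.6,
    n_mirna = 25L, n_rewire_gain = 4L, n_rewire_loss = 4L,
    expr_log_mean = 5.5, expr_log_sd = 1, expr_gene_noise_sd = 0.4
  )
  cfg <- utils::modifyList(defaults, list(...))
  n_planted <- cfg$n_gain + cfg$n_loss + cfg$n_dys +
    cfg$n_expression + cfg$n_survival
  check_that(n_planted <= cfg$n_sites, "planted site counts exceed n_sites")
  check_that(cfg$n_paired <= min(cfg$n_tumor, cfg$n_normal),
             "n_paired exceeds group sizes")
  check_that(cfg$n_rewire_gain <= cfg$n_gain && cfg$n_rewire_loss <= cfg$n_loss,
             "rewire-designed counts exceed their classes")
  check_that(cfg$degree_shape1 > 0 && cfg$degree_shape2 > 0,
             "degree Beta parameters must be positive")
  structure(cfg, class = "simulation_config")
}

#' Configuration with all planted effects removed (null cohort)
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `"simulation_config"` with zero gain/loss/dys/expression/
#'   survival-linked sites, used for type-I-error calibration.
#' @export
null_simulation_config <- function(...) {
  simulation_config(n_gain = 0L, n_loss = 0L, n_dys = 0L,
                    n_expression = 0L, n_survival = 0L,
                    n_rewire_gain = 0L, n_rewire_loss = 0L, ...)
}

# gene layout: one transcript per protein-coding gene with three exons;
# transcript-order lengths utr5 150, cds 200/250/60 (510, divisible by 3),
# utr3 540, introns 200; total genomic span 1600
sim_gene_models <- function(cfg) {
  per_chrom <- cfg$n_genes %/% cfg$n_chrom
  spacing <- (cfg$chrom_len - 1000L) %/% per_chrom
  check_that(spacing >= 1700L, "chromosomes too short for gene count")
  lnc_idx <- integer(0)
  if (cfg$n_genes >= 12) lnc_idx <- seq(4L, cfg$n_genes, by = 10L)
  incomplete_idx <- if (cfg$n_genes >= 6) 6L else integer(0)
  rows <- purrr::map(seq_len(cfg$n_genes), function(i) {
    chrom_i <- ((i - 1L) %/% per_chrom) + 1L
    slot <- (i - 1L) %% per_chrom
    g <- 500L + slot * spacing
    strand <- if (i %% 2L == 0L) "-" else "+"
    chrom <- paste0("chr", chrom_i)
    gid <- sprintf("G%03d", i)
    tid <- sprintf("T%03d", i)
    gname <- sprintf("GENE%03d", i)
    if (i %in% lnc_idx) {
      return(tibble(
        gene_id = gid, gene_name = gname, gene_type = "lncRNA",
        chrom = chrom, strand = strand, transcript_id = tid,
        feature = "exon",
        start = g + c(0L, 550L, 1000L), end = g + c(350L, 800L, 1600L),
        frame = NA_integer_, complete = TRUE
      ))
    }
    if (strand == "+") {
      feats <- tibble(
        feature = c("exon", "exon", "exon", "utr5", "cds", "cds", "cds", "utr3"),
        start = g + c(0L, 550L, 1000L, 0L, 150L, 550L, 1000L, 1060L),
        end = g + c(350L, 800L, 1600L, 150L, 350L, 800L, 1060L, 1600L),
        frame = c(NA, NA, NA, NA, 0L, 1L, 0L, NA)
      )
    } else {
      feats <- tibble(
        feature = c("exon", "exon", "exon", "utr5", "cds", "cds", "cds", "utr3"),
        start = g + c(1250L, 800L, 0L, 1450L, 1250L, 800L, 540L, 0L),
        end = g + c(1600L, 1050L, 600L, 1600L, 1450L, 1050L, 600L, 540L),
        frame = c(NA, NA, NA, NA, 0L, 1L, 0L, NA)
      )
    }
    complete <- !(i %in% incomplete_idx)
    if (!complete) feats$frame[feats$feature == "cds"] <- NA_integer_
    dplyr::mutate(feats, gene_id = gid, gene_name = gname,
                  gene_type = "protein_coding", chrom = chrom,
                  strand = strand, transcript_id = tid, complete = complete)
  })
  models <- dplyr::bind_rows(rows)
  # two antisense single-exon lncRNAs covering the first gene of each
  # chromosome: sites inside those spans map to genes on both strands
  first_ids <- models |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(gene_id = dplyr::first(.data$gene_id),
                     .groups = "drop")
  first_genes <- models |>
    dplyr::semi_join(first_ids, by = c("chrom", "gene_id")) |>
    dplyr::group_by(.data$chrom, .data$gene_id) |>
    dplyr::summarise(strand = dplyr::first(.data$strand),
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  anti <- dplyr::mutate(first_genes,
    gene_id = paste0("AS_", .data$gene_id),
    gene_name = paste0("AS-", .data$gene_id),
    gene_type = "lncRNA",
    strand = ifelse(.data$strand == "+", "-", "+"),
    transcript_id = paste0("AS_T_", .data$gene_id),
    feature = "exon", frame = NA_integer_, complete = TRUE
  )
  models <- dplyr::bind_rows(models, anti[names(models)])
  dplyr::bind_rows(models, derive_introns(models)) |>
    dplyr::arrange(.data$gene_id, .data$start)
}

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# draw a non-A-to-I substitution pair (genomic labels), weighted to keep
# T-to-C, G-to-A, C-to-T the next most frequent types after A-to-G
draw_other_substitution <- function(n) {
  pairs <- c("T>C", "G>A", "C>T", "A>C", "A>T", "C>A", "C>G",
             "G>C", "G>T", "T>A", "T>G")
  w <- c(0.30, 0.25, 0.20, rep(0.25 / 8, 8))
  sample(pairs, n, replace = TRUE, prob = w)
}

REWIRE_MOTIF_GAIN <- "GCTGCAGTCGCAGTCG"  # site at motif position 12 (ref A)
REWIRE_MOTIF_LOSS <- "GCTGCAGTCGCTGTCG"  # site at motif position 12 (ref T)
REWIRE_SITE_OFFSET <- 11L                # 0-based offset of the site in motif

# miRNA perfectly complementary to the 16-mer (edited for gain designs,
# reference for loss designs), with a 6-nt C tail that cannot pair the
# A-run guard planted upstream of the motif
rewire_mirna <- function(motif16) paste0(revcomp(motif16), "CCCCCC")

#' Generate a fully synthetic tumor/normal RNA-editing cohort
#'
#' Draws a genome, gene annotation, per-sample variant observations with
#' read counts and quality annotations, somatic mutations, known SNPs,
#' mature miRNAs, expression counts and a clinical table, with ground truth
#' recorded for every planted effect. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"synthetic_cohort"` with elements `config`,
#'   `samples`, `canonical_chroms`, `genome`, `genes`, `mirnas`,
#'   `observations`, `mutations`, `snps`, `expression`, `clinical`, and
#'   `truth` (tables `sites`, `degrees`, `rewire`, `expression_link`,
#'   `survival`).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  cfg <- config
  if (cfg$n_tumor < 1 || cfg$n_normal < 1) {
    abort("configuration yields an empty tumor or normal group")
  }
  set.seed(cfg$seed)

  samples <- tibble(
    sample_id = c(sprintf("T%03d", seq_len(cfg$n_tumor)),
                  sprintf("N%03d", seq_len(cfg$n_normal))),
    role = c(rep("tumor", cfg$n_tumor), rep("normal", cfg$n_normal)),
    pair_id = NA_character_
  )
  if (cfg$n_paired > 0) {
    pid <- sprintf("P%03d", seq_len(cfg$n_paired))
    samples$pair_id[seq_len(cfg$n_paired)] <- pid
    samples$pair_id[cfg$n_tumor + seq_len(cfg$n_paired)] <- pid
  }

  genes <- sim_gene_models(cfg)
  canonical <- paste0("chr", seq_len(cfg$n_chrom))
  genome <- setNames(
    c(purrr::map_chr(seq_len(cfg$n_chrom), ~ rand_dna(cfg$chrom_len)),
      rand_dna(5000L)),
    c(canonical, "chrUn_scaffold1")
  )

  placed <- sim_sites(cfg, genes, canonical)
  sites <- placed$sites
  genome <- patch_genome(genome, sites, placed$windows)
  mirnas <- sim_mirnas(cfg, placed$windows)
  degrees <- sim_degrees(cfg, sites, samples)
  conf <- sim_confounders(cfg, sites, samples, degrees, canonical)
  degrees <- conf$degrees
  observations <- sim_observations(cfg, sites, degrees, conf$indels)
  expr <- sim_expression(cfg, sites, degrees, samples, genes)
  clin <- sim_clinical(cfg, sites, degrees, samples, expr$counts,
                       expr$size_factors)

  sites <- sites |>
    dplyr::left_join(attr(degrees, "dys_direction"), by = "site_id") |>
    dplyr::left_join(
      clin$survival$site_signs |>
        dplyr::select("site_id", surv_sign = "sign"),
      by = "site_id")
  attr(degrees, "dys_direction") <- NULL

  structure(list(
    config = cfg,
    samples = samples,
    canonical_chroms = canonical,
    genome = genome,
    genes = genes,
    mirnas = mirnas,
    observations = observations,
    mutations = conf$mutations,
    snps = conf$snps,
    expression = expr$counts,
    clinical = clin$clinical,
    truth = list(
      sites = sites,
      degrees = degrees,
      rewire = placed$rewire,
      expression_link = expr$link,
      survival = clin$survival
    )
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d tumor / %d normal (%d paired), %d candidate sites, %d genes\n",
    x$config$n_tumor, x$config$n_normal, x$config$n_paired,
    nrow(x$truth$sites), x$config$n_genes))
  print(dplyr::count(x$truth$sites, .data$class))
  invisible(x)
}

# ---- site placement -------------------------------------------------------

sim_sites <- function(cfg, genes, canonical) {
  dual_genes <- unique(genes$gene_id[startsWith(genes$gene_id, "AS_")])
  dual_spans <- genes |>
    dplyr::filter(.data$gene_id %in% dual_genes) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  covered <- genes |>
    dplyr::semi_join(dual_spans, by = "chrom") |>
    dplyr::filter(!startsWith(.data$gene_id, "AS_")) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     chrom = dplyr::first(.data$chrom), .groups = "drop") |>
    dplyr::inner_join(dual_spans, by = "chrom", suffix = c("", ".as")) |>
    dplyr::filter(.data$start < .data$end.as, .data$end > .data$start.as) |>
    dplyr::pull(.data$gene_id)
  usable <- genes |>
    dplyr::filter(!.data$gene_id %in% c(covered, dual_genes))

  pool <- function(feat, pc_only = TRUE, complete_only = FALSE) {
    p <- dplyr::filter(usable, .data$feature == feat)
    if (pc_only) p <- dplyr::filter(p, .data$gene_type == "protein_coding")
    if (complete_only) p <- dplyr::filter(p, .data$complete)
    p
  }
  pools <- list(
    utr3 = pool("utr3"), utr5 = pool("utr5"),
    cds = pool("cds", complete_only = TRUE), intron = pool("intron")
  )
  gene_spans <- genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(iv = list(IRanges::reduce(IRanges::IRanges(
      start = .data$start + 1L, end = .data$end))), .groups = "drop")

  occupied <- new.env(parent = emptyenv())
  take_pos <- function(chrom, lo, hi, margin = 0L) {
    for (i in 1:200) {
      p <- sample(seq.int(lo + margin, hi - 1L - margin), 1L)
      key <- paste0(chrom, ":", p)
      if (is.null(occupied[[key]])) {
        for (q in (p - margin):(p + margin)) {
          occupied[[paste0(chrom, ":", q)]] <- TRUE
        }
        return(p)
      }
    }
    abort("could not place site: region saturated")
  }
  place_in_pool <- function(p, margin = 0L, strand = NULL) {
    if (!is.null(strand)) p <- dplyr::filter(p, .data$strand == !!strand)
    row <- p[sample.int(nrow(p), 1L), ]
    tibble(chrom = row$chrom,
           pos = take_pos(row$chrom, row$start, row$end, margin),
           gene_id = row$gene_id, transcript_id = row$transcript_id,
           strand = row$strand, feature = row$feature)
  }
  place_intergenic <- function(chrom) {
    iv <- gene_spans$iv[[match(chrom, gene_spans$chrom)]]
    for (i in 1:500) {
      p <- sample.int(cfg$chrom_len, 1L) - 1L
      inside <- any(p + 1L >= IRanges::start(iv) & p + 1L <= IRanges::end(iv))
      key <- paste0(chrom, ":", p)
      if (!inside && is.null(occupied[[key]])) {
        occupied[[key]] <- TRUE
        return(p)
      }
    }
    abort("could not place intergenic site")
  }

  feature_of <- function(class, k) {
    if (class %in% c("gain", "loss")) {
      sample(c("utr3", "cds", "intron"), k, TRUE, prob = c(0.6, 0.2, 0.2))
    } else if (class == "dys_edit") {
      sample(c("utr3", "cds", "intron"), k, TRUE, prob = c(0.5, 0.25, 0.25))
    } else if (class %in% c("expression_linked", "survival_linked")) {
      rep("utr3", k)
    } else {
      sample(c("utr3", "intron", "utr5", "cds", "intergenic"), k, TRUE,
             prob = c(0.52, 0.20, 0.08, 0.05, 0.15))
    }
  }

  n_bg <- cfg$n_sites - cfg$n_gain - cfg$n_loss - cfg$n_dys -
    cfg$n_expression - cfg$n_survival - cfg$n_dual_strand - cfg$n_nonstandard
  spec <- tibble(
    class = c(rep("gain", cfg$n_gain), rep("loss", cfg$n_loss),
              rep("dys_edit", cfg$n_dys),
              rep("expression_linked", cfg$n_expression),
              rep("survival_linked", cfg$n_survival),
              rep("background", n_bg)),
    rewire_design = NA_character_
  )
  if (cfg$n_rewire_gain > 0) {
    spec$rewire_design[seq_len(cfg$n_rewire_gain)] <- "gain"
  }
  if (cfg$n_rewire_loss > 0) {
    spec$rewire_design[cfg$n_gain + seq_len(cfg$n_rewire_loss)] <- "loss"
  }
  spec$feature <- NA_character_
  for (cl in unique(spec$class)) {
    idx <- which(spec$class == cl)
    spec$feature[idx] <- feature_of(cl, length(idx))
  }
  spec$feature[!is.na(spec$rewire_design)] <- "utr3"

  # expression-linked and survival-linked sites get one distinct gene each
  # (survival-linked sites carry a planted degree-expression link so they
  # qualify as consequence-bearing downstream)
  n_linked <- cfg$n_expression + cfg$n_survival
  expr_genes <- character(0)
  if (n_linked > 0) {
    cand <- unique(pools$utr3$gene_id)
    check_that(length(cand) >= n_linked,
               "not enough genes for expression/survival-linked sites")
    expr_genes <- sample(cand, n_linked)
  }

  windows <- list()
  rows <- vector("list", nrow(spec))
  expr_i <- 0L
  for (i in seq_len(nrow(spec))) {
    cl <- spec$class[[i]]
    feat <- spec$feature[[i]]
    design <- spec$rewire_design[[i]]
    if (!is.na(design)) {
      # designed miRNA-rewiring site: interior of a + strand 3'UTR so the
      # 16-mer motif and its upstream guard fit in transcript orientation
      loc <- place_in_pool(pools$utr3, margin = 30L, strand = "+")
      ref <- if (design == "gain") "A" else "T"
      alt <- if (design == "gain") "G" else "C"
      motif <- if (design == "gain") REWIRE_MOTIF_GAIN else REWIRE_MOTIF_LOSS
      windows[[length(windows) + 1L]] <- list(
        chrom = loc$chrom, pos = loc$pos, design = design, motif = motif)
    } else if (cl %in% c("expression_linked", "survival_linked")) {
      expr_i <- expr_i + 1L
      p <- dplyr::filter(pools$utr3, .data$gene_id == expr_genes[[expr_i]])
      loc <- place_in_pool(p)
    } else if (feat == "intergenic") {
      chrom <- sample(canonical, 1L)
      loc <- tibble(chrom = chrom, pos = place_intergenic(chrom),
                    gene_id = NA_character_, transcript_id = NA_character_,
                    strand = NA_character_, feature = "intergenic")
    } else {
      loc <- place_in_pool(pools[[feat]])
    }
    if (is.na(design)) {
      a2i <- !is.na(loc$strand) && stats::runif(1) < cfg$a2i_frac
      if (a2i) {
        ref <- if (loc$strand == "+") "A" else "T"
        alt <- if (loc$strand == "+") "G" else "C"
      } else {
        sub <- strsplit(draw_other_substitution(1L), ">", fixed = TRUE)[[1]]
        ref <- sub[[1]]; alt <- sub[[2]]
      }
    }
    rows[[i]] <- dplyr::mutate(loc, class = cl, ref = ref, alt = alt,
                               rewire_design = design)
  }
  main <- dplyr::bind_rows(rows)

  extra <- list()
  if (cfg$n_dual_strand > 0) {
    ds <- purrr::map(seq_len(cfg$n_dual_strand), function(i) {
      row <- dual_spans[sample.int(nrow(dual_spans), 1L), ]
      tibble(chrom = row$chrom,
             pos = take_pos(row$chrom, row$start + 5L, row$end - 5L),
             gene_id = NA_character_, transcript_id = NA_character_,
             strand = NA_character_, feature = "exonic",
             class = "background", ref = NA_character_, alt = NA_character_,
             rewire_design = NA_character_)
    })
    ds <- dplyr::bind_rows(ds)
    sub <- strsplit(draw_other_substitution(nrow(ds)), ">", TRUE)
    ds$ref <- purrr::map_chr(sub, 1); ds$alt <- purrr::map_chr(sub, 2)
    ds$is_dual_strand <- TRUE
    extra$dual <- ds
  }
  if (cfg$n_nonstandard > 0) {
    ns <- tibble(
      chrom = "chrUn_scaffold1",
      pos = sample.int(4900L, cfg$n_nonstandard) + 50L,
      gene_id = NA_character_, transcript_id = NA_character_,
      strand = NA_character_, feature = "intergenic",
      class = "background", rewire_design = NA_character_,
      is_nonstandard = TRUE
    )
    sub <- strsplit(draw_other_substitution(nrow(ns)), ">", TRUE)
    ns$ref <- purrr::map_chr(sub, 1); ns$alt <- purrr::map_chr(sub, 2)
    extra$ns <- ns
  }
  sites <- dplyr::bind_rows(c(list(main), unname(extra)))
  sites$is_dual_strand <- isTRUE_vec(sites$is_dual_strand, nrow(sites))
  sites$is_nonstandard <- isTRUE_vec(sites$is_nonstandard, nrow(sites))
  sites <- dplyr::mutate(sites,
    site_id = site_key(.data$chrom, .data$pos, .data$ref, .data$alt))

  # artifact / confounder flags over background sites on canonical chroms
  bg <- which(sites$class == "background" & !sites$is_dual_strand &
                !sites$is_nonstandard)
  pick <- function(n, from) {
    sel <- sample(from, min(n, length(from)))
    from <<- setdiff(from, sel)
    sel
  }
  from <- bg
  sites$is_snp_overlap <- FALSE
  sites$is_mut_overlap <- FALSE
  sites$is_full_degree_artifact <- FALSE
  sites$is_low_coverage <- FALSE
  sites$is_snp_overlap[pick(cfg$n_snp_overlap, from)] <- TRUE
  sites$is_mut_overlap[pick(cfg$n_mut_overlap, from)] <- TRUE
  sites$is_full_degree_artifact[pick(cfg$n_full_degree_artifact, from)] <- TRUE
  sites$is_low_coverage[pick(cfg$n_lowcov_artifact, from)] <- TRUE

  rewire <- tibble(site_id = character(), mirna_id = character(),
                   expected_kind = character())
  if (length(windows) > 0) {
    wdf <- dplyr::bind_rows(purrr::map(windows, as_tibble))
    wdf <- dplyr::left_join(wdf,
      dplyr::select(sites, "chrom", "pos", "site_id"),
      by = c("chrom", "pos"))
    gi <- cumsum(wdf$design == "gain")
    li <- cumsum(wdf$design == "loss")
    wdf$mirna_id <- ifelse(wdf$design == "gain",
                           sprintf("mir-gain-%d", gi),
                           sprintf("mir-loss-%d", li))
    rewire <- tibble(site_id = wdf$site_id, mirna_id = wdf$mirna_id,
                     expected_kind = paste0("edited_", wdf$design))
    windows <- purrr::map2(windows, wdf$mirna_id,
                           function(w, id) { w$mirna_id <- id; w })
  }
  list(sites = sites, windows = windows, rewire = rewire)
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) rep(FALSE, n) else !is.na(x) & x
}

patch_genome <- function(genome, sites, windows) {
  ss <- dplyr::filter(sites, !is.na(.data$ref))
  for (chrom in unique(ss$chrom)) {
    rows <- ss[ss$chrom == chrom, ]
    s <- genome[[chrom]]
    for (j in seq_len(nrow(rows))) {
      substr(s, rows$pos[[j]] + 1L, rows$pos[[j]] + 1L) <- rows$ref[[j]]
    }
    genome[[chrom]] <- s
  }
  # designed motifs: 16-mer with the site at offset 11 (0-based) plus a
  # 6-A guard immediately upstream of the motif
  for (w in windows) {
    s <- genome[[w$chrom]]
    m_start <- w$pos - REWIRE_SITE_OFFSET          # 0-based motif start
    substr(s, m_start - 5L, m_start) <- "AAAAAA"
    substr(s, m_start + 1L, m_start + 16L) <- w$motif
    genome[[w$chrom]] <- s
  }
  genome
}

sim_mirnas <- function(cfg, windows) {
  designed <- character(0)
  if (length(windows) > 0) {
    designed <- setNames(
      purrr::map_chr(windows, function(w) {
        motif <- w$motif
        if (w$design == "gain") {
          substr(motif, REWIRE_SITE_OFFSET + 1L, REWIRE_SITE_OFFSET + 1L) <- "G"
        }
        rewire_mirna(motif)
      }),
      purrr::map_chr(windows, "mirna_id")
    )
  }
  n_rand <- max(0L, cfg$n_mirna - length(designed))
  rand <- setNames(purrr::map_chr(seq_len(n_rand), ~ rand_dna(22L)),
                   sprintf("mir-%03d", seq_len(n_rand)))
  c(designed, rand)
}

# ---- editing degrees ------------------------------------------------------

sim_degrees <- function(cfg, sites, samples) {
  tumors <- samples$sample_id[samples$role == "tumor"]
  normals <- samples$sample_id[samples$role == "normal"]
  all_ids <- samples$sample_id
  pairs <- samples |>
    dplyr::filter(!is.na(.data$pair_id)) |>
    dplyr::select("sample_id", "role", "pair_id") |>
    tidyr::pivot_wider(names_from = "role", values_from = "sample_id")

  rbeta_deg <- function(n) {
    clamp(rbeta(n, cfg$degree_shape1, cfg$degree_shape2), 0.02, 0.95)
  }
  bern_subset <- function(ids, frac) ids[stats::runif(length(ids)) < frac]

  out <- vector("list", nrow(sites))
  dys_dir <- rep(NA_character_, nrow(sites))
  n_hypo_left <- cfg$dys_n_hypo
  for (i in seq_len(nrow(sites))) {
    cl <- sites$class[[i]]
    sid <- sites$site_id[[i]]
    if (cl == "gain" || cl == "survival_linked") {
      tf <- if (cl == "gain") cfg$gain_tumor_frac else 0.6
      ed_t <- bern_subset(tumors, tf)
      ed_n <- bern_subset(normals, cfg$gain_normal_frac)
      ed <- c(ed_t, ed_n)
      if (length(ed) == 0) next
      out[[i]] <- tibble(site_id = sid, sample_id = ed,
                         degree = rbeta_deg(length(ed)))
    } else if (cl == "loss") {
      ed <- c(bern_subset(normals, cfg$loss_normal_frac),
              bern_subset(tumors, cfg$loss_tumor_frac))
      if (length(ed) == 0) next
      out[[i]] <- tibble(site_id = sid, sample_id = ed,
                         degree = rbeta_deg(length(ed)))
    } else if (cl == "dys_edit") {
      hypo <- n_hypo_left > 0
      if (hypo) n_hypo_left <- n_hypo_left - 1L
      dys_dir[[i]] <- if (hypo) "hypo" else "hyper"
      base <- if (hypo) stats::runif(1, 0.40, 0.60) else stats::runif(1, 0.08, 0.45)
      u <- rnorm(nrow(pairs), 0, 0.03)
      nd <- clamp(base + u, 0.03, 0.92)
      td <- clamp(nd + ifelse(hypo, -cfg$dys_shift, cfg$dys_shift), 0.02, 0.95)
      unpaired <- setdiff(all_ids, c(pairs$tumor, pairs$normal))
      ed_u <- bern_subset(unpaired, 0.3)
      out[[i]] <- dplyr::bind_rows(
        tibble(site_id = sid, sample_id = pairs$normal, degree = nd),
        tibble(site_id = sid, sample_id = pairs$tumor, degree = td),
        if (length(ed_u) > 0) {
          tibble(site_id = sid, sample_id = ed_u,
                 degree = clamp(rbeta(length(ed_u), 4, 8), 0.02, 0.95))
        }
      )
    } else {
      # background, artifacts, expression-linked
      prev <- if (cl == "expression_linked") {
        stats::runif(1, 0.4, 0.7)
      } else {
        rbeta(1, cfg$prevalence_shape1, cfg$prevalence_shape2)
      }
      ed <- bern_subset(all_ids, prev)
      if (length(ed) == 0) next
      out[[i]] <- tibble(site_id = sid, sample_id = ed,
                         degree = rbeta_deg(length(ed)))
    }
  }
  degrees <- dplyr::bind_rows(out)
  attr(degrees, "dys_direction") <- tibble(
    site_id = sites$site_id, dys_direction = dys_dir
  ) |> dplyr::filter(!is.na(.data$dys_direction))
  degrees
}

# ---- confounders: SNPs, mutations, indels ---------------------------------

sim_confounders <- function(cfg, sites, samples, degrees, canonical) {
  tumors <- samples$sample_id[samples$role == "tumor"]

  snp_sites <- dplyr::filter(sites, .data$is_snp_overlap)
  extra_pos <- tibble(
    chrom = sample(canonical, cfg$n_snp_extra, replace = TRUE),
    pos = sample.int(cfg$chrom_len - 2L, cfg$n_snp_extra)
  )
  snps <- dplyr::bind_rows(
    dplyr::select(snp_sites, "chrom", "pos"),
    extra_pos
  ) |> dplyr::distinct()

  mut_sites <- dplyr::filter(sites, .data$is_mut_overlap)
  mut_rows <- purrr::map(seq_len(nrow(mut_sites)), function(i) {
    carriers <- sample(tumors, cfg$n_mut_overlap_samples)
    tibble(sample_id = carriers,
           chrom = mut_sites$chrom[[i]], pos = mut_sites$pos[[i]],
           ref = mut_sites$ref[[i]], alt = mut_sites$alt[[i]])
  })
  extra_mut <- purrr::map(tumors, function(s) {
    tibble(sample_id = s,
           chrom = sample(canonical, cfg$n_mut_per_sample, replace = TRUE),
           pos = sample.int(cfg$chrom_len - 2L, cfg$n_mut_per_sample),
           ref = "N", alt = "N")
  })
  mutations <- dplyr::bind_rows(c(mut_rows, extra_mut))

  # mutation carriers must show the variant so removal is observable:
  # force them into the edited set of the overlapped site
  forced <- dplyr::bind_rows(mut_rows) |>
    dplyr::inner_join(dplyr::select(sites, "chrom", "pos", "site_id"),
                      by = c("chrom", "pos")) |>
    dplyr::transmute(.data$site_id, .data$sample_id,
                     degree = clamp(rbeta(dplyr::n(), cfg$degree_shape1,
                                          cfg$degree_shape2), 0.02, 0.95))
  degrees <- dplyr::bind_rows(degrees, forced) |>
    dplyr::distinct(.data$site_id, .data$sample_id, .keep_all = TRUE)

  indels <- tibble()
  if (cfg$n_indel > 0) {
    ipos <- sample.int(cfg$chrom_len - 10L, cfg$n_indel)
    indels <- tibble(
      sample_id = sample(tumors, cfg$n_indel, replace = TRUE),
      chrom = sample(canonical, cfg$n_indel, replace = TRUE),
      pos = ipos,
      ref = sample(DNA_BASES, cfg$n_indel, replace = TRUE),
      alt = NA_character_
    )
    indels$alt <- paste0(indels$ref, sample(DNA_BASES, cfg$n_indel, TRUE))
  }
  list(snps = snps, mutations = mutations, indels = indels, degrees = degrees)
}

# ---- read-level observations ----------------------------------------------

sim_observations <- function(cfg, sites, degrees, indels) {
  d <- dplyr::left_join(degrees,
    dplyr::select(sites, "site_id", "chrom", "pos", "ref", "alt",
                  "is_low_coverage", "is_full_degree_artifact"),
    by = "site_id")
  n <- nrow(d)
  cov <- ifelse(d$is_low_coverage,
                pmax(1L, rpois(n, 4)),
                pmax(2L, rnbinom(n, size = cfg$coverage_size,
                                 mu = cfg$coverage_mean)))
  k <- pmax(1L, rbinom(n, cov, d$degree))
  # 100%-degree artifacts: force k = n in up to 3 edited samples per site
  if (any(d$is_full_degree_artifact)) {
    idx <- which(d$is_full_degree_artifact)
    by_site <- split(idx, d$site_id[idx])
    force_idx <- unlist(purrr::map(by_site, function(ii) {
      ii[seq_len(min(3L, length(ii)))]
    }), use.names = FALSE)
    k[force_idx] <- cov[force_idx]
  }
  fs <- ifelse(stats::runif(n) < cfg$frac_fs_violate,
               stats::runif(n, 20.5, 60), stats::runif(n, 0, 15))
  qd <- ifelse(stats::runif(n) < cfg$frac_qd_violate,
               stats::runif(n, 0, 1.9), stats::runif(n, 2.5, 35))
  fs[stats::runif(n) < cfg$frac_info_missing] <- NA
  qd[stats::runif(n) < cfg$frac_info_missing] <- NA
  obs <- tibble(
    sample_id = d$sample_id, chrom = d$chrom, pos = d$pos,
    ref = d$ref, alt = d$alt,
    ref_reads = as.integer(cov - k), alt_reads = as.integer(k),
    fs = fs, qd = qd
  )
  if (nrow(indels) > 0) {
    ind <- dplyr::mutate(indels,
      ref_reads = pmax(2L, rnbinom(dplyr::n(), size = cfg$coverage_size,
                                   mu = cfg$coverage_mean)),
      alt_reads = pmax(2L, rbinom(dplyr::n(), .data$ref_reads, 0.3)),
      fs = stats::runif(dplyr::n(), 0, 10),
      qd = stats::runif(dplyr::n(), 5, 30))
    obs <- dplyr::bind_rows(obs, ind[names(obs)])
  }
  dplyr::arrange(obs, .data$sample_id, .data$chrom, .data$pos)
}

# ---- expression and clinical ----------------------------------------------

sim_expression <- function(cfg, sites, degrees, samples, genes) {
  gene_ids <- unique(genes$gene_id[!startsWith(genes$gene_id, "AS_")])
  n_g <- length(gene_ids)
  n_s <- nrow(samples)
  base <- exp(rnorm(n_g, cfg$expr_log_mean, cfg$expr_log_sd))
  sf <- exp(rnorm(n_s, 0, 0.15))
  log_mu <- matrix(rnorm(n_g * n_s, 0, cfg$expr_gene_noise_sd), n_g, n_s,
                   dimnames = list(gene_ids, samples$sample_id))

  link_sites <- dplyr::filter(
    sites, .data$class %in% c("expression_linked", "survival_linked"))
  link <- tibble(site_id = character(), gene_id = character(),
                 target_r = double(), slope = double())
  if (nrow(link_sites) > 0) {
    r <- cfg$expression_target_r
    sd_deg <- sqrt(cfg$degree_shape1 * cfg$degree_shape2 /
      ((cfg$degree_shape1 + cfg$degree_shape2)^2 *
         (cfg$degree_shape1 + cfg$degree_shape2 + 1)))
    # 1.6: empirical inflation so the Pearson r measured on normalized
    # counts matches the target despite the exp link, Poisson count noise
    # and binomial read-sampling noise on the observed degrees
    slope <- 1.6 * sign(r) * abs(r) / sqrt(1 - r^2) *
      cfg$expression_noise_sd / sd_deg
    link <- tibble(site_id = link_sites$site_id,
                   gene_id = link_sites$gene_id,
                   target_r = r, slope = slope)
    deg_w <- degrees |>
      dplyr::semi_join(link, by = "site_id") |>
      dplyr::left_join(dplyr::select(link, "site_id", "gene_id"),
                       by = "site_id")
    for (j in seq_len(nrow(deg_w))) {
      g <- deg_w$gene_id[[j]]; s <- deg_w$sample_id[[j]]
      log_mu[g, s] <- rnorm(1, slope * deg_w$degree[[j]],
                            cfg$expression_noise_sd)
    }
  }
  mu <- base * exp(log_mu) %*% diag(sf)
  counts <- matrix(rpois(n_g * n_s, mu), n_g, n_s,
                   dimnames = list(gene_ids, samples$sample_id))
  storage.mode(counts) <- "integer"
  list(counts = counts, link = link,
       size_factors = setNames(sf, samples$sample_id))
}

sim_clinical <- function(cfg, sites, degrees, samples, counts,
                         size_factors) {
  tumors <- samples$sample_id[samples$role == "tumor"]
  surv_sites <- dplyr::filter(sites, .data$class == "survival_linked")
  signs <- tibble(site_id = surv_sites$site_id,
                  gene_id = surv_sites$gene_id,
                  sign = rep_len(c(1, 1, 1, 1, 1, 1, 1, -1, -1, -1),
                                 nrow(surv_sites)))
  # the true linear predictor has the same functional form as the risk
  # score the method estimates: sign x normalized expression x degree
  lp <- setNames(rep(0, length(tumors)), tumors)
  if (nrow(signs) > 0) {
    dd <- degrees |>
      dplyr::semi_join(signs, by = "site_id") |>
      dplyr::filter(.data$sample_id %in% tumors) |>
      dplyr::left_join(signs, by = "site_id")
    dd$expr <- purrr::map_dbl(seq_len(nrow(dd)), function(i) {
      counts[dd$gene_id[[i]], dd$sample_id[[i]]] /
        size_factors[[dd$sample_id[[i]]]]
    })
    dd <- dd |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(lp = sum(.data$sign * .data$expr * .data$degree),
                       .groups = "drop")
    lp[dd$sample_id] <- dd$lp
  }
  lp_std <- if (sd(lp) > 0) (lp - mean(lp)) / sd(lp) else lp * 0
  rate <- log(2) / cfg$baseline_median_days * exp(cfg$surv_log_hr * lp_std)
  t_event <- rexp(length(tumors), rate)
  t_cens <- stats::runif(length(tumors), cfg$censor_min, cfg$censor_max)
  time <- pmax(1, round(pmin(t_event, t_cens)))
  event <- as.integer(t_event <= t_cens)

  n <- length(tumors)
  grade_lat <- 0.4 * lp_std + rnorm(n)
  stage_lat <- 0.4 * lp_std + rnorm(n)
  cutq <- function(x, probs, labels) {
    cuts <- stats::quantile(x, cumsum(probs)[-length(probs)])
    labels[findInterval(x, cuts) + 1L]
  }
  clinical <- tibble(
    sample_id = tumors,
    time = time, event = event,
    gender = sample(c("male", "female"), n, TRUE, prob = c(0.7, 0.3)),
    age = round(rnorm(n, 60, 10)),
    bmi = round(rnorm(n, 25, 4), 1),
    grade = cutq(grade_lat, c(0.15, 0.45, 0.30, 0.10),
                 c("G1", "G2", "G3", "G4")),
    stage = cutq(stage_lat, c(0.25, 0.35, 0.30, 0.10),
                 c("T1", "T2", "T3", "T4")),
    hbv_hcv = as.integer(stats::runif(n) < 0.45),
    alcohol = as.integer(stats::runif(n) < 0.30),
    nafld = as.integer(stats::runif(n) < 0.25)
  )
  list(clinical = clinical,
       survival = list(per_patient = tibble(sample_id = tumors,
                                            true_lp = unname(lp),
                                            true_lp_std = unname(lp_std)),
                       site_signs = signs))
}

# ---- file emission --------------------------------------------------------

#' Write a synthetic cohort to standard-format files
#'
#' Emits per-sample variant VCFs, a mutations TSV, a known-SNP VCF, the
#' genome FASTA, gene annotation GTF, miRNA FASTA (RNA alphabet),
#' expression TSV, clinical TSV and ground-truth TSVs.
#'
#' @param cohort A `"synthetic_cohort"` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of emitted paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  contigs <- setNames(nchar(cohort$genome), names(cohort$genome))
  vcfs <- purrr::map_chr(unique(cohort$samples$sample_id), function(s) {
    p <- file.path(dir, "vcf", paste0(s, ".vcf"))
    obs <- dplyr::filter(cohort$observations, .data$sample_id == s)
    write_variant_vcf(obs, p, sample_id = s, contigs = contigs)
    p
  })
  paths <- list(
    vcfs = vcfs,
    mutations = file.path(dir, "mutations.tsv"),
    snps = file.path(dir, "snps.vcf"),
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    mirnas = file.path(dir, "mirnas.fa"),
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth_sites = file.path(dir, "truth", "sites.tsv"),
    truth_degrees = file.path(dir, "truth", "degrees.tsv")
  )
  readr::write_tsv(dplyr::mutate(cohort$mutations, pos = .data$pos + 1L),
                   paths$mutations)
  write_snp_vcf(cohort$snps, paths$snps)
  write_fasta(cohort$genome, paths$genome)
  write_gtf(cohort$genes, paths$gtf)
  write_fasta(cohort$mirnas, paths$mirnas, rna = TRUE)
  write_expression_matrix(cohort$expression, paths$expression)
  readr::write_tsv(cohort$clinical, paths$clinical)
  readr::write_tsv(cohort$truth$sites, paths$truth_sites)
  readr::write_tsv(cohort$truth$degrees, paths$truth_degrees)
  invisible(paths)
}
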