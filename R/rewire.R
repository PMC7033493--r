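#' Parameters of the internal miRNA-target duplex scorer
#'
#' A self-contained miRanda-style engine: a local alignment of the
#' reversed miRNA against the target window by dynamic programming over
#' complementarity, and a nearest-neighbor stack-energy model for the
#' duplex free energy. Pair rewards are Watson-Crick +5, G:U wobble +2,
#' mismatch -3, with positions 2-8 of the miRNA (the seed) weighted by a
#' fixed x2 multiplier; gaps are affine with open -4 and extend -9. The
#' final score is scaled by 1.25 so that a perfect ~22-nt duplex scores
#' about 180, comfortably above the 140 reporting cutoff. A hit is
#' reported iff score > `min_score` and duplex free energy < `max_dg`
#' kcal/mol.
#'
#' @param wc,wobble,mismatch Per-position pair scores.
#' @param seed_from,seed_to,seed_mult Seed window (miRNA positions) and
#'   multiplier.
#' @param gap_open,gap_extend Affine gap penalties (a length-L gap costs
#'   `gap_open + L * gap_extend`).
#' @param scale Final score scale factor.
#' @param min_score,max_dg Hit-reporting thresholds.
#' @param initiation Duplex initiation penalty (kcal/mol).
#' @param wobble_stack Stack energy when a wobble pair is involved.
#' @return A list of scorer parameters.
#' @export
duplex_params <- function(wc = 5, wobble = 2, mismatch = -3,
                          seed_from = 2L, seed_to = 8L, seed_mult = 2,
                          gap_open = -4, gap_extend = -9, scale = 1.25,
                          min_score = 140, max_dg = -14,
                          initiation = 4.1, wobble_stack = -1.3) {
  as.list(environment())
}

# Turner-like RNA nearest-neighbor stack energies (kcal/mol) keyed by the
# target-strand dinucleotide (DNA alphabet, T for U), Watson-Crick pairs
NN_STACK <- c(
  AA = -0.93, AT = -1.10, AC = -2.24, AG = -2.08,
  TA = -1.33, TT = -0.93, TG = -2.11, TC = -2.35,
  CA = -2.11, CT = -2.08, CG = -2.36, CC = -3.26,
  GA = -2.35, GT = -2.24, GG = -3.26, GC = -3.42
)

pair_class <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "C" & t == "G") | (m == "G" & t == "C")
  wob <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "wc", ifelse(wob, "wobble", "mismatch"))
}

#' Score a miRNA against a target window
#'
#' Runs the duplex scorer of [duplex_params()] and reports the best local
#' alignment. The duplex free energy is computed over the aligned pairs by
#' nearest-neighbor stacking: consecutive complementary pairs contribute
#' the stack energy of their target dinucleotide (a flat value when a
#' wobble is involved), mismatch and gap positions contribute 0 and break
#' stacking, plus a duplex-initiation penalty.
#'
#' @param mirna miRNA sequence, 5'->3', DNA alphabet (>= 15 nt).
#' @param window Target window sequence, 5'->3', DNA alphabet.
#' @param params [duplex_params()].
#' @return One-row tibble with `score`, `dg`, `target_start`,
#'   `target_end` (0-based half-open in the window), `n_paired`, `hit`
#'   (does it pass both thresholds?).
#' @export
score_duplex <- function(mirna, window, params = duplex_params()) {
  if (nchar(mirna) < 15) abort("miRNA shorter than 15 nt")
  m <- rev(strsplit(mirna, "", fixed = TRUE)[[1]])     # reversed miRNA
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  nm <- length(m); nw <- length(w)
  orig_pos <- nm:1                                     # miRNA position of m[i]
  seed <- orig_pos >= params$seed_from & orig_pos <= params$seed_to
  sub <- matrix(0, nm, nw)
  for (i in seq_len(nm)) {
    cls <- pair_class(m[[i]], w)
    s <- ifelse(cls == "wc", params$wc,
                ifelse(cls == "wobble", params$wobble, params$mismatch))
    if (seed[[i]]) s <- s * params$seed_mult
    sub[i, ] <- s
  }
  go <- params$gap_open + params$gap_extend
  ge <- params$gap_extend
  H <- matrix(0, nm + 1, nw + 1)
  E <- matrix(-Inf, nm + 1, nw + 1)
  F <- matrix(-Inf, nm + 1, nw + 1)
  ptr <- matrix(0L, nm + 1, nw + 1)  # 0 stop, 1 diag, 2 left(E), 3 up(F)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2:(nm + 1)) {
    for (j in 2:(nw + 1)) {
      E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
      diag <- H[i - 1, j - 1] + sub[i - 1, j - 1]
      h <- max(0, diag, E[i, j], F[i, j])
      H[i, j] <- h
      ptr[i, j] <- if (h == 0) 0L else if (h == diag) 1L else
        if (h == E[i, j]) 2L else 3L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  score <- best * params$scale
  pairs_i <- integer(0); pairs_j <- integer(0)
  i <- bi; j <- bj
  eps <- 1e-9
  while (i > 1 && j > 1 && H[i, j] > 0) {
    p <- ptr[i, j]
    if (p == 1L) {
      pairs_i <- c(i - 1L, pairs_i); pairs_j <- c(j - 1L, pairs_j)
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) {
      # gap consuming window bases: find its length, no pairs emitted
      L <- 1L
      while (j - L >= 1 &&
             abs(E[i, j] - (H[i, j - L] + go + (L - 1) * ge)) > eps) {
        L <- L + 1L
      }
      j <- j - L
    } else if (p == 3L) {
      L <- 1L
      while (i - L >= 1 &&
             abs(F[i, j] - (H[i - L, j] + go + (L - 1) * ge)) > eps) {
        L <- L + 1L
      }
      i <- i - L
    } else break
  }
  dg <- duplex_dg(m, w, pairs_i, pairs_j, params)
  tibble(
    score = score, dg = dg,
    target_start = if (length(pairs_j)) pairs_j[[1]] - 1L else NA_integer_,
    target_end = if (length(pairs_j)) pairs_j[[length(pairs_j)]] else NA_integer_,
    n_paired = length(pairs_i),
    hit = score > params$min_score & dg < params$max_dg
  )
}

duplex_dg <- function(m, w, pairs_i, pairs_j, params) {
  if (length(pairs_i) == 0) return(params$initiation)
  cls <- pair_class(m[pairs_i], w[pairs_j])
  dg <- params$initiation
  for (k in seq_len(length(pairs_i) - 1)) {
    adjacent <- pairs_i[[k + 1]] == pairs_i[[k]] + 1L &&
      pairs_j[[k + 1]] == pairs_j[[k]] + 1L
    both_paired <- cls[[k]] != "mismatch" && cls[[k + 1]] != "mismatch"
    if (adjacent && both_paired) {
      if (cls[[k]] == "wc" && cls[[k + 1]] == "wc") {
        dinuc <- paste0(w[pairs_j[[k]]], w[pairs_j[[k + 1]]])
        dg <- dg + NN_STACK[[dinuc]]
      } else {
        dg <- dg + params$wobble_stack
      }
    }
  }
  dg
}

#' Build reference and edited target windows for a 3'UTR editing site
#'
#' For every transcript whose 3'UTR contains the site, the spliced
#' transcript sequence is built in sense orientation (minus-strand genes
#' reverse-complemented), and a window of `flank` bases on each side of
#' the site is extracted (truncated at transcript ends). The edited
#' window substitutes the alternate allele, mapped to the transcript
#' strand, at the site position.
#'
#' @param site One-row tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models Gene-model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param flank Flank length (default 50 bp).
#' @return Tibble with `transcript_id`, `ref_window`, `edited_window`,
#'   `center` (0-based site offset within the window); zero rows when the
#'   site is in no transcript's 3'UTR.
#' @export
build_windows <- function(site, gene_models, genome, flank = 50L) {
  utr <- gene_models |>
    dplyr::filter(.data$feature == "utr3", .data$chrom == site$chrom,
                  .data$start <= site$pos, .data$end > site$pos)
  purrr::map(unique(utr$transcript_id), function(tid) {
    exons <- gene_models |>
      dplyr::filter(.data$transcript_id == tid, .data$feature == "exon") |>
      dplyr::arrange(.data$start)
    minus <- exons$strand[[1]] == "-"
    ex <- if (minus) exons[rev(seq_len(nrow(exons))), ] else exons
    seqs <- purrr::map_chr(seq_len(nrow(ex)), function(i) {
      s <- substr(genome[[ex$chrom[[i]]]], ex$start[[i]] + 1L, ex$end[[i]])
      if (minus) revcomp(s) else s
    })
    tx_seq <- paste(seqs, collapse = "")
    off <- 0L; tpos <- NA_integer_
    for (i in seq_len(nrow(ex))) {
      if (site$pos >= ex$start[[i]] && site$pos < ex$end[[i]]) {
        within <- if (minus) ex$end[[i]] - 1L - site$pos else
          site$pos - ex$start[[i]]
        tpos <- off + within
        break
      }
      off <- off + (ex$end[[i]] - ex$start[[i]])
    }
    if (is.na(tpos)) return(NULL)
    ref_t <- if (minus) complement_base(site$ref) else site$ref
    alt_t <- if (minus) complement_base(site$alt) else site$alt
    if (substr(tx_seq, tpos + 1L, tpos + 1L) != ref_t) return(NULL)
    lo <- max(0L, tpos - flank)
    hi <- min(nchar(tx_seq), tpos + flank + 1L)
    ref_w <- substr(tx_seq, lo + 1L, hi)
    center <- tpos - lo
    edit_w <- ref_w
    substr(edit_w, center + 1L, center + 1L) <- alt_t
    tibble(transcript_id = tid, ref_window = ref_w, edited_window = edit_w,
           center = center)
  }) |> dplyr::bind_rows()
}

#' Classify miRNA-target regulation changes between reference and edited
#' windows
#'
#' Per miRNA: a hit on the reference window only is an `edited_loss`, on
#' the edited window only an `edited_gain`; a hit on both whose binding
#' energies differ by more than `ddg_threshold` kcal/mol (absolute value)
#' is an `edited_change`; a hit on both otherwise yields no record.
#'
#' @param ref_hits,edited_hits Hit tibbles with `mirna_id`, `score`, `dg`.
#' @param ddg_threshold Energy-change threshold (default 14 kcal/mol).
#' @return Tibble with `mirna_id`, `kind`, `ddg` (`NA` except for
#'   `edited_change`).
#' @export
classify_regulation_change <- function(ref_hits, edited_hits,
                                       ddg_threshold = 14) {
  r <- dplyr::distinct(ref_hits, .data$mirna_id, .keep_all = TRUE)
  e <- dplyr::distinct(edited_hits, .data$mirna_id, .keep_all = TRUE)
  j <- dplyr::full_join(
    dplyr::select(r, "mirna_id", dg_ref = "dg"),
    dplyr::select(e, "mirna_id", dg_edited = "dg"),
    by = "mirna_id")
  j |>
    dplyr::mutate(
      kind = dplyr::case_when(
        is.na(.data$dg_edited) ~ "edited_loss",
        is.na(.data$dg_ref) ~ "edited_gain",
        abs(.data$dg_ref - .data$dg_edited) > ddg_threshold ~ "edited_change",
        TRUE ~ NA_character_),
      ddg = ifelse(.data$kind %in% "edited_change",
                   abs(.data$dg_ref - .data$dg_edited), NA_real_)) |>
    dplyr::filter(!is.na(.data$kind)) |>
    dplyr::select("mirna_id", "kind", "ddg")
}

#' miRNA-regulation consequence flag for a site
#'
#' A site has an miRNA-target regulation consequence iff its edit induces
#' more than `threshold` distinct miRNA-target regulation changes (gains,
#' losses and changes pooled together).
#'
#' @param changes Regulation-change tibble for one site
#'   ([classify_regulation_change()]).
#' @param threshold Strict lower bound (default 10: 11 changes flag, 10
#'   do not).
#' @return Logical flag.
#' @export
call_mirna_consequence <- function(changes, threshold = 10L) {
  nrow(dplyr::distinct(changes, .data$mirna_id, .data$kind)) > threshold
}

#' Score miRNA-target rewiring for 3'UTR editing sites
#'
#' For each annotated 3'UTR site: builds reference and edited windows for
#' all containing transcripts, scores the full miRNA catalog against
#' both, aggregates per miRNA by the best transcript window, classifies
#' regulation changes, and flags sites with more than `threshold` changes
#' as having an miRNA-regulation consequence.
#'
#' @param sites Annotated site tibble ([annotate_sites()]); only rows
#'   with `feature == "utr3"` are evaluated.
#' @param gene_models Gene-model tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param mirnas Named character vector of mature miRNA sequences (DNA
#'   alphabet).
#' @param params [duplex_params()].
#' @param threshold Consequence-count threshold (default 10).
#' @return List with `changes` (per site x miRNA regulation changes) and
#'   `consequence` (per site: `n_changes`, `mirna_consequence`).
#' @export
rewire_sites <- function(sites, gene_models, genome, mirnas,
                         params = duplex_params(), threshold = 10L) {
  utr_sites <- dplyr::filter(sites, .data$feature == "utr3")
  res <- purrr::map(seq_len(nrow(utr_sites)), function(i) {
    site <- utr_sites[i, ]
    wins <- build_windows(site, gene_models, genome)
    if (nrow(wins) == 0) return(NULL)
    hits <- function(col) {
      purrr::map(seq_len(nrow(wins)), function(k) {
        purrr::map(names(mirnas), function(mid) {
          h <- score_duplex(mirnas[[mid]], wins[[col]][[k]], params)
          if (!h$hit) return(NULL)
          dplyr::mutate(h, mirna_id = mid)
        }) |> dplyr::bind_rows()
      }) |>
        dplyr::bind_rows()
    }
    best_hits <- function(col) {
      h <- hits(col)
      if (nrow(h) == 0) {
        return(tibble(mirna_id = character(), score = double(),
                      dg = double()))
      }
      h |>
        dplyr::group_by(.data$mirna_id) |>
        dplyr::arrange(dplyr::desc(.data$score), .data$dg, .by_group = TRUE) |>
        dplyr::slice(1) |>
        dplyr::ungroup()
    }
    ch <- classify_regulation_change(best_hits("ref_window"),
                                     best_hits("edited_window"))
    if (nrow(ch) == 0) return(list(changes = NULL, site_id = site$site_id,
                                   n = 0L))
    list(changes = dplyr::mutate(ch, site_id = site$site_id),
         site_id = site$site_id, n = nrow(dplyr::distinct(ch, .data$mirna_id,
                                                          .data$kind)))
  })
  res <- purrr::compact(res)
  changes <- dplyr::bind_rows(purrr::map(res, "changes"))
  consequence <- tibble(
    site_id = purrr::map_chr(res, "site_id"),
    n_changes = purrr::map_int(res, "n")
  ) |> dplyr::mutate(mirna_consequence = .data$n_changes > threshold)
  list(changes = changes, consequence = consequence)
}
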