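DNA_BASES <- c("A", "C", "G", "T")

#' Normalize chromosome names to UCSC style
#'
#' Adds the `"chr"` prefix when absent so that inputs mixing Ensembl-style
#' (`"1"`) and UCSC-style (`"chr1"`) names join correctly.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector with a `"chr"` prefix on every element.
#' @export
#' @examples
#' normalize_chrom(c("1", "chr2", "X"))
normalize_chrom <- function(chrom) {
  ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom))
}

#' Reverse-complement a DNA string vector
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L & ref %in% DNA_BASES & alt %in% DNA_BASES
}

site_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stopifnot-style check with a readable message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}
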