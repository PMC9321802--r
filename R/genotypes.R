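# Genotype-string conventions shared across the package.
#
# A diploid genotype at a biallelic SNP is written as an unordered allele
# pair with the alleles in alphabetical order: "GT" and "TG" denote the same
# heterozygote and both canonicalize to "GT".

#' Canonicalize genotype strings
#'
#' Genotypes are unordered allele pairs; the canonical spelling sorts the two
#' alleles alphabetically, so `"TG"` becomes `"GT"`. Input is upper-cased and
#' trimmed first.
#'
#' @param genotype character vector of two-allele genotype strings
#'   (e.g. `"GT"`, `"tg"`).
#' @return character vector of canonical genotype strings.
#' @examples
#' normalize_genotype(c("TG", "cc"))
#' @export
normalize_genotype <- function(genotype) {
  vapply(as.character(genotype), function(g) {
    g <- toupper(trimws(g))
    if (!grepl("^[ACGT]{2}$", g)) {
      stop("invalid genotype string '", g,
           "': expected two alleles from A/C/G/T, e.g. 'GT'", call. = FALSE)
    }
    paste(sort(strsplit(g, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' The three genotype classes of a biallelic variant
#'
#' Returns the canonical homozygous-reference, heterozygous and
#' homozygous-alternate genotype strings, in that order.
#'
#' @param ref,alt single-character reference and alternate alleles.
#' @return character vector of length 3.
#' @examples
#' genotype_classes("G", "T")  # "GG" "GT" "TT"
#' @export
genotype_classes <- function(ref, alt) {
  stopifnot(length(ref) == 1, length(alt) == 1)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]$", ref) || !grepl("^[ACGT]$", alt))
    stop("alleles must be single characters from A/C/G/T", call. = FALSE)
  if (ref == alt)
    stop("reference and alternate alleles must differ", call. = FALSE)
  c(paste0(ref, ref),
    normalize_genotype(paste0(ref, alt)),
    paste0(alt, alt))
}

#' Hardy-Weinberg genotype probabilities
#'
#' Expands an alternate-allele frequency q into the genotype-class triple
#' (p^2, 2pq, q^2) with p = 1 - q, renormalized to sum to exactly 1.
#'
#' @param alt_freq alternate-allele frequency in \[0, 1\].
#' @return numeric triple (hom-ref, het, hom-alt) summing to 1.
#' @examples
#' hwe_triple(0.5)  # 0.25 0.50 0.25
#' @export
hwe_triple <- function(alt_freq) {
  if (!is.numeric(alt_freq) || length(alt_freq) != 1 || is.na(alt_freq) ||
      alt_freq < 0 || alt_freq > 1)
    stop("alt_freq must be a single number in [0, 1], got ",
         format(alt_freq), call. = FALSE)
  p <- 1 - alt_freq
  q <- alt_freq
  tri <- c(p * p, 2 * p * q, q * q)
  tri / sum(tri)
}

# Internal: validate a genotype-probability triple, renormalize to sum 1.
check_triple <- function(tri, rs_id = NULL) {
  lbl <- if (is.null(rs_id)) "" else paste0(" for ", rs_id)
  if (!is.numeric(tri) || length(tri) != 3 || anyNA(tri))
    stop("genotype frequencies", lbl, " must be a numeric triple", call. = FALSE)
  if (any(tri < 0) || any(tri > 1))
    stop("genotype frequencies", lbl, " must lie in [0, 1]", call. = FALSE)
  s <- sum(tri)
  if (abs(s - 1) > 1e-6)
    stop("genotype frequencies", lbl, " sum to ", format(s),
         ", not 1", call. = FALSE)
  tri / s
}
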