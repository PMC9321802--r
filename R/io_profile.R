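# Subject-profile readers: key-value CSV and single-sample VCF.

#' Read a subject profile from a key-value CSV
#'
#' Rows are `rs_id,genotype`, plus optional rows `smoking,<yes|no>` and
#' `familiarity,<present|absent>`. Heterozygote allele order is
#' canonicalized; duplicate keys are rejected.
#'
#' @param path path to the profile CSV.
#' @param subject_id identifier for the report (defaults to the file name).
#' @return a `ware_profile`.
#' @export
read_profile_csv <- function(path,
                             subject_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path))
    stop("profile file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         col.names = c("key", "value"))
  tab$key <- trimws(tab$key)
  tab$value <- trimws(tab$value)
  tab <- tab[tab$key != "rs_id", , drop = FALSE]  # tolerate a header row
  if (anyDuplicated(tab$key))
    stop("duplicate rows in profile for: ",
         paste(unique(tab$key[duplicated(tab$key)]), collapse = ", "),
         call. = FALSE)

  is_factor_row <- tab$key %in% c("smoking", "familiarity")
  geno_rows <- tab[!is_factor_row, , drop = FALSE]
  bad <- geno_rows$key[!grepl("^rs[0-9]+$", geno_rows$key)]
  if (length(bad))
    stop("unknown profile keys (not rsIDs or smoking/familiarity): ",
         paste(bad, collapse = ", "), call. = FALSE)

  genotypes <- stats::setNames(geno_rows$value, geno_rows$key)
  getv <- function(key) {
    if (key %in% tab$key) tab$value[tab$key == key] else NA_character_
  }
  subject_profile(genotypes,
                  smoking = getv("smoking"),
                  familiarity = getv("familiarity"),
                  subject_id = subject_id)
}

#' Write a subject profile as a key-value CSV
#'
#' @param profile a `ware_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "ware_profile"))
  lines <- paste(names(profile$genotypes), profile$genotypes, sep = ",")
  if (!is.na(profile$smoking))
    lines <- c(lines, paste0("smoking,", profile$smoking))
  if (!is.na(profile$familiarity))
    lines <- c(lines, paste0("familiarity,", profile$familiarity))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject profile from a VCF
#'
#' Panel variants are located by the VCF `ID` column (rsID matching only; no
#' positional matching across genome builds). Each variant's `GT` field is
#' mapped to a genotype class through the panel's ref/alt alleles. The VCF
#' `REF`/`ALT` must equal the panel alleles — mismatches (including strand
#' flips) are rejected, never silently resolved. Every panel variant must be
#' present with a called genotype.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param panel a `ware_panel` giving the variants to extract.
#' @param sample sample name to read; may be omitted for single-sample VCFs.
#' @param subject_id identifier for the report (defaults to the sample name).
#' @return a `ware_profile` (non-genetic factor levels unset).
#' @export
read_profile_vcf <- function(path, panel, sample = NULL,
                             subject_id = NULL) {
  if (!file.exists(path))
    stop("VCF file not found: ", path, call. = FALSE)
  validate_panel(panel)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample)) {
    if (length(samples) != 1)
      stop("VCF has ", length(samples),
           " samples; specify one with 'sample'", call. = FALSE)
    sample <- samples[1]
  }
  if (!sample %in% samples)
    stop("sample '", sample, "' not found in VCF (has: ",
         paste(samples, collapse = ", "), ")", call. = FALSE)

  missing_rs <- setdiff(panel$variants$rs_id, fix$ID)
  if (length(missing_rs))
    stop("VCF does not contain panel variants: ",
         paste(missing_rs, collapse = ", "),
         " (a genotype is required for every panel variant)", call. = FALSE)

  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  genotypes <- vapply(seq_len(nrow(panel$variants)), function(i) {
    v <- panel$variants[i, ]
    idx <- which(fix$ID == v$rs_id)
    if (length(idx) > 1)
      stop("VCF contains ", v$rs_id, " more than once", call. = FALSE)
    if (!identical(toupper(fix$REF[idx]), v$ref) ||
        !identical(toupper(fix$ALT[idx]), v$alt))
      stop("REF/ALT mismatch for ", v$rs_id, ": VCF has ",
           fix$REF[idx], "/", fix$ALT[idx], ", panel expects ",
           v$ref, "/", v$alt,
           " (strand flips are not resolved automatically)", call. = FALSE)
    gt <- gt_mat[idx, sample]
    alleles <- strsplit(gt %||% ".", "[/|]")[[1]]
    if (is.na(gt) || length(alleles) != 2 || any(!alleles %in% c("0", "1")))
      stop("uncalled or non-diploid genotype for ", v$rs_id,
           " in sample ", sample, ": '", gt %||% "NA", "'", call. = FALSE)
    n_alt <- sum(alleles == "1")
    genotype_classes(v$ref, v$alt)[n_alt + 1]
  }, character(1))

  subject_profile(stats::setNames(genotypes, panel$variants$rs_id),
                  subject_id = subject_id %||% sample)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
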