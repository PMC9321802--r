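# Individual risk: the multiplicative model.
#
# A subject's genetic risk is the product of the normalized odds ratios of
# their genotype at every panel variant; the overall risk further multiplies
# in the odds ratios of the active non-genetic factors (smoking, positive
# family history). Setting both non-genetic factors to their lowest level
# ("no"/"absent") leaves the genetic risk unchanged.

SMOKING_LEVELS <- c("yes", "no")
FAMILIARITY_LEVELS <- c("present", "absent")

#' Construct a subject profile
#'
#' @param genotypes named character vector mapping rs_id to genotype string;
#'   heterozygote allele order is canonicalized.
#' @param smoking `"yes"`, `"no"`, or `NA` (unset).
#' @param familiarity `"present"`, `"absent"`, or `NA` (unset).
#' @param subject_id identifier echoed into reports.
#' @return a `ware_profile` object.
#' @examples
#' subject_profile(c(rs1 = "GT", rs2 = "CC"), smoking = "no",
#'                 familiarity = "absent")
#' @export
subject_profile <- function(genotypes, smoking = NA_character_,
                            familiarity = NA_character_,
                            subject_id = "subject") {
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    stop("genotypes must be a named vector keyed by rs_id", call. = FALSE)
  if (anyDuplicated(names(genotypes)))
    stop("duplicate rs_id in profile: ",
         paste(unique(names(genotypes)[duplicated(names(genotypes))]),
               collapse = ", "), call. = FALSE)
  g <- normalize_genotype(genotypes)
  names(g) <- names(genotypes)
  smoking <- check_level(smoking, SMOKING_LEVELS, "smoking")
  familiarity <- check_level(familiarity, FAMILIARITY_LEVELS, "familiarity")
  structure(list(genotypes = g, smoking = smoking, familiarity = familiarity,
                 subject_id = as.character(subject_id)[1]),
            class = "ware_profile")
}

check_level <- function(x, levels, what) {
  x <- as.character(x)[1]
  if (is.na(x)) return(NA_character_)
  x <- tolower(trimws(x))
  if (!x %in% levels)
    stop(what, " level must be one of ", paste(levels, collapse = "/"),
         " (got '", x, "')", call. = FALSE)
  x
}

#' @export
print.ware_profile <- function(x, ...) {
  cat("<ware_profile> ", x$subject_id, "\n", sep = "")
  cat("  genotypes:  ",
      paste(names(x$genotypes), x$genotypes, sep = "=", collapse = " "),
      "\n", sep = "")
  cat("  smoking: ", ifelse(is.na(x$smoking), "<unset>", x$smoking),
      "  familiarity: ",
      ifelse(is.na(x$familiarity), "<unset>", x$familiarity), "\n", sep = "")
  invisible(x)
}

#' Non-genetic factor odds ratios
#'
#' Odds ratios applied when smoking is `"yes"` and when family history is
#' `"present"`; the lowest levels (`"no"`, `"absent"`) always contribute a
#' factor of 1. There are no packaged defaults: both values must be supplied
#' (typically from a factors-configuration file, see [load_factors()]).
#'
#' @param smoking_or positive odds ratio for active smoking.
#' @param familiarity_or positive odds ratio for positive family history.
#' @return a `ware_factors` object.
#' @export
non_genetic_factors <- function(smoking_or, familiarity_or) {
  for (v in c(smoking_or, familiarity_or)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop("factor odds ratios must be single positive numbers",
           call. = FALSE)
  }
  structure(list(smoking_or = smoking_or, familiarity_or = familiarity_or),
            class = "ware_factors")
}

#' Read a non-genetic factors configuration file
#'
#' A two-column CSV (no header comment required) with rows
#' `smoking,<or>` and `familiarity,<or>`; both rows are mandatory.
#'
#' @param path path to the factors CSV.
#' @return a `ware_factors` object.
#' @export
load_factors <- function(path) {
  if (!file.exists(path))
    stop("factors file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         col.names = c("factor", "or"))
  tab$factor <- tolower(trimws(tab$factor))
  tab <- tab[tab$factor != "factor", , drop = FALSE]  # tolerate a header row
  get_or <- function(name) {
    row <- tab[tab$factor == name, , drop = FALSE]
    if (nrow(row) != 1)
      stop("factors file must contain exactly one '", name, "' row",
           call. = FALSE)
    as.numeric(row$or)
  }
  non_genetic_factors(smoking_or = get_or("smoking"),
                      familiarity_or = get_or("familiarity"))
}

#' Genetic risk of a subject
#'
#' The product over all panel variants of the normalized odds ratio of the
#' subject's genotype class. A genotype is required for every panel variant;
#' no estimate is produced otherwise.
#'
#' @param profile a `ware_profile`.
#' @param panel a `ware_panel`.
#' @return positive scalar genetic risk on the odds-ratio scale.
#' @examples
#' panel <- default_panel()
#' prof <- subject_profile(c(rs1061170 = "CT", rs10490924 = "GT",
#'   rs2227306 = "CC", rs5749482 = "CG", rs8135665 = "CC",
#'   rs8017304 = "AA", rs943080 = "CT", rs13081855 = "GG"))
#' genetic_risk(prof, panel)
#' @export
genetic_risk <- function(profile, panel) {
  stopifnot(inherits(profile, "ware_profile"))
  validate_panel(panel)
  missing_rs <- setdiff(panel$variants$rs_id, names(profile$genotypes))
  if (length(missing_rs))
    stop("cannot compute risk: no genotype for ",
         paste(missing_rs, collapse = ", "),
         " (a genotype is required for every panel variant)", call. = FALSE)
  risk <- 1
  for (i in seq_len(nrow(panel$variants))) {
    rs <- panel$variants$rs_id[i]
    risk <- risk * panel_or(panel, rs, profile$genotypes[[rs]])$or_point
  }
  risk
}

#' Overall risk combining genetic and non-genetic factors
#'
#' Multiplies the previously computed genetic risk by the smoking odds ratio
#' when smoking is `"yes"` and the familiarity odds ratio when family history
#' is `"present"`. The lowest levels contribute 1, so a subject with
#' `smoking = "no"` and `familiarity = "absent"` keeps exactly their genetic
#' risk; users who do not know a factor should set its lowest level.
#'
#' @param genetic positive genetic risk (compute it first with
#'   [genetic_risk()]).
#' @param smoking `"yes"` or `"no"`; must be set.
#' @param familiarity `"present"` or `"absent"`; must be set.
#' @param factors a `ware_factors` object.
#' @return positive scalar overall risk.
#' @export
overall_risk <- function(genetic, smoking, familiarity, factors) {
  if (!is.numeric(genetic) || length(genetic) != 1 || is.na(genetic) ||
      genetic <= 0)
    stop("genetic risk must be a positive number; compute it first with ",
         "genetic_risk()", call. = FALSE)
  stopifnot(inherits(factors, "ware_factors"))
  smoking <- check_level(smoking, SMOKING_LEVELS, "smoking")
  familiarity <- check_level(familiarity, FAMILIARITY_LEVELS, "familiarity")
  if (is.na(smoking) || is.na(familiarity))
    stop("both non-genetic levels must be set before computing the overall ",
         "risk; if a factor is unknown, set its lowest level ",
         "(smoking='no', familiarity='absent')", call. = FALSE)
  genetic *
    (if (smoking == "yes") factors$smoking_or else 1) *
    (if (familiarity == "present") factors$familiarity_or else 1)
}
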