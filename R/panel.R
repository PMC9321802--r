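# The risk panel: variants plus per-genotype normalized odds ratios.
#
# A `ware_panel` is a list with
#   variants   data.frame(rs_id, gene, ref, alt), one row per variant,
#              in panel order
#   ors        data.frame(rs_id, genotype, or_point, ci_low, ci_high),
#              three rows per variant in class order (hom-ref, het, hom-alt)
#   provenance free-text source note
#
# The packaged default panel (`default_panel()`) carries the eight variants
# validated for wet AMD in the Italian population with their normalized ORs
# and 95% confidence intervals.

PANEL_COLUMNS <- c("rs_id", "gene", "ref", "alt",
                   "genotype", "or_point", "ci_low", "ci_high")

new_panel <- function(variants, ors, provenance) {
  structure(list(variants = variants, ors = ors,
                 provenance = as.character(provenance)[1]),
            class = "ware_panel")
}

#' Construct a risk panel from a per-genotype table
#'
#' @param x data.frame with columns `rs_id`, `gene`, `ref`, `alt`,
#'   `genotype`, `or_point`, `ci_low`, `ci_high`; one row per genotype class
#'   (three per variant). Heterozygote spellings are canonicalized
#'   ("TG" becomes "GT").
#' @param provenance free-text source note stored with the panel.
#' @return a `ware_panel` object.
#' @seealso [load_panel()], [default_panel()]
#' @export
risk_panel <- function(x, provenance = "unspecified") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PANEL_COLUMNS, names(x))
  if (length(missing_cols))
    stop("panel table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x <- x[PANEL_COLUMNS]
  x$rs_id <- as.character(x$rs_id)
  x$gene <- as.character(x$gene)
  x$ref <- toupper(as.character(x$ref))
  x$alt <- toupper(as.character(x$alt))
  x$genotype <- normalize_genotype(x$genotype)
  for (col in c("or_point", "ci_low", "ci_high")) x[[col]] <- as.numeric(x[[col]])

  variants <- unique(x[c("rs_id", "gene", "ref", "alt")])
  if (anyDuplicated(variants$rs_id))
    stop("duplicate rs_id in panel: ",
         paste(unique(variants$rs_id[duplicated(variants$rs_id)]),
               collapse = ", "), call. = FALSE)
  rownames(variants) <- NULL

  # reorder each variant's rows into class order (hom-ref, het, hom-alt)
  ors_list <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    classes <- genotype_classes(v$ref, v$alt)
    rows <- x[x$rs_id == v$rs_id, ]
    if (nrow(rows) != 3 || !setequal(rows$genotype, classes))
      stop("variant ", v$rs_id, " must have exactly the 3 genotype classes ",
           paste(classes, collapse = ", "), "; found ",
           paste(sort(rows$genotype), collapse = ", "), call. = FALSE)
    rows[match(classes, rows$genotype), c("rs_id", "genotype",
                                          "or_point", "ci_low", "ci_high")]
  })
  ors <- do.call(rbind, c(ors_list, list(make.row.names = FALSE)))
  if (is.null(ors))
    ors <- data.frame(rs_id = character(), genotype = character(),
                      or_point = numeric(), ci_low = numeric(),
                      ci_high = numeric())

  panel <- new_panel(variants, ors, provenance)
  validate_panel(panel)
  panel
}

#' Validate a risk panel
#'
#' Checks the structural invariants: well-formed rsIDs, distinct alleles,
#' exactly three genotype classes per variant, positive odds ratios, and
#' confidence intervals that bracket the point value.
#'
#' @param panel a `ware_panel`.
#' @return the panel, invisibly, if valid; otherwise an error naming the
#'   offending variant or genotype.
#' @export
validate_panel <- function(panel) {
  if (!inherits(panel, "ware_panel")) stop("not a ware_panel", call. = FALSE)
  v <- panel$variants
  bad_rs <- v$rs_id[!grepl("^rs[0-9]+$", v$rs_id)]
  if (length(bad_rs))
    stop("malformed rs_id: ", paste(bad_rs, collapse = ", "), call. = FALSE)
  same <- v$rs_id[v$ref == v$alt]
  if (length(same))
    stop("ref and alt alleles identical for: ",
         paste(same, collapse = ", "), call. = FALSE)
  o <- panel$ors
  for (i in seq_len(nrow(v))) {
    rows <- o[o$rs_id == v$rs_id[i], ]
    classes <- genotype_classes(v$ref[i], v$alt[i])
    if (nrow(rows) != 3 || !identical(rows$genotype, classes))
      stop("variant ", v$rs_id[i],
           " does not have its 3 genotype classes in canonical order",
           call. = FALSE)
    for (j in seq_len(3)) {
      r <- rows[j, ]
      if (is.na(r$or_point) || r$or_point <= 0)
        stop("non-positive OR for ", r$rs_id, " ", r$genotype, call. = FALSE)
      if (is.na(r$ci_low) || is.na(r$ci_high) ||
          r$ci_low <= 0 || r$ci_low > r$or_point || r$ci_high < r$or_point)
        stop("confidence interval for ", r$rs_id, " ", r$genotype,
             " must satisfy 0 < ci_low <= or_point <= ci_high", call. = FALSE)
    }
  }
  invisible(panel)
}

#' Read a risk panel from CSV or JSON
#'
#' The CSV format has columns `rs_id,gene,ref,alt,genotype,or_point,ci_low,
#' ci_high`, one row per genotype class, preceded by optional `#` comment
#' lines; a `# source=<label>` comment sets the provenance. A `.json` file
#' holding `{"provenance": ..., "entries": [<row objects>]}` (or a bare array
#' of row objects) is accepted as the equivalent document.
#'
#' @param path path to the panel file.
#' @return a validated `ware_panel`.
#' @examples
#' panel <- default_panel()
#' panel_or(panel, "rs10490924", "TT")$or_point  # 8.3
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  if (tolower(tools::file_ext(path)) == "json") {
    doc <- jsonlite::fromJSON(path)
    if (is.data.frame(doc)) {
      tab <- doc
      provenance <- "unspecified"
    } else {
      tab <- as.data.frame(doc$entries, stringsAsFactors = FALSE)
      provenance <- if (!is.null(doc$provenance)) doc$provenance else "unspecified"
    }
    return(risk_panel(tab, provenance = provenance))
  }
  provenance <- read_source_comment(path, default = "unspecified")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  risk_panel(tab, provenance = provenance)
}

#' Write a risk panel in canonical CSV form
#'
#' The canonical form has a single `# source=` comment line, the fixed column
#' order, variants in panel order and genotype classes in (hom-ref, het,
#' hom-alt) order. `write_panel(load_panel(p), p2)` reproduces a canonical
#' file byte for byte.
#'
#' @param panel a `ware_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  o <- merge(panel$ors, panel$variants, by = "rs_id", sort = FALSE)
  o <- o[PANEL_COLUMNS]
  lines <- c(
    paste0("# source=", panel$provenance),
    paste(PANEL_COLUMNS, collapse = ","),
    vapply(seq_len(nrow(o)), function(i) {
      paste(c(o$rs_id[i], o$gene[i], o$ref[i], o$alt[i], o$genotype[i],
              format_num(o$or_point[i]), format_num(o$ci_low[i]),
              format_num(o$ci_high[i])), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

# Canonical number formatting: plain decimal, up to 15 significant digits.
format_num <- function(x) {
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

# First "# source=<label>" comment line of a file, if any.
read_source_comment <- function(path, default = NULL) {
  head_lines <- readLines(path, n = 20L, warn = FALSE)
  src <- grep("^#\\s*source=", head_lines, value = TRUE)
  if (length(src)) sub("^#\\s*source=\\s*", "", src[1]) else default
}

#' The packaged Italian wet-AMD risk panel
#'
#' Loads the packaged reference panel `italian_wet_amd_v1`: eight variants
#' (rs1061170 *CFH*, rs10490924 *ARMS2*, rs2227306 *IL8*, rs5749482 *TIMP3*,
#' rs8135665 *SLC16A8*, rs8017304 *RAD51B*, rs943080 *VEGFA*, rs13081855
#' *COL8A1*) with population-normalized per-genotype odds ratios and 95%
#' confidence intervals.
#'
#' @return a `ware_panel` with 8 variants and 24 genotype entries.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "italian_wet_amd_v1.csv",
                         package = "wareamd", mustWork = TRUE))
}

#' Look up the odds-ratio entry for one genotype
#'
#' @param panel a `ware_panel`.
#' @param rs_id variant identifier.
#' @param genotype genotype string (any allele order).
#' @return a one-row data.frame with `or_point`, `ci_low`, `ci_high`.
#' @export
panel_or <- function(panel, rs_id, genotype) {
  validate_panel(panel)
  if (!rs_id %in% panel$variants$rs_id)
    stop("variant ", rs_id, " is not in the panel", call. = FALSE)
  g <- normalize_genotype(genotype)
  row <- panel$ors[panel$ors$rs_id == rs_id & panel$ors$genotype == g, ]
  if (nrow(row) != 1)
    stop("genotype ", g, " is not a class of ", rs_id, " (expected one of ",
         paste(panel$ors$genotype[panel$ors$rs_id == rs_id], collapse = ", "),
         ")", call. = FALSE)
  row[c("or_point", "ci_low", "ci_high")]
}

#' @export
print.ware_panel <- function(x, ...) {
  cat("<ware_panel> ", nrow(x$variants), " variants (",
      x$provenance, ")\n", sep = "")
  print(merge(x$ors, x$variants, by = "rs_id", sort = FALSE)[PANEL_COLUMNS],
        row.names = FALSE)
  invisible(x)
}
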