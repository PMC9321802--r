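# Per-variant genotype-class frequencies.
#
# A `ware_freqs` is a data.frame with columns rs_id, f_refref, f_het,
# f_altalt (each row a probability triple over the variant's genotype
# classes) and attributes `source` (mandatory provenance label). Frequencies
# may be supplied directly as triples or as a single alternate-allele
# frequency, which is expanded under Hardy-Weinberg equilibrium.

#' Construct a genotype-frequency table
#'
#' @param x data.frame with column `rs_id` and either `alt_freq` (expanded
#'   via Hardy-Weinberg into (p^2, 2pq, q^2)) or the explicit triple columns
#'   `f_refref`, `f_het`, `f_altalt`. When both are present, the explicit
#'   triple takes precedence row by row (an `NA` triple falls back to
#'   `alt_freq`).
#' @param source mandatory free-text provenance label (e.g. the database and
#'   superpopulation the frequencies came from).
#' @return a `ware_freqs` data.frame with one normalized triple per variant.
#' @examples
#' genotype_frequencies(data.frame(rs_id = "rs1", alt_freq = 0.5),
#'                      source = "example")
#' @export
genotype_frequencies <- function(x, source) {
  if (missing(source) || is.null(source) || !nzchar(source))
    stop("a frequency table requires a 'source' provenance label",
         call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"rs_id" %in% names(x))
    stop("frequency table lacks an rs_id column", call. = FALSE)
  has_triple <- all(c("f_refref", "f_het", "f_altalt") %in% names(x))
  has_allele <- "alt_freq" %in% names(x)
  if (!has_triple && !has_allele)
    stop("frequency table needs either alt_freq or f_refref/f_het/f_altalt",
         call. = FALSE)
  if (anyDuplicated(x$rs_id))
    stop("duplicate rs_id in frequency table: ",
         paste(unique(x$rs_id[duplicated(x$rs_id)]), collapse = ", "),
         call. = FALSE)

  triples <- t(vapply(seq_len(nrow(x)), function(i) {
    if (has_triple && !anyNA(unlist(x[i, c("f_refref", "f_het", "f_altalt")]))) {
      check_triple(as.numeric(x[i, c("f_refref", "f_het", "f_altalt")]),
                   rs_id = x$rs_id[i])
    } else if (has_allele && !is.na(x$alt_freq[i])) {
      q <- as.numeric(x$alt_freq[i])
      if (is.na(q) || q < 0 || q > 1)
        stop("alt_freq for ", x$rs_id[i], " must lie in [0, 1]",
             call. = FALSE)
      hwe_triple(q)
    } else {
      stop("no frequency given for ", x$rs_id[i], call. = FALSE)
    }
  }, numeric(3)))

  out <- data.frame(rs_id = as.character(x$rs_id),
                    f_refref = triples[, 1],
                    f_het = triples[, 2],
                    f_altalt = triples[, 3],
                    stringsAsFactors = FALSE)
  structure(out, source = as.character(source)[1],
            class = c("ware_freqs", "data.frame"))
}

#' Read a genotype-frequency file
#'
#' The file is a CSV with column `rs_id` and either `alt_freq` or the triple
#' `f_refref,f_het,f_altalt`, preceded by a mandatory comment line
#' `# source=<label>`. Allele frequencies are expanded under Hardy-Weinberg
#' equilibrium; triples are normalized to sum to 1.
#'
#' @param path path to the frequency CSV.
#' @param panel optional `ware_panel`; when given, the file must cover every
#'   panel variant and the table is returned in panel order.
#' @return a `ware_freqs` table.
#' @export
load_frequencies <- function(path, panel = NULL) {
  if (!file.exists(path))
    stop("frequency file not found: ", path, call. = FALSE)
  src <- read_source_comment(path)
  if (is.null(src))
    stop("frequency file ", path,
         " lacks the mandatory '# source=<label>' comment line",
         call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  freqs <- genotype_frequencies(tab, source = src)
  if (!is.null(panel)) freqs <- align_frequencies(freqs, panel)
  freqs
}

# Check coverage against a panel and return rows in panel order.
align_frequencies <- function(freqs, panel) {
  missing_rs <- setdiff(panel$variants$rs_id, freqs$rs_id)
  if (length(missing_rs))
    stop("frequency table does not cover panel variants: ",
         paste(missing_rs, collapse = ", "), call. = FALSE)
  out <- freqs[match(panel$variants$rs_id, freqs$rs_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, source = attr(freqs, "source"),
            class = c("ware_freqs", "data.frame"))
}

#' Write a genotype-frequency table
#'
#' Writes the explicit-triple CSV form with its `# source=` provenance line.
#'
#' @param freqs a `ware_freqs` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequencies <- function(freqs, path) {
  lines <- c(
    paste0("# source=", attr(freqs, "source")),
    "rs_id,f_refref,f_het,f_altalt",
    vapply(seq_len(nrow(freqs)), function(i) {
      paste(c(freqs$rs_id[i], format_num(freqs$f_refref[i]),
              format_num(freqs$f_het[i]), format_num(freqs$f_altalt[i])),
            collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

# Internal: genotype-probability triple for one variant as a plain vector.
freq_triple <- function(freqs, rs_id) {
  row <- freqs[freqs$rs_id == rs_id, , drop = FALSE]
  if (nrow(row) != 1)
    stop("no frequency entry for ", rs_id, call. = FALSE)
  as.numeric(row[1, c("f_refref", "f_het", "f_altalt")])
}
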