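# Odds-ratio normalization to the population mean.
#
# Raw per-genotype odds ratios are anchored to the lowest-risk genotype
# (OR = 1) in the source association study. For risk profiling, each
# variant's ORs are instead rescaled so that the frequency-weighted average
# risk in the general population equals 1: the mean population risk
# m = sum_g f_g * OR_g is computed and every OR (and its confidence bounds)
# is divided by m. A normalized OR is then directly interpretable as risk
# relative to the population average, and the product of normalized ORs over
# independent variants keeps a population mean of 1.

#' Normalize one variant's odds ratios to its population mean
#'
#' @param raw numeric vector of 3 positive raw odds ratios, in genotype-class
#'   order (hom-ref, het, hom-alt).
#' @param freqs genotype-probability triple for the same classes (sums to 1).
#' @return a list with `mean_population_risk` (`sum(freqs * raw)`) and
#'   `normalized` (`raw / mean_population_risk`), whose expectation under
#'   `freqs` is exactly 1.
#' @examples
#' normalize_ors(c(1, 2, 4), c(0.25, 0.5, 0.25))
#' @export
normalize_ors <- function(raw, freqs) {
  if (!is.numeric(raw) || length(raw) != 3 || anyNA(raw))
    stop("raw must be a numeric triple of odds ratios", call. = FALSE)
  if (any(raw <= 0))
    stop("raw odds ratios must be positive", call. = FALSE)
  freqs <- check_triple(freqs)
  m <- sum(freqs * raw)
  list(mean_population_risk = m, normalized = raw / m)
}

#' Normalize a whole panel of raw odds ratios
#'
#' Applies [normalize_ors()] per variant; confidence-interval bounds are
#' divided by the same per-variant population mean as the point value.
#'
#' @param raw_panel a `ware_panel` whose `or_point`/`ci_low`/`ci_high`
#'   columns hold raw (study-anchored) odds ratios.
#' @param freqs a `ware_freqs` table covering exactly the panel's variants.
#' @return a `ware_panel` with normalized odds ratios; its provenance is the
#'   raw panel's provenance tagged with the frequency source.
#' @export
normalize_panel <- function(raw_panel, freqs) {
  validate_panel(raw_panel)
  panel_rs <- raw_panel$variants$rs_id
  if (length(panel_rs) == 0) return(raw_panel)
  extra <- setdiff(freqs$rs_id, panel_rs)
  missing_rs <- setdiff(panel_rs, freqs$rs_id)
  if (length(extra) || length(missing_rs))
    stop("frequency table and panel cover different variants",
         if (length(missing_rs)) paste0("; missing: ",
                                        paste(missing_rs, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)

  ors <- raw_panel$ors
  for (rs in panel_rs) {
    idx <- which(ors$rs_id == rs)
    res <- normalize_ors(ors$or_point[idx], freq_triple(freqs, rs))
    m <- res$mean_population_risk
    ors$or_point[idx] <- res$normalized
    ors$ci_low[idx] <- ors$ci_low[idx] / m
    ors$ci_high[idx] <- ors$ci_high[idx] / m
  }
  out <- new_panel(raw_panel$variants, ors,
                   paste0(raw_panel$provenance, " normalized to ",
                          attr(freqs, "source")))
  validate_panel(out)
  out
}
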