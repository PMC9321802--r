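# Exact risk distributions over genotype combinations.
#
# Under linkage equilibrium the genotype classes of distinct variants are
# independent, so the population distribution of the multiplicative risk is
# obtained exactly by enumerating all 3^k genotype combinations: each
# combination's risk is the product of its normalized ORs and its weight the
# product of its genotype frequencies. The distribution among cases is the
# risk-tilted population distribution, w_case ∝ w_pop * risk — the standard
# enrichment identity when the normalized OR is read as a relative risk.

#' Construct a discrete risk distribution
#'
#' @param support positive risk values.
#' @param weights matching probabilities; must sum to 1 (within 1e-9) after
#'   dropping zero-weight atoms. Equal support values are merged with summed
#'   weights and the support is sorted.
#' @param kind `"population"` or `"case"`.
#' @return a `risk_distribution` data.frame with columns `risk`, `weight`.
#' @export
risk_distribution <- function(support, weights,
                              kind = c("population", "case")) {
  kind <- match.arg(kind)
  if (length(support) != length(weights) || length(support) == 0)
    stop("support and weights must be non-empty and of equal length",
         call. = FALSE)
  if (any(!is.finite(support)) || any(support <= 0))
    stop("risk support values must be positive and finite", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be non-negative", call. = FALSE)
  keep <- weights > 0
  support <- support[keep]; weights <- weights[keep]
  s <- sum(weights)
  if (abs(s - 1) > 1e-9)
    stop("weights sum to ", format(s), ", not 1", call. = FALSE)
  o <- order(support)
  support <- support[o]; weights <- weights[o]
  grp <- cumsum(c(TRUE, diff(support) != 0))
  merged_w <- as.numeric(rowsum(weights, grp))
  structure(data.frame(risk = support[!duplicated(grp)], weight = merged_w),
            kind = kind, class = c("risk_distribution", "data.frame"))
}

#' Exact population risk distribution of a panel
#'
#' Enumerates every genotype combination of the panel (at most 3^k atoms for
#' k variants; zero-frequency classes are dropped), with risks as products of
#' normalized odds ratios and weights as products of genotype frequencies.
#' For a panel produced by [normalize_panel()] with the same frequencies, the
#' mean of this distribution is 1.
#'
#' @param panel a `ware_panel`.
#' @param freqs a `ware_freqs` table covering the panel.
#' @return a `risk_distribution` of kind `"population"`.
#' @export
population_distribution <- function(panel, freqs) {
  validate_panel(panel)
  freqs <- align_frequencies(freqs, panel)
  support <- 1
  weight <- 1
  for (i in seq_len(nrow(panel$variants))) {
    rs <- panel$variants$rs_id[i]
    ors <- panel$ors$or_point[panel$ors$rs_id == rs]
    tri <- freq_triple(freqs, rs)
    keep <- tri > 0
    support <- as.vector(outer(support, ors[keep]))
    weight <- as.vector(outer(weight, tri[keep]))
  }
  risk_distribution(support, weight, kind = "population")
}

#' Case risk distribution by risk tilting
#'
#' Reweights a population distribution by relative risk:
#' `w_case_i = w_pop_i * r_i / sum_j(w_pop_j * r_j)`. When the population
#' distribution has mean exactly 1 the normalizing constant is 1.
#'
#' @param pop a population-kind `risk_distribution`.
#' @return a `risk_distribution` of kind `"case"`.
#' @export
case_distribution <- function(pop) {
  stopifnot(inherits(pop, "risk_distribution"))
  if (!identical(attr(pop, "kind"), "population"))
    stop("case_distribution() expects a population-kind distribution",
         call. = FALSE)
  tilted <- pop$weight * pop$risk
  risk_distribution(pop$risk, tilted / sum(tilted), kind = "case")
}

#' Mean of a discrete risk distribution
#'
#' @param dist a `risk_distribution`.
#' @return the probability-weighted mean risk.
#' @export
distribution_mean <- function(dist) {
  stopifnot(inherits(dist, "risk_distribution"))
  sum(dist$risk * dist$weight)
}

#' Equal-risk window fractions
#'
#' Splits the distribution's mass around a subject's risk r into the fraction
#' with lower risk (strictly below r - h), the fraction with equal risk
#' (within the closed window r ± h) and the fraction with greater risk
#' (strictly above r + h). The default half-width is 0.15 on the odds-ratio
#' scale; these are the three pie-chart slices of the risk report (green,
#' grey, red).
#'
#' @param dist a `risk_distribution`.
#' @param risk the subject's risk.
#' @param half_width positive half-width h of the window (default 0.15).
#' @return a `ware_window` list with `lower`, `equal`, `greater`,
#'   `half_width`; the three fractions partition the total mass.
#' @export
window_fractions <- function(dist, risk, half_width = 0.15) {
  stopifnot(inherits(dist, "risk_distribution"))
  if (!is.numeric(risk) || length(risk) != 1 || !is.finite(risk))
    stop("risk must be a single finite number", call. = FALSE)
  if (!is.numeric(half_width) || length(half_width) != 1 || half_width <= 0)
    stop("half_width must be positive", call. = FALSE)
  lo <- risk - half_width
  hi <- risk + half_width
  structure(list(
    lower = sum(dist$weight[dist$risk < lo]),
    equal = sum(dist$weight[dist$risk >= lo & dist$risk <= hi]),
    greater = sum(dist$weight[dist$risk > hi]),
    half_width = half_width
  ), class = "ware_window")
}

#' @export
print.ware_window <- function(x, ...) {
  cat(sprintf(
    "<ware_window> +/-%.2f: lower %.3f | equal %.3f | greater %.3f\n",
    x$half_width, x$lower, x$equal, x$greater))
  invisible(x)
}

#' Percentile of a risk in a distribution
#'
#' The right-closed cumulative distribution function: the probability mass on
#' support values less than or equal to `risk`.
#'
#' @param dist a `risk_distribution`.
#' @param risk the subject's risk.
#' @return a probability in \[0, 1\].
#' @export
risk_percentile <- function(dist, risk) {
  stopifnot(inherits(dist, "risk_distribution"))
  sum(dist$weight[dist$risk <= risk])
}

#' Risk-zone boundaries
#'
#' The packaged defaults mark the low-risk zone at OR 0.7 and the high-risk
#' zone at OR 2.0, the boundaries drawn on the risk-distribution plots to
#' avoid over/under-interpretation of the estimate.
#'
#' @param low_boundary upper edge of the low-risk zone (default 0.7).
#' @param high_boundary lower edge of the high-risk zone (default 2.0).
#' @return a `ware_zones` list.
#' @export
zone_config <- function(low_boundary = 0.7, high_boundary = 2.0) {
  if (!is.numeric(low_boundary) || !is.numeric(high_boundary) ||
      low_boundary <= 0 || high_boundary <= low_boundary)
    stop("zone boundaries must satisfy 0 < low_boundary < high_boundary",
         call. = FALSE)
  structure(list(low_boundary = low_boundary, high_boundary = high_boundary),
            class = "ware_zones")
}

#' Classify a risk into a zone
#'
#' Boundaries are inclusive toward the outer zones: a risk exactly at the low
#' boundary is `"low"`, exactly at the high boundary `"high"`.
#'
#' @param risk positive risk value.
#' @param zones a `ware_zones` configuration (defaults 0.7 / 2.0).
#' @return `"low"`, `"intermediate"` or `"high"`.
#' @export
classify_zone <- function(risk, zones = zone_config()) {
  if (!is.numeric(risk) || length(risk) != 1 || is.na(risk) || risk <= 0)
    stop("risk must be a single positive number", call. = FALSE)
  stopifnot(inherits(zones, "ware_zones"))
  if (risk <= zones$low_boundary) "low"
  else if (risk >= zones$high_boundary) "high"
  else "intermediate"
}

#' Monte-Carlo sample of genetic risks
#'
#' Draws `n` independent subjects (genotypes sampled per variant from the
#' frequency table) and returns their genetic risks. This is the sampling
#' counterpart of the exact enumeration in [population_distribution()] and is
#' reproducible under a fixed seed; the caller's random-number state is left
#' untouched.
#'
#' @param panel a `ware_panel`.
#' @param freqs a `ware_freqs` table covering the panel.
#' @param n number of subjects to draw.
#' @param seed integer seed.
#' @return numeric vector of `n` risks.
#' @export
sample_risks <- function(panel, freqs, n, seed) {
  validate_panel(panel)
  freqs <- align_frequencies(freqs, panel)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  with_preserved_seed(seed, {
    risk <- rep(1, n)
    for (i in seq_len(nrow(panel$variants))) {
      rs <- panel$variants$rs_id[i]
      ors <- panel$ors$or_point[panel$ors$rs_id == rs]
      idx <- sample.int(3L, n, replace = TRUE, prob = freq_triple(freqs, rs))
      risk <- risk * ors[idx]
    }
    risk
  })
}

# Run expr under set.seed(seed), restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Export a risk distribution as CSV
#'
#' Columns `risk,weight,kind`; several distributions can be concatenated by
#' appending files with the same header.
#'
#' @param dist a `risk_distribution`.
#' @param path output path.
#' @param append append rows without a header (for writing population and
#'   case distributions to one file).
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path, append = FALSE) {
  stopifnot(inherits(dist, "risk_distribution"))
  tab <- data.frame(risk = dist$risk, weight = dist$weight,
                    kind = attr(dist, "kind"))
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat("<risk_distribution> kind=", attr(x, "kind"), ", ", nrow(x),
      " atoms, mean ", format(distribution_mean(x), digits = 6), "\n",
      sep = "")
  invisible(x)
}
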