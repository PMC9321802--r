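# Seeded synthetic generators: random raw panels, frequencies and cohorts.
#
# These make every module testable without external data. Raw per-genotype
# odds ratios follow a log-additive allelic model (heterozygote OR drawn
# uniformly, homozygote-alternate OR its square, reference OR 1), the
# dominant convention for risk variants; alternate-allele frequencies are
# drawn uniformly and expanded under Hardy-Weinberg equilibrium.

#' Specification for a synthetic raw panel
#'
#' @param n_variants number of variants (>= 1).
#' @param allele_freq_range interval in (0, 1) from which alternate-allele
#'   frequencies are drawn uniformly.
#' @param raw_or_range positive interval from which heterozygote raw odds
#'   ratios are drawn uniformly.
#' @param seed integer seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_variants, allele_freq_range = c(0.05, 0.95),
                         raw_or_range = c(1, 3), seed = 1L) {
  stopifnot(n_variants >= 1,
            length(allele_freq_range) == 2,
            allele_freq_range[1] > 0, allele_freq_range[2] < 1,
            allele_freq_range[1] <= allele_freq_range[2],
            length(raw_or_range) == 2, raw_or_range[1] > 0,
            raw_or_range[1] <= raw_or_range[2])
  structure(list(n_variants = as.integer(n_variants),
                 allele_freq_range = allele_freq_range,
                 raw_or_range = raw_or_range,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a random raw panel with matching frequencies
#'
#' @param spec a [fixture_spec()].
#' @return a list with `panel` (a `ware_panel` of raw odds ratios, synthetic
#'   confidence bounds at 0.8x / 1.25x the point value) and `freqs` (a
#'   `ware_freqs` table). Reproducible under the spec's seed.
#' @export
random_raw_panel <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_seed(spec$seed, {
    k <- spec$n_variants
    rs_ids <- paste0("rs", 900000000 + sample.int(99999999, k))
    alleles <- t(vapply(seq_len(k),
                        function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))
    het_or <- stats::runif(k, spec$raw_or_range[1], spec$raw_or_range[2])
    alt_freq <- stats::runif(k, spec$allele_freq_range[1],
                             spec$allele_freq_range[2])

    rows <- do.call(rbind, lapply(seq_len(k), function(i) {
      ors <- c(1, het_or[i], het_or[i]^2)  # log-additive allelic model
      data.frame(rs_id = rs_ids[i], gene = paste0("GENE", i),
                 ref = alleles[i, 1], alt = alleles[i, 2],
                 genotype = genotype_classes(alleles[i, 1], alleles[i, 2]),
                 or_point = ors, ci_low = ors * 0.8, ci_high = ors * 1.25,
                 stringsAsFactors = FALSE)
    }))
    panel <- risk_panel(rows, provenance = sprintf(
      "synthetic raw panel (%d variants, seed %d)", k, spec$seed))
    freqs <- genotype_frequencies(
      data.frame(rs_id = rs_ids, alt_freq = alt_freq,
                 stringsAsFactors = FALSE),
      source = sprintf("synthetic HWE frequencies (seed %d)", spec$seed))
    list(panel = panel, freqs = freqs)
  })
}

#' Draw a random cohort of subject profiles
#'
#' Genotypes are sampled per variant from the frequency table; smoking and
#' familiarity levels are Bernoulli(0.5).
#'
#' @param panel a `ware_panel`.
#' @param freqs a `ware_freqs` table covering the panel.
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @return list of `n` `ware_profile` objects.
#' @export
random_cohort <- function(panel, freqs, n, seed = 1L) {
  validate_panel(panel)
  freqs <- align_frequencies(freqs, panel)
  stopifnot(n >= 1)
  n <- as.integer(n)
  with_preserved_seed(seed, {
    k <- nrow(panel$variants)
    class_mat <- vapply(seq_len(k), function(i) {
      v <- panel$variants[i, ]
      classes <- genotype_classes(v$ref, v$alt)
      classes[sample.int(3L, n, replace = TRUE,
                         prob = freq_triple(freqs, v$rs_id))]
    }, character(n))
    class_mat <- matrix(class_mat, nrow = n)
    smoking <- sample(SMOKING_LEVELS, n, replace = TRUE)
    familiarity <- sample(FAMILIARITY_LEVELS, n, replace = TRUE)
    lapply(seq_len(n), function(j) {
      subject_profile(
        stats::setNames(class_mat[j, ], panel$variants$rs_id),
        smoking = smoking[j], familiarity = familiarity[j],
        subject_id = sprintf("synthetic_subject_%04d", j))
    })
  })
}
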