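# Shared fixture builders. Everything is constructed in code; no binary data.

# Frozen reference values for the packaged Italian wet-AMD panel: per variant,
# the ref/alt alleles and the (hom-ref, het, hom-alt) normalized ORs with 95%
# CI bounds. Used to check that loading the packaged file reproduces the
# published panel exactly.
published_panel_reference <- function() {
  entry <- function(rs, gene, ref, alt, g, or, lo, hi) {
    data.frame(rs_id = rs, gene = gene, ref = ref, alt = alt, genotype = g,
               or_point = or, ci_low = lo, ci_high = hi,
               stringsAsFactors = FALSE)
  }
  rbind(
    entry("rs1061170", "CFH", "T", "C", "TT", 0.19, 0.14, 0.25),
    entry("rs1061170", "CFH", "T", "C", "CT", 2.19, 1.76, 2.72),
    entry("rs1061170", "CFH", "T", "C", "CC", 5.16, 3.90, 6.82),
    entry("rs10490924", "ARMS2", "G", "T", "GG", 0.12, 0.08, 0.17),
    entry("rs10490924", "ARMS2", "G", "T", "GT", 2.38, 1.95, 2.90),
    entry("rs10490924", "ARMS2", "G", "T", "TT", 8.30, 5.73, 12.04),
    entry("rs2227306", "IL8", "C", "T", "CC", 0.53, 0.39, 0.72),
    entry("rs2227306", "IL8", "C", "T", "CT", 1.32, 1.08, 1.59),
    entry("rs2227306", "IL8", "C", "T", "TT", 1.87, 1.38, 2.53),
    entry("rs5749482", "TIMP3", "C", "G", "CC", 0.63, 0.31, 1.29),
    entry("rs5749482", "TIMP3", "C", "G", "CG", 1.00, 0.45, 1.91),
    entry("rs5749482", "TIMP3", "C", "G", "GG", 1.56, 0.77, 3.16),
    entry("rs8135665", "SLC16A8", "C", "T", "CC", 0.44, 0.28, 0.69),
    entry("rs8135665", "SLC16A8", "C", "T", "CT", 1.59, 1.30, 1.95),
    entry("rs8135665", "SLC16A8", "C", "T", "TT", 2.25, 1.44, 3.51),
    entry("rs8017304", "RAD51B", "A", "G", "AA", 0.69, 0.52, 0.91),
    entry("rs8017304", "RAD51B", "A", "G", "AG", 1.15, 0.94, 1.40),
    entry("rs8017304", "RAD51B", "A", "G", "GG", 1.44, 1.10, 1.88),
    entry("rs943080", "VEGFA", "C", "T", "CC", 0.59, 0.45, 0.77),
    entry("rs943080", "VEGFA", "C", "T", "CT", 1.23, 0.97, 1.55),
    entry("rs943080", "VEGFA", "C", "T", "TT", 1.69, 1.29, 2.19),
    entry("rs13081855", "COL8A1", "G", "T", "GG", 0.16, 0.04, 0.55),
    entry("rs13081855", "COL8A1", "G", "T", "GT", 1.85, 1.43, 2.39),
    entry("rs13081855", "COL8A1", "G", "T", "TT", 6.19, 1.78, 21.49)
  )
}

# Build a panel from a compact per-variant description:
#   list(list(rs, gene, ref, alt, ors = c(hom_ref, het, hom_alt)), ...)
# Synthetic CI bounds bracket the point value.
make_panel <- function(spec, provenance = "test panel") {
  rows <- do.call(rbind, lapply(spec, function(v) {
    data.frame(rs_id = v$rs, gene = v$gene, ref = v$ref, alt = v$alt,
               genotype = genotype_classes(v$ref, v$alt),
               or_point = v$ors, ci_low = v$ors * 0.8,
               ci_high = v$ors * 1.25, stringsAsFactors = FALSE)
  }))
  risk_panel(rows, provenance = provenance)
}

# Two variants with the packaged heterozygote ORs, for product checks.
two_variant_panel <- function() {
  make_panel(list(
    list(rs = "rs10490924", gene = "ARMS2", ref = "G", alt = "T",
         ors = c(0.12, 2.38, 8.3)),
    list(rs = "rs1061170", gene = "CFH", ref = "T", alt = "C",
         ors = c(0.19, 2.19, 5.16))
  ))
}

# Two-variant mean-1 fixture whose population distribution has exactly four
# equal-weight atoms (0.4, 0.6, 1.2, 1.8): per-variant ORs (0.5, 1.5, *) and
# (0.8, 1.2, *) with genotype frequencies (0.5, 0.5, 0).
four_atom_fixture <- function() {
  panel <- make_panel(list(
    list(rs = "rs101", gene = "GENEA", ref = "G", alt = "T",
         ors = c(0.5, 1.5, 4.5)),
    list(rs = "rs102", gene = "GENEB", ref = "C", alt = "T",
         ors = c(0.8, 1.2, 1.8))
  ))
  freqs <- genotype_frequencies(
    data.frame(rs_id = c("rs101", "rs102"),
               f_refref = 0.5, f_het = 0.5, f_altalt = 0),
    source = "four-atom fixture")
  list(panel = panel, freqs = freqs,
       support = c(0.4, 0.6, 1.2, 1.8), weights = rep(0.25, 4))
}

# Uniform genotype frequencies for every variant of a panel.
uniform_freqs <- function(panel, source = "uniform test frequencies") {
  genotype_frequencies(
    data.frame(rs_id = panel$variants$rs_id,
               f_refref = 1 / 3, f_het = 1 / 3, f_altalt = 1 / 3),
    source = source)
}

# A genotype profile covering a panel, by per-variant class index (1 = hom
# ref, 2 = het, 3 = hom alt), recycled over variants.
profile_by_class <- function(panel, class_idx, ...) {
  k <- nrow(panel$variants)
  idx <- rep_len(class_idx, k)
  genotypes <- vapply(seq_len(k), function(i) {
    genotype_classes(panel$variants$ref[i], panel$variants$alt[i])[idx[i]]
  }, character(1))
  subject_profile(stats::setNames(genotypes, panel$variants$rs_id), ...)
}

# Write a minimal VCF for the given panel. `gts` is a named list mapping
# rs_id to a vector of GT strings (one per sample); variants absent from
# `gts` are omitted from the file. REF/ALT default to the panel alleles but
# can be overridden per variant via `ref_override`/`alt_override`.
write_test_vcf <- function(path, panel, gts,
                           samples = paste0("S", seq_along(gts[[1]])),
                           ref_override = list(), alt_override = list()) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(0)
  pos <- 1000
  for (rs in names(gts)) {
    v <- panel$variants[panel$variants$rs_id == rs, ]
    ref <- ref_override[[rs]] %||% v$ref
    alt <- alt_override[[rs]] %||% v$alt
    pos <- pos + 100
    body <- c(body, paste(c("1", pos, rs, ref, alt, ".", "PASS", ".", "GT",
                            gts[[rs]]), collapse = "\t"))
  }
  writeLines(c(header, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
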