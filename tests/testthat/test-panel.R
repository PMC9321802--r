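# Panel and frequency-table data model.

test_that("the packaged panel loads with the published values and structure", {
  panel <- default_panel()
  expect_s3_class(panel, "ware_panel")
  expect_equal(nrow(panel$variants), 8)
  expect_equal(nrow(panel$ors), 24)
  expect_setequal(panel$variants$rs_id,
                  c("rs1061170", "rs10490924", "rs2227306", "rs5749482",
                    "rs8135665", "rs8017304", "rs943080", "rs13081855"))
  expect_equal(panel_or(panel, "rs10490924", "TT")$or_point, 8.3)
  expect_equal(panel_or(panel, "rs1061170", "CC")$or_point, 5.16)
  # genotype lookup is allele-order insensitive
  expect_equal(panel_or(panel, "rs10490924", "TG")$or_point,
               panel_or(panel, "rs10490924", "GT")$or_point)
})

test_that("the packaged panel round-trips byte-identically through write_panel", {
  src <- system.file("extdata", "italian_wet_amd_v1.csv", package = "wareamd")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel(load_panel(src), tmp)
  expect_identical(readLines(tmp), readLines(src))
})

test_that("a panel can be supplied as an equivalent JSON document", {
  panel <- default_panel()
  tab <- merge(panel$ors, panel$variants, by = "rs_id", sort = FALSE)
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(provenance = panel$provenance, entries = tab),
    tmp, auto_unbox = TRUE, digits = NA)
  from_json <- load_panel(tmp)
  expect_equal(from_json$ors, panel$ors)
  expect_equal(from_json$variants, panel$variants)
})

test_that("malformed panels are rejected with the offending variant named", {
  tab <- published_panel_reference()
  # a variant with only two genotype classes
  expect_error(risk_panel(tab[-1, ]), "rs1061170")
  # duplicate rs_id under conflicting metadata
  dup <- tab
  dup$gene[dup$rs_id == "rs943080"] <- c("VEGFA", "VEGFA2", "VEGFA")
  expect_error(risk_panel(dup), "duplicate|rs943080")
  # malformed rs identifier
  bad_rs <- tab
  bad_rs$rs_id[bad_rs$rs_id == "rs2227306"] <- "snp-2227306"
  expect_error(risk_panel(bad_rs), "snp-2227306")
  # non-positive OR and CI not bracketing the point value
  bad_or <- tab
  bad_or$or_point[5] <- -1
  expect_error(risk_panel(bad_or), "rs10490924")
  bad_ci <- tab
  bad_ci$ci_high[3] <- bad_ci$or_point[3] / 2
  expect_error(risk_panel(bad_ci), "ci_low <= or_point <= ci_high")
})

test_that("allele frequencies expand under Hardy-Weinberg, triples pass through", {
  expect_equal(hwe_triple(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_triple(0), c(1, 0, 0))
  expect_equal(hwe_triple(1), c(0, 0, 1))

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# source=unit test",
               "rs_id,alt_freq",
               "rs101,0.5",
               "rs102,0.0"), tmp)
  freqs <- load_frequencies(tmp)
  expect_equal(unlist(freqs[freqs$rs_id == "rs101",
                            c("f_refref", "f_het", "f_altalt")],
                      use.names = FALSE),
               c(0.25, 0.5, 0.25))
  expect_equal(unlist(freqs[freqs$rs_id == "rs102",
                            c("f_refref", "f_het", "f_altalt")],
                      use.names = FALSE),
               c(1, 0, 0))
  expect_identical(attr(freqs, "source"), "unit test")

  explicit <- genotype_frequencies(
    data.frame(rs_id = "rs103", f_refref = 0.2, f_het = 0.5, f_altalt = 0.3),
    source = "explicit")
  expect_equal(unlist(explicit[1, c("f_refref", "f_het", "f_altalt")],
                      use.names = FALSE),
               c(0.2, 0.5, 0.3))
})

test_that("Hardy-Weinberg expansion yields a valid triple across the whole range", {
  for (q in c(0, 1e-9, 0.01, 0.25, 0.5, 0.75, 0.99, 1 - 1e-9, 1)) {
    tri <- hwe_triple(q)
    expect_true(all(tri >= 0))
    expect_equal(sum(tri), 1, tolerance = 1e-12)
  }
})

test_that("frequency files are validated: coverage, bounds, provenance", {
  panel <- default_panel()
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("# source=partial",
               "rs_id,alt_freq",
               "rs1061170,0.3"), tmp)
  expect_error(load_frequencies(tmp, panel), "rs10490924")

  writeLines(c("# source=bad",
               "rs_id,alt_freq",
               "rs1061170,1.3"), tmp)
  expect_error(load_frequencies(tmp), "\\[0, 1\\]")

  writeLines(c("rs_id,alt_freq", "rs1061170,0.3"), tmp)
  expect_error(load_frequencies(tmp), "source")

  expect_error(
    genotype_frequencies(
      data.frame(rs_id = "rs1", f_refref = 0.5, f_het = 0.4, f_altalt = 0.4),
      source = "s"),
    "sum")
})

test_that("genotype strings canonicalize and invalid ones are rejected", {
  expect_identical(normalize_genotype(c("TG", "gt", "CC")),
                   c("GT", "GT", "CC"))
  expect_error(normalize_genotype("G"), "invalid genotype")
  expect_error(normalize_genotype("GTT"), "invalid genotype")
  expect_error(normalize_genotype("XY"), "invalid genotype")
  expect_identical(genotype_classes("G", "T"), c("GG", "GT", "TT"))
  expect_identical(genotype_classes("T", "C"), c("TT", "CT", "CC"))
  expect_error(genotype_classes("G", "G"), "differ")
})
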