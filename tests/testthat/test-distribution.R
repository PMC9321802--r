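# Exact population/case risk distributions and their summaries.

test_that("the exact enumeration reproduces the hand-enumerated four-atom case", {
  fix <- four_atom_fixture()
  pop <- population_distribution(fix$panel, fix$freqs)
  expect_equal(pop$risk, fix$support)
  expect_equal(pop$weight, fix$weights)
  expect_equal(distribution_mean(pop), 1)
  expect_identical(attr(pop, "kind"), "population")
})

test_that("a fully degenerate frequency table gives a point mass at 1 after normalization", {
  panel <- make_panel(list(
    list(rs = "rs501", gene = "G1", ref = "A", alt = "G", ors = c(1, 2, 4))
  ))
  freqs <- genotype_frequencies(
    data.frame(rs_id = "rs501", f_refref = 1, f_het = 0, f_altalt = 0),
    source = "degenerate")
  np <- normalize_panel(panel, freqs)
  pop <- population_distribution(np, freqs)
  expect_equal(nrow(pop), 1)
  expect_equal(pop$risk, 1)   # mean-1 contract forces the retained OR to 1
  expect_equal(pop$weight, 1)
})

test_that("support size is bounded by 3^k and weights always sum to 1", {
  for (seed in 1:5) {
    k <- seed
    fix <- random_raw_panel(fixture_spec(k, seed = seed))
    np <- normalize_panel(fix$panel, fix$freqs)
    pop <- population_distribution(np, fix$freqs)
    expect_lte(nrow(pop), 3^k)
    expect_equal(sum(pop$weight), 1, tolerance = 1e-12)
    expect_equal(distribution_mean(pop), 1, tolerance = 1e-9)
  }
})

test_that("case tilting matches the hand-computed weights and identities", {
  fix <- four_atom_fixture()
  pop <- population_distribution(fix$panel, fix$freqs)
  cases <- case_distribution(pop)
  expect_equal(cases$risk, fix$support)
  expect_equal(cases$weight, c(0.10, 0.15, 0.30, 0.45))

  # point mass at 1 is invariant under tilting
  unit <- risk_distribution(1, 1, kind = "population")
  expect_equal(case_distribution(unit)$risk, 1)
  expect_equal(case_distribution(unit)$weight, 1)

  # for a mean-1 population the tilt is already normalized,
  # and tilting never decreases the mean
  for (seed in 6:9) {
    fix <- random_raw_panel(fixture_spec(4, seed = seed))
    np <- normalize_panel(fix$panel, fix$freqs)
    pop <- population_distribution(np, fix$freqs)
    expect_equal(sum(pop$weight * pop$risk), 1, tolerance = 1e-9)
    expect_gte(distribution_mean(case_distribution(pop)),
               distribution_mean(pop) - 1e-12)
  }
  expect_error(case_distribution(case_distribution(pop)), "population-kind")
})

test_that("window fractions account for every atom around the subject's risk", {
  fix <- four_atom_fixture()
  pop <- population_distribution(fix$panel, fix$freqs)

  wf <- window_fractions(pop, risk = 1.2, half_width = 0.15)
  expect_equal(wf$lower, 0.5)    # atoms 0.4 and 0.6
  expect_equal(wf$equal, 0.25)   # atom 1.2 in [1.05, 1.35]
  expect_equal(wf$greater, 0.25) # atom 1.8

  far <- window_fractions(pop, risk = 100)
  expect_equal(far$lower, 1)
  expect_equal(far$equal, 0)
  expect_equal(far$greater, 0)

  # the default half-width is 0.15 OR units
  expect_equal(window_fractions(pop, 1.2)$equal, 0.25)
  expect_equal(formals(window_fractions)$half_width, 0.15)

  # the three fractions partition the mass for arbitrary risks and widths
  set.seed(404)
  for (i in 1:50) {
    wf <- window_fractions(pop, stats::runif(1, 0, 3),
                           half_width = stats::runif(1, 0.01, 1))
    expect_equal(wf$lower + wf$equal + wf$greater, 1, tolerance = 1e-12)
  }
})

test_that("percentiles follow the right-closed CDF", {
  fix <- four_atom_fixture()
  pop <- population_distribution(fix$panel, fix$freqs)
  expect_equal(risk_percentile(pop, 1.0), 0.5)
  expect_equal(risk_percentile(pop, 0.1), 0)
  expect_equal(risk_percentile(pop, 1.8), 1)
  expect_equal(risk_percentile(pop, 0.4), 0.25)  # right-closed at an atom
})

test_that("risk zones use the 0.7 / 2.0 boundaries, inclusive outward", {
  expect_identical(classify_zone(0.5), "low")
  expect_identical(classify_zone(2.5), "high")
  expect_identical(classify_zone(1.0), "intermediate")
  expect_identical(classify_zone(0.7), "low")
  expect_identical(classify_zone(2.0), "high")
  zones <- zone_config()
  expect_equal(zones$low_boundary, 0.7)
  expect_equal(zones$high_boundary, 2.0)

  # monotone in the risk
  order_of <- c(low = 1, intermediate = 2, high = 3)
  risks <- sort(stats::runif(30, 0.05, 3))
  labels <- vapply(risks, classify_zone, character(1))
  expect_true(all(diff(order_of[labels]) >= 0))

  expect_error(classify_zone(0), "positive")
  expect_error(zone_config(2, 0.7), "low_boundary < high_boundary")
})

test_that("Monte-Carlo sampling is seeded, reproducible, and consistent with the exact mean", {
  fix <- random_raw_panel(fixture_spec(4, seed = 11))
  np <- normalize_panel(fix$panel, fix$freqs)

  expect_identical(sample_risks(np, fix$freqs, 500, seed = 5),
                   sample_risks(np, fix$freqs, 500, seed = 5))

  pop <- population_distribution(np, fix$freqs)
  n <- 20000
  s <- sample_risks(np, fix$freqs, n, seed = 6)
  exact_mean <- distribution_mean(pop)
  exact_sd <- sqrt(sum(pop$weight * (pop$risk - exact_mean)^2))
  expect_lt(abs(mean(s) - exact_mean), 3 * exact_sd / sqrt(n))

  # degenerate frequencies give the single deterministic risk
  panel1 <- make_panel(list(
    list(rs = "rs601", gene = "G1", ref = "A", alt = "G", ors = c(1, 2, 4))
  ))
  degen <- genotype_frequencies(
    data.frame(rs_id = "rs601", f_refref = 1, f_het = 0, f_altalt = 0),
    source = "degenerate")
  expect_identical(sample_risks(panel1, degen, 1, seed = 1), 1)

  # the caller's RNG state is not disturbed
  set.seed(99); before <- stats::runif(3)
  set.seed(99); invisible(sample_risks(np, fix$freqs, 100, seed = 3))
  expect_identical(stats::runif(3), before)
})

test_that("distributions export as risk,weight,kind CSV", {
  fix <- four_atom_fixture()
  pop <- population_distribution(fix$panel, fix$freqs)
  cases <- case_distribution(pop)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_distribution(pop, tmp)
  write_distribution(cases, tmp, append = TRUE)
  tab <- utils::read.csv(tmp)
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$kind), c("population", "case"))
  expect_equal(tab$risk[tab$kind == "population"], pop$risk)
  expect_equal(tab$weight[tab$kind == "case"], cases$weight)
})
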