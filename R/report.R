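# The risk report: computation, JSON serialization, structural validation.

#' Compute a full risk report for a subject
#'
#' Combines the risk engine and the population model: genetic risk (product
#' of normalized ORs), overall risk (genetic times non-genetic factors),
#' percentiles and equal-risk-window fractions of the genetic risk against
#' the general-population and case distributions, ratio-to-mean relative
#' risks, and the risk-zone label of the overall risk.
#'
#' @param profile a `ware_profile` with both non-genetic levels set.
#' @param panel a `ware_panel` of normalized odds ratios.
#' @param freqs a `ware_freqs` table covering the panel.
#' @param factors a `ware_factors` object.
#' @param zones a `ware_zones` configuration (defaults 0.7 / 2.0).
#' @param half_width equal-risk window half-width (default 0.15).
#' @param pop,cases optionally precomputed population and case
#'   distributions (recomputed from `panel`/`freqs` when omitted).
#' @return a `ware_report` list; see the packaged JSON schema
#'   (`system.file("schema", "risk-report.schema.json", package =
#'   "wareamd")`) for the serialized layout.
#' @export
risk_report <- function(profile, panel, freqs, factors,
                        zones = zone_config(), half_width = 0.15,
                        pop = NULL, cases = NULL) {
  stopifnot(inherits(profile, "ware_profile"))
  genetic <- genetic_risk(profile, panel)
  overall <- overall_risk(genetic, profile$smoking, profile$familiarity,
                          factors)
  if (is.null(pop)) pop <- population_distribution(panel, freqs)
  if (is.null(cases)) cases <- case_distribution(pop)

  report <- list(
    subject_id = profile$subject_id,
    genetic_risk = genetic,
    overall_risk = overall,
    zone = classify_zone(overall, zones),
    percentile_population = risk_percentile(pop, genetic),
    percentile_cases = risk_percentile(cases, genetic),
    relative_risk_population = genetic / distribution_mean(pop),
    relative_risk_cases = genetic / distribution_mean(cases),
    window_fractions_population = unclass(
      window_fractions(pop, genetic, half_width)),
    window_fractions_cases = unclass(
      window_fractions(cases, genetic, half_width)),
    zone_config = unclass(zones),
    panel_provenance = panel$provenance,
    inputs_echo = list(
      genotypes = as.list(profile$genotypes),
      smoking = profile$smoking,
      familiarity = profile$familiarity
    )
  )
  structure(report, class = "ware_report")
}

#' @export
print.ware_report <- function(x, ...) {
  cat("<ware_report> ", x$subject_id, "\n", sep = "")
  cat(sprintf("  genetic risk %.2f | overall risk %.2f | zone %s\n",
              x$genetic_risk, x$overall_risk, x$zone))
  cat(sprintf("  percentile: population %.1f%% | cases %.1f%%\n",
              100 * x$percentile_population, 100 * x$percentile_cases))
  wf <- x$window_fractions_population
  cat(sprintf("  population within +/-%.2f: %.1f%% (%.1f%% lower, %.1f%% greater)\n",
              wf$half_width, 100 * wf$equal, 100 * wf$lower, 100 * wf$greater))
  invisible(x)
}

#' Write a risk report and its figures
#'
#' Writes `report.json` (full numeric precision), two pie charts (fractions
#' of the population and of cases with lower / equal / greater risk, in
#' green / grey / red) and two risk-density plots (population and cases, with
#' the low-risk zone shaded green, the high-risk zone red, and a red vertical
#' line at the subject's risk). Figures are saved as both SVG and PNG.
#'
#' @param report a `ware_report`.
#' @param pop,cases the population and case `risk_distribution`s the report
#'   was computed against.
#' @param out_dir output directory, created if needed.
#' @param formats image formats to write (subset of `"svg"`, `"png"`).
#' @return character vector of written file paths, invisibly.
#' @export
render_report <- function(report, pop, cases, out_dir,
                          formats = c("svg", "png")) {
  stopifnot(inherits(report, "ware_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)

  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- json_path

  zones <- do.call(zone_config, report$zone_config)
  figures <- list(
    pie_population = plot_window_pie(report$window_fractions_population,
                                     title = "Risk relative to the general population"),
    pie_cases = plot_window_pie(report$window_fractions_cases,
                                title = "Risk relative to AMD cases"),
    density_population = plot_risk_density(pop, risk = report$genetic_risk,
                                           zones = zones),
    density_cases = plot_risk_density(cases, risk = report$genetic_risk,
                                      zones = zones)
  )
  for (name in names(figures)) {
    for (fmt in formats) {
      f <- file.path(out_dir, paste0(name, ".", fmt))
      save_figure(figures[[name]], f, fmt)
      written <- c(written, f)
    }
  }
  invisible(written)
}

save_figure <- function(plot, path, fmt) {
  if (fmt == "svg") {
    grDevices::svg(path, width = 6, height = 4.5)
  } else {
    grDevices::png(path, width = 900, height = 675, res = 150,
                   type = "cairo")
  }
  on.exit(grDevices::dev.off())
  print(plot)
}

#' Read a serialized risk report
#'
#' @param path path to a `report.json` written by [render_report()].
#' @return a `ware_report` list.
#' @export
read_report <- function(path) {
  report <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  report$inputs_echo$genotypes <- as.list(report$inputs_echo$genotypes)
  structure(report, class = "ware_report")
}

#' Validate the structure of a risk report
#'
#' Checks a report (in-memory object or `report.json` path) against the
#' packaged JSON schema: required fields, types, probability bounds, the
#' partition of the window fractions, and consistency of the zone label with
#' the zone boundaries.
#'
#' @param report a `ware_report`, a plain list, or a path to a JSON file.
#' @return `TRUE` invisibly if valid; otherwise an error describing the first
#'   violation.
#' @export
validate_report <- function(report) {
  if (is.character(report) && length(report) == 1)
    report <- read_report(report)
  schema <- jsonlite::fromJSON(
    system.file("schema", "risk-report.schema.json", package = "wareamd",
                mustWork = TRUE),
    simplifyVector = FALSE)
  check_against_schema(unclass(report), schema, where = "report")

  for (field in c("percentile_population", "percentile_cases")) {
    p <- report[[field]]
    if (p < 0 || p > 1) stop(field, " outside [0, 1]", call. = FALSE)
  }
  for (field in c("window_fractions_population", "window_fractions_cases")) {
    wf <- report[[field]]
    total <- wf$lower + wf$equal + wf$greater
    if (abs(total - 1) > 1e-9)
      stop(field, " does not partition the mass (sums to ",
           format(total), ")", call. = FALSE)
  }
  zones <- do.call(zone_config, report$zone_config[c("low_boundary",
                                                     "high_boundary")])
  if (!identical(report$zone, classify_zone(report$overall_risk, zones)))
    stop("zone label '", report$zone,
         "' inconsistent with the overall risk and zone boundaries",
         call. = FALSE)
  invisible(TRUE)
}

# Minimal structural validator for the subset of JSON Schema the packaged
# schema uses: type, required, properties, enum, minimum/exclusiveMinimum,
# and local "#/definitions/..." references.
check_against_schema <- function(x, schema, where, root = schema) {
  ref <- schema[["$ref"]]
  if (!is.null(ref)) {
    path <- strsplit(sub("^#/", "", ref), "/", fixed = TRUE)[[1]]
    schema <- root[[path]]
  }
  type <- schema$type
  if (!is.null(type)) {
    ok <- switch(type,
      object = is.list(x),
      number = is.numeric(x) && length(x) == 1 && is.finite(x),
      string = is.character(x) && length(x) == 1,
      stop("unsupported schema type: ", type, call. = FALSE))
    if (!ok) stop(where, ": expected ", type, call. = FALSE)
  }
  if (!is.null(schema$enum) && !x %in% unlist(schema$enum))
    stop(where, ": value '", x, "' not among ",
         paste(unlist(schema$enum), collapse = ", "), call. = FALSE)
  if (!is.null(schema$minimum) && x < schema$minimum)
    stop(where, ": value below minimum ", schema$minimum, call. = FALSE)
  if (!is.null(schema$exclusiveMinimum) && x <= schema$exclusiveMinimum)
    stop(where, ": value must exceed ", schema$exclusiveMinimum,
         call. = FALSE)
  if (!is.null(schema$maximum) && x > schema$maximum)
    stop(where, ": value above maximum ", schema$maximum, call. = FALSE)
  for (req in unlist(schema$required)) {
    if (is.null(x[[req]]))
      stop(where, ": missing required field '", req, "'", call. = FALSE)
  }
  for (name in names(schema$properties)) {
    if (!is.null(x[[name]]))
      check_against_schema(x[[name]], schema$properties[[name]],
                           where = paste0(where, ".", name), root = root)
  }
  invisible(TRUE)
}
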