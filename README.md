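# wareamd

Individual risk evaluation for exudative ("wet") age-related macular
degeneration, for clinicians and analysts working with the eight-variant
risk panel validated in the Italian population (*CFH* rs1061170, *ARMS2*
rs10490924, *IL8* rs2227306, *TIMP3* rs5749482, *SLC16A8* rs8135665,
*RAD51B* rs8017304, *VEGFA* rs943080, *COL8A1* rs13081855).

The model at the core:

* **Normalized odds ratios.** Per-genotype raw ORs are rescaled by the mean
  population risk `m = Σ_g f_g·OR_g` (with `f_g` the genotype frequencies),
  so every variant's normalized OR has expectation 1 in the general
  population. The packaged panel (`default_panel()`) ships the published
  normalized ORs and 95% CIs; `normalize_ors()` / `normalize_panel()`
  perform the rescaling for user-supplied raw panels.
* **Multiplicative risk.** A subject's genetic risk is
  `Π_variants OR~genotype~`; the overall risk further multiplies in the
  smoking and family-history ORs (lowest levels "no"/"absent" contribute
  exactly 1).
* **Exact risk distributions.** Enumeration of all 3^8 genotype
  combinations gives the exact population distribution of the risk; the
  case distribution is its risk-tilt `w_case ∝ w_pop·r`. From these come
  the subject's percentile, the fraction of subjects with equal risk
  (±0.15 OR), and the low/intermediate/high risk zone (boundaries OR 0.7
  and 2.0).

## Worked example

The packaged frequency, profile and factors files are synthetic
illustrations (the real genotype frequencies and non-genetic ORs are inputs
you supply for your population):

```r
library(wareamd)
ext <- function(f) system.file("extdata", f, package = "wareamd")

panel   <- default_panel()
freqs   <- load_frequencies(ext("frequencies_synthetic_example.csv"), panel)
profile <- read_profile_csv(ext("profile_synthetic_example.csv"))
factors <- load_factors(ext("factors_synthetic_example.csv"))

pop   <- population_distribution(panel, freqs)
cases <- case_distribution(pop)
risk_report(profile, panel, freqs, factors, pop = pop, cases = cases)
```

```
<ware_report> profile_synthetic_example
  genetic risk 1.37 | overall risk 2.60 | zone high
  percentile: population 85.6% | cases 8.7%
  population within +/-0.15: 2.4% (84.5% lower, 13.1% greater)
```

Reading it: this subject's genotypes multiply to a genetic risk of 1.37
(37% above the population average); being a smoker (synthetic OR 1.9)
raises the overall risk to 2.60, in the high-risk zone (≥ 2.0). Their
genetic risk exceeds that of 85.6% of the general population but only 8.7%
of cases; 2.4% of the population has a risk within ±0.15 of theirs.
`render_report(report, pop, cases, "out/")` writes `report.json` plus the
two pie charts and two zone-shaded density plots (SVG and PNG). Profiles
can equally be read from a VCF with `read_profile_vcf()` (rsID-matched,
strict REF/ALT checking).

## Command line

```sh
WARE=$(Rscript -e 'cat(system.file("cli/ware-risk.R", package="wareamd"))')
Rscript "$WARE" score \
  --panel inst/extdata/italian_wet_amd_v1.csv \
  --freqs inst/extdata/frequencies_synthetic_example.csv \
  --profile inst/extdata/profile_synthetic_example.csv \
  --factors inst/extdata/factors_synthetic_example.csv \
  --out out/
```

Subcommands: `score` (full report + figures), `distribution` (export the
exact population/case distributions as CSV), `validate` (check a panel
and/or profile). Errors exit non-zero with a single `ware-risk error:` line.

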