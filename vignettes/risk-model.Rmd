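---
title: "The wareamd risk model: normalization, enumeration and reporting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The wareamd risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wareamd)
```

## The problem

Exudative ("wet") age-related macular degeneration is a multifactorial
disease: susceptibility is spread over common variants of modest effect plus
non-genetic exposures (smoking, positive family history in first-degree
relatives). Association studies report each variant's per-genotype odds
ratios (ORs) anchored to the lowest-risk genotype, which is assigned OR = 1.
That anchoring is inconvenient for individual risk profiling, because the
anchor genotype may be rare: a subject carrying only "reference" genotypes
is then assigned risk 1 even though they sit well below the population
average.

`wareamd` implements the risk-evaluation model used for the Italian
wet-AMD panel: eight variants (*CFH* rs1061170, *ARMS2* rs10490924, *IL8*
rs2227306, *TIMP3* rs5749482, *SLC16A8* rs8135665, *RAD51B* rs8017304,
*VEGFA* rs943080, *COL8A1* rs13081855) whose association was validated in
the Italian population, with ORs rescaled so that the *population-average*
risk is 1.

## Normalization

For one variant with genotype classes $g \in \{\text{hom-ref}, \text{het},
\text{hom-alt}\}$, raw odds ratios $\mathrm{OR}_g$ and population genotype
frequencies $f_g$, the mean population risk is

$$ m = \sum_g f_g \, \mathrm{OR}_g $$

and the normalized ORs are $\widetilde{\mathrm{OR}}_g = \mathrm{OR}_g / m$.
By construction $\sum_g f_g \widetilde{\mathrm{OR}}_g = 1$: the module's
defining contract, enforced to a relative tolerance of 1e-12 (the
computation is a dot product and one division). Normalization is invariant
to rescaling all of a variant's raw ORs and is idempotent. Confidence-bound
treatment was a genuinely open choice — the source panel publishes CI bounds
but not their transformation — and we divide `ci_low`/`ci_high` by the same
per-variant mean $m$, the only transformation consistent with the point
values.

Genotype frequencies may be supplied as explicit triples or as a single
alternate-allele frequency expanded under Hardy–Weinberg equilibrium,
$(p^2, 2pq, q^2)$. Every frequency table carries a mandatory `source` label;
the package deliberately hard-codes no frequencies as "the" population
truth (the packaged example table is synthetic and labelled as such). The
packaged panel's normalized ORs are shipped as published constants; the
generic normalization operation is *not* used to regenerate them, since the
exact frequency snapshot behind them is not recoverable.

## The multiplicative risk

A subject's genetic risk is the product of the normalized ORs of their
genotypes over all eight variants; a genotype is required for every panel
variant, and scoring fails otherwise, naming the missing rsIDs. The overall
risk multiplies in the non-genetic factors:

$$ R_\text{overall} = R_\text{genetic} \times
   \mathrm{OR}_\text{smoking}^{[\text{smoking = yes}]} \times
   \mathrm{OR}_\text{familiarity}^{[\text{familiarity = present}]} $$

Both levels must be set before the overall risk is computed; a user who does
not know a factor sets its lowest level ("no"/"absent"), which contributes
exactly 1 and leaves the genetic risk unchanged. The model is strictly
multiplicative — no interaction terms — and no confidence interval is
propagated onto the product (the inputs' CIs are correlated in unknown
ways). Non-genetic ORs are mandatory configuration with no packaged
defaults, because no authoritative values ship with the panel; the example
file in `inst/extdata/` is synthetic.

## Exact population and case distributions

Because the eight loci sit on different chromosomes or chromosome arms,
linkage equilibrium — independence of genotype classes across variants — is
a defensible assumption, and the population distribution of the
multiplicative risk can be enumerated exactly: all $3^k$ genotype
combinations ($6561$ for $k = 8$), each with risk the product of its
normalized ORs and weight the product of its genotype frequencies.
Zero-frequency classes are dropped and identical risk values merged (exact
floating-point equality; atoms produced by different multiplication orders
that differ in the last bit are simply kept as separate atoms, which changes
no probability). For a panel normalized against the same frequencies the
distribution's mean is 1 to within 1e-9 — the composition of the
per-variant mean-1 contracts.

The distribution among cases is obtained by risk tilting,

$$ w^\text{case}_i = \frac{w_i \, r_i}{\sum_j w_j \, r_j}, $$

the standard case-enrichment identity when the normalized OR is read as a
relative risk. For a mean-1 population distribution the normalizing constant
is exactly 1, and tilting can only increase the mean. The construction of
the case curve was an open design point; risk tilting is our choice, and a
user who instead has observed case genotype frequencies can build the case
distribution directly with `population_distribution()` on those
frequencies.

All reported probabilities come from the exact discrete distribution:

* **Percentile** — the right-closed CDF, $P(R \le r)$, against both the
  population and the case distribution.
* **Equal-risk window** — the mass within the closed interval $r \pm 0.15$
  (OR units; the packaged default half-width), with the strictly-lower and
  strictly-higher masses as the complementary slices. The three fractions
  partition the mass to within 1e-12 for any $r$ and any half-width.
* **Risk zones** — "low" at OR $\le 0.7$, "high" at OR $\ge 2.0$,
  "intermediate" between. Boundaries are inclusive toward the outer zones,
  the more cautious reading at exactly 0.7 or 2.0.
* **Relative risk** is reported both as the percentile and as the ratio to
  the distribution mean, since either reading is defensible; the report
  carries both. The genetic risk is compared against the genotype-only
  distributions; the overall risk (which mixes in non-genetic factors the
  distributions do not model) is reported with its zone label only.

The density *plots* are a kernel-smoothed view (Gaussian kernel, Silverman's
rule-of-thumb bandwidth computed on the support) of the same discrete
distribution, drawn purely for visual comparison — with the low-risk zone
shaded green, the high-risk zone red and a red vertical line at the
subject's risk. No reported number is ever read off the smoothed curve.

## Monte-Carlo cross-check

`sample_risks()` draws subjects genotype-by-genotype from the frequency
table and scores them, providing a sampling oracle for the enumerator. Both
paths multiply ORs in the same variant order, so sampled risks coincide
bit-for-bit with enumeration atoms and the Kolmogorov–Smirnov distance
between the empirical and exact CDFs can be evaluated exactly on the atoms.
The test suite requires the KS distance at $n = 10^5$ draws to stay below
the 99% Dvoretzky–Kiefer–Wolfowitz bound $\sqrt{\ln(2/0.01)/(2n)} \approx
0.0051$; observed values are typically 0.003–0.005.

## Synthetic data

The generators in `fixture_spec()` / `random_raw_panel()` /
`random_cohort()` emulate a biallelic risk panel under a log-additive
allelic model: heterozygote raw OR drawn uniformly (default range 1–3,
typical for common risk variants; tests of the normalization contract widen
this to 0.5–6 to cover protective variants), homozygote-alternate OR its
square, reference OR 1, synthetic CI bounds at 0.8×/1.25× the point value,
and alternate-allele frequencies uniform on (0.05, 0.95) expanded under
Hardy–Weinberg. Cohort subjects draw genotypes from those frequencies and
Bernoulli(0.5) factor levels. What this does *not* emulate: linkage
disequilibrium between loci, deviations from Hardy–Weinberg, genotyping
error, population stratification, or dominance effects. Passing tests
therefore demonstrate the arithmetic contracts of the pipeline, not
calibration on real cohorts — the packaged panel's ORs, not the generator,
carry the empirical content.

Problem sizes used by the test suite and the acceptance script: 1000
3-variant panels for the normalization contract, full $3^8$ enumeration for
the 8-variant distributions, $10^5$ Monte-Carlo draws for the KS check, and
cohorts of 2000–3000 for binomial-consistency checks. These sizes make every
Monte-Carlo tolerance a ≥3-sigma bound while keeping the whole suite to
about a minute.

## Numerical and interface choices

* Risks are kept in full double precision throughout; rounding to two
  decimals happens only in human-readable rendering. `report.json` stores
  full precision.
* Genotypes are unordered allele pairs, canonicalized alphabetically
  ("TG" ≡ "GT") on every input path.
* VCF profiles are matched by rsID only (no positional matching across
  genome builds), require `REF`/`ALT` to equal the panel alleles exactly —
  strand flips are rejected, never silently resolved — and require a called
  diploid genotype at every panel variant.
* The empty panel is a valid vacuous input (risk 1, point-mass
  distribution); fully degenerate frequencies are likewise handled.
* `validate_report()` checks reports against the shipped JSON schema with a
  small built-in structural validator (types, required fields, enums,
  bounds) plus the semantic invariants (fraction partition, zone/classifier
  consistency).

## Limitations

The model predicts risk for the wet form only, on a panel validated in one
population; applying it elsewhere requires that population's frequencies,
factor ORs and panel. Odds ratios are treated as exchangeable with relative
risks in the tilting step, a standard approximation that degrades for very
common, high-risk genotypes. Disease prevalence is not used to convert the
relative risk into an absolute probability of disease — no such formula
ships with the panel — so all outputs remain on the relative (OR) scale.
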