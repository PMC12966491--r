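---
title: "Diet-constrained community flux modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet-constrained community flux modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
library(dplyr)
```

# The modeling problem

gutflux simulates the metabolism of a gut microbial community under a
defined diet. The pipeline has four stages:

1. **Diet construction.** Food intakes (g/day) and food-composition tables
   (mg of metabolite per 100 g) are converted into metabolite uptake
   fluxes in mmol/day, the unit used throughout the package.
2. **Abundance profiling.** A sample-by-model genome-coverage table is
   converted into relative abundances, filtered at a strict detection
   cutoff, and renormalized.
3. **Community assembly and simulation.** Per-taxon genome-scale metabolic
   models are namespaced and joined through a shared lumen compartment;
   the diet bounds the lumen's import exchanges; flux variability analysis
   (FVA) yields per-metabolite net secretion and uptake.
4. **Contribution analysis.** FVA over each taxon's lumen-transfer
   reactions decomposes community fluxes into per-taxon contributions,
   from which metabolite producers and prebiotic responders are called.

# The community model

Each member model is a stoichiometric network with flux bounds and a
biomass reaction. At assembly time every member id is prefixed with its
tag, the member's own exchange reactions are removed, and each
extracellular metabolite `m__e` is connected to a community lumen
metabolite `m__u` by a reversible transfer reaction (positive flux =
secretion into the lumen). Every lumen metabolite receives two boundary
reactions under the export-positive convention:

* a **diet exchange** `EX_m__d` with bounds `[-flux, 0]` — import up to
  the dietary supply, never export through the diet side; metabolites
  absent from the diet stay closed (an optional gap-fill list admits a
  trace import of 0.1 mmol/day for user-named micronutrients, since
  real-repository communities can be infeasible on food-only diets);
* a **fecal exchange** `EX_m__fe` with bounds `[0, 1e6]` — export only.

A **community biomass** reaction consumes `a_k` units of each taxon's
biomass metabolite, where `a_k` is the taxon's relative abundance, and
produces one unit of community biomass whose exchange is bounded to
`[0.4, 1]` mmol/day — the physiological range from fecal emptying every
three days to once per day. Because the flux through the community biomass
reaction is shared, each taxon's growth is pinned to `a_k * mu` with
`mu` in `[0.4, 1]`: taxa grow at their observed ratios.

**Coupling constraints.** For every member reaction `r` of taxon `k`
(including its lumen transfers) two rows are added:

```
 v_r <= c * v_bio_k + u      and      v_r >= -c * v_bio_k - u
```

with defaults `c = 400` (dimensionless) and `u = 0` (mmol/day). These
prevent growth-free metabolic activity: a taxon whose biomass flux is zero
can carry no flux at all when `u = 0`. The constants are the established
community-modeling convention; both are configurable
(`coupling_config()`). Note an implication that matters when reading FVA
results: a transfer carrying `y` units per unit of fermentation flux hits
its own cap `c * v_bio` before the fermentation reaction does, so the
binding row is usually the transfer of the highest-yield product.

# Units, conventions and numerical choices

* **Units** are mmol/day per person everywhere — diet fluxes, flux
  bounds, biomass — matching the daily-intake framing of the diet data.
* **Open bounds** default to ±1e6 mmol/day rather than infinity so every
  linear program is bounded; an FVA optimum at ±1e6 is reported with an
  `unbounded_min`/`unbounded_max` flag.
* **Solver.** All optimizations run on a dense bounded-variable two-phase
  simplex implemented in the package (R/lp.R). Problems here are small
  (tens to a few hundred variables) and solved repeatedly with different
  objectives, so the implementation keeps an explicit tableau and
  re-optimizes in place after each objective swap; FVA and contribution
  analysis share one feasibility phase per model. Results are checked in
  the test suite against exhaustive vertex enumeration of the flux
  polytope on toy models. Feasibility and optimality comparisons use an
  absolute tolerance of 1e-6; Dantzig pricing switches to Bland's rule
  after a pivot budget to rule out cycling. Infeasibility is always
  surfaced as a status or error, never repaired.
* **Readability clamp.** Reported FVA fluxes below 1e-9 are shown as 0;
  raw values are kept in `raw_minimum`/`raw_maximum`.

# Diet construction

`build_diet_fluxes()` computes, for each metabolite `m`,

```
flux(m) = sum_foods intake_g_per_day * (mg_per_100g(m) / 100) / MW(m)
```

summing over both the primary and the manually curated composition
sources. The conversion is linear and additive, which the tests exploit
as properties. Foods with no composition entry are retained in the
provenance table with zero contribution and a warning — mirroring the
situation where traditional foods are missing from the main composition
database and must be curated by hand.

Energy profiling uses Atwater factors 4/9/4 kcal/g for
carbohydrate/fat/protein and 7 kcal/g for alcohol (the intake fixture
includes beer); the factors are arguments. Reference-intake validation
checks energy (1500–2400 kcal/day) and the energy shares of carbohydrate
(45–65%), fat (20–35%) and protein (10–15%), the last with a 30%
cautionary ceiling that turns the verdict into the three-way
within / above-but-below-caution / above.

Supplement arms are built with `add_supplement()`: a placebo arm adds
10 g/day maltodextrin, a prebiotic arm 5 g/day manno-oligosaccharide
(MOS, as mannotriose, MW 504.44 g/mol) plus 5 g/day maltodextrin.
Maltodextrin is a glucose polymer of variable length; the fixture assigns
it a triose-equivalent molecular weight (504.44 g/mol) so doses convert
deterministically — a documented simplification, not a measured value.

# Abundance profiling

Coverage (reads mapped, normalized by genome size) is converted to
fractions per sample; entries are kept only when the fraction **strictly
exceeds** the cutoff (default 1e-5, i.e. 0.001%) — a fraction exactly at
the cutoff is dropped — and survivors are renormalized to sum to exactly
1, so the community biomass coefficients always sum to 1. Whether to
renormalize after the cutoff is genuinely open (upstream toolboxes do;
the source protocols are silent); the package renormalizes by default and
exposes `renormalize = FALSE`. Prevalence filtering (`shared_models()`)
uses a `>=` floor: with 4 samples and prevalence 0.5, presence in exactly
2 samples suffices.

# Net secretion and net uptake

For each lumen metabolite with diet exchange `d` and fecal exchange `f`,
the default **signed** convention defines

```
net_secretion = maxFVA(f) + minFVA(d)
net_uptake    = maxFVA(d) + minFVA(f)
```

Because imports are negative, a metabolite that can only pass through
(imported then re-exported, never transformed) nets to exactly zero
secretion, while a fermentation product nets to its full production
capacity. The phrasing "sum of maximal secretion and minimal uptake"
admits a second, magnitude-based reading; it is implemented behind
`convention = "magnitude"` (`net_uptake = -minFVA(d) + minFVA(f)`,
`net_secretion = maxFVA(f) - maxFVA(d)`), which reports positive uptake
potentials but does not cancel pass-through. The signed reading is the
default because it is the only one that keeps the two formulas symmetric
and makes the pass-through identity exact.

FVA runs with the community biomass *bounded* to `[0.4, 1]`, not fixed at
an optimum; a fix-at-fraction-of-optimum mode (`fix_biomass =`) is
provided for comparison.

# Contribution analysis, producers and responders

`compute_contributions()` optimizes each member's lumen-transfer reaction
for each target metabolite independently under the full community
constraints; joint optimality across members is deliberately not enforced
(each member's range is a relaxation, so the sum of member secretion
maxima bounds the community maximum from above, with equality in
single-producer communities — a tested invariant).

* A **producer** is a taxon whose mean secretion-side contribution
  (per-sample FVA maxima truncated at zero; samples without the taxon
  count as zero) is at least 0.01 mmol/day for at least one target;
  producers are ranked by total mean secretion across targets.
* A **responder** to a supplemented substrate is a taxon whose mean
  uptake-side flux (absolute value of per-sample FVA minima) is at least
  1 mmol/day; the report carries mean, population standard deviation and
  min–max, the shape of an intervention-study summary table. The
  estimator (mean of per-sample FVA extrema, population SD) is a
  documented choice; a fixed-point alternative would require selecting a
  single optimum among degenerate solutions.

Both thresholds use `>=` ("at least") and are configurable.

# The synthetic cohort generator

The generator exists so that every stage has a known ground truth without
any model repository or sequencing data. Six toy fermenter templates span
the behaviors the pipeline must resolve:

| template | genus (synthetic) | pathway |
|---|---|---|
| acetogen | Acetifaber | glc → 2 ac |
| propionogen | Propionifaber | glc → 1.5 ppa |
| butyrogen | Butyrifaber | glc → 1 but; glc + ac → 2.5 but (cross-feeds) |
| isobutyrogen | Isobutyrifaber | val → 1 isobut (branched-chain amino acid route) |
| mos_utilizer | Mannovorax | mos → 3 ac |
| generalist | Omnivorax | glc → ac + 0.5 ppa; mdx → 3 glc |

All templates grow on glucose (biomass yield 1); the isobutyrate producer
requires dietary valine, exercising the protein-fermentation route; the
MOS utilizer is the sole taxon with a MOS pathway, so the responder
analysis has an unambiguous expected answer; the butyrogen's acetate
cross-feed exercises inter-taxon exchange. Taxonomies are synthetic
lineages (marked by genus names like *Acetifaber*) chosen to exercise
rank aggregation, not to name real organisms.

Cohorts draw per-sample abundances from a symmetric Dirichlet
(concentration 5 by default — moderately even communities in which every
template stays comfortably above the 0.001% cutoff, so presence/absence
never confounds parameter-recovery tests) and convert them to coverages
with multiplicative lognormal noise (sd 0.1) and a lognormal sequencing
depth — arbitrary but documented and configurable. Everything is
reproducible byte-for-byte from the seed.

The bundled food fixture combines a verbatim transcription of a national
food-consumption table (25 items with g/day and a matched/unmatched flag)
with a synthetic composition database: macronutrient values are plausible
per-100 g figures for each food, glucose is allocated as 90% of
carbohydrate mass and valine as 6% of protein mass. These allocations are
toy conventions that guarantee template feasibility; they are not
measured compositions, so the fixture's absolute energy (about 2340 kcal)
and macronutrient split are illustrative, not reproductions of any
cohort-level figure.

**What passing tests do and do not show.** The synthetic cohort has
clean, fully-determined pathway structure, no unmapped reads, no strain
ambiguity, and noise only in coverage. Recovering producers and
responders here validates the *machinery* — constraint construction,
FVA, thresholding — not the biology of any real dataset, which depends on
repository model quality and composition-database coverage that the toys
idealize away.

# Degenerate inputs and edge behavior

* Empty diets make growing communities infeasible; this is reported, not
  repaired.
* A sample with all-zero coverage is an error naming the sample.
* Forcing one taxon's biomass to zero with the community biomass lower
  bound at 0.4 is infeasible by construction (the community biomass
  reaction consumes every member's biomass metabolite); the
  zero-growth-collapse property is therefore checked with community
  biomass bounds `[0, 1]`.
* Targets absent from the lumen are skipped with a warning; diet entries
  without a lumen metabolite produce a warning list, not an error.
* Responder analysis against a diet lacking the substrate is refused when
  the diet is supplied, since the question is then meaningless; placebo
  contributions simply yield an empty responder table.

# Problem sizes and runtime

The shipped tests and the acceptance script use toy communities of 6
members (about 60 reactions and 120 coupling rows per community model)
and cohorts of 10 samples; parameter recovery runs 20 seeded cohorts
across three diet arms. On one CPU the full test suite takes on the order
of two minutes and the acceptance script about a minute and a half.
These sizes were chosen so the exhaustive enumeration oracle stays exact
and iteration stays fast; the machinery itself is generic, but the dense
simplex would need replacing with a sparse solver before repository-scale
models (tens of thousands of reactions) became practical — the main known
limitation.

# A worked example

```{r example}
models <- setNames(
  lapply(seq_len(nrow(taxon_templates())),
         function(i) make_taxon_model(taxon_templates()[i, ])),
  taxon_templates()$model_id)
db <- make_food_db()
diets <- fixture_diets(db)

cohort <- make_cohort(n_samples = 3, seed = 1)
profile <- normalize_coverage(cohort$coverage)

contrib <- cohort_contributions(models, profile, diets$prebiotic,
                                targets = c("ac", "ppa", "but", "isobut",
                                            "mos"))
ranked <- aggregate_by_rank(contrib, cohort$taxonomy, "genus")
identify_producers(dplyr::filter(ranked, metabolite != "mos"))
identify_responders(ranked, "mos", diet = diets$prebiotic)
```
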