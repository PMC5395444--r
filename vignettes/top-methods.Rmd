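---
title: "Screening outcrossing risk with TOPscreen: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening outcrossing risk with TOPscreen: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TOPscreen)
```

## The screening problem

Pollen-mediated gene flow from a cultivated or genetically modified (GM)
donor into surrounding vegetation is a standing concern in coexistence
policy and environmental risk assessment. A full mechanistic treatment
(pollen dispersal kernels, phenology dynamics, hybrid fitness) is rarely
feasible at the scale of a national flora, so TOPscreen implements a
screening-level index: cheap to compute for thousands of donor–receptor
couples, transparent in its factors, and deliberately conservative where
data are missing.

The unit of evaluation is an ordered couple (pollen donor, pollen receptor)
at an optional geographic point, scored as

$$\mathrm{TOP} = \frac{\mathrm{OP}}{100} \times \mathrm{RPI} \times
\mathrm{SDP} \in [0, 1].$$

The three factors isolate three necessary conditions for outcrossing:
biological compatibility (OP), a pollination vector (RPI), and spatial
co-occurrence (SDP). Multiplication — rather than any additive
combination — encodes that each condition is necessary: if any factor is
zero the total risk is zero, and the total can never exceed its weakest
factor. It also keeps TOP on the $[0,1]$ scale that the quintile
classification requires. OP enters as a fraction for the same reason.

## The outcrossing-potential rubric (OP)

OP is a percentage built from the couple's biological traits. Two contract
properties anchor it:

* it is defined **only within a genus** — cross-genus couples are outside
  the domain of genus-level hybridization screening and score 0;
* a **conspecific** couple (same binomial after synonym resolution) carries
  a minimum of 50%, reflecting that intraspecific crossing is always at
  least plausible regardless of how little else is known.

The default rubric distributes the remaining 50 points over four trait
factors:

| factor | max points | scoring |
|---|---|---|
| flowering overlap | 20 | $|A \cap B| / \min(|A|, |B|)$ over month sets |
| syndrome match | 10 | full iff the pollination-syndrome sets intersect |
| breeding system | 10 | mean of per-species scores: outcrossing 1, mixed 0.5, selfing 0.1, unknown 0 |
| ploidy match | 10 | full iff equal and both known |

plus the 50-point conspecific bonus. The bonus is implemented as additive
(not as a floor applied after the fact): a fully compatible conspecific
couple reaches exactly 100, and the validity of `rubricWeights()` enforces
that the four factor maxima sum to 50 so this identity holds for any
configured weight set. Making the bonus additive rather than a clamp was a
genuine design choice; the additive form preserves monotonicity in the
trait factors within the conspecific stratum, whereas a floor would flatten
all weakly compatible conspecific couples to exactly 50.

Flowering overlap divides by the *shorter* season so that a short-flowering
species fully nested in a long-flowering partner's season scores 1 — the
limiting partner is the one with less opportunity. `"both"` syndromes count
as either insect- or wind-pollinated for the match; `"unknown"` intersects
nothing.

**Missing data are never imputed.** Unknown traits (empty month set, ploidy
`NA`, `"unknown"` enums) contribute 0 points and are visible as zeros in
the `OPScore` breakdown. This is conservative for congeneric couples
(under-scoring, never over-scoring) and is the reason the conspecific
minimum of exactly 50 is attained by the all-unknown couple.

Weights are configurable (`rubricWeights()`, or the `rubric:` block of a
YAML config file for the CLI) so alternative published rubrics can be
substituted without touching the engine.

## The regional pollinators index (RPI)

Insect-mediated outcrossing needs insects. RPI summarizes pollinator
availability at one-dimensional (latitudinal) resolution: the territory,
18–56 degrees south, is divided into nine sectional blocks (18–19, 20–24,
25–29, 30–34, 35–39, 40–44, 45–49, 50–54, 55–56 °S), each pollinator taxon
carries a latitudinal range, and the frequency $Pf_i$ of block $i$ is the
number of taxa whose range intersects it. Then

$$\mathrm{RPI}_i = \frac{Pf_i}{Pf_{\max}},$$

so the richest block scores exactly 1 and every block scores in $(0, 1]$
(or 0 where no taxon reaches). Counting is per taxon — tables are
deduplicated on (genus, species) — because the registry records presence,
not abundance; RPI is a richness ratio, not a visitation rate.

Numerical conventions, chosen once and applied everywhere:

* **Block closure.** The printed block labels tile the territory only under
  a right-open convention: block $[l, u]$ covers latitudes $[l, u+1)$
  degrees south, the last block covering $[55, 57)$. A boundary latitude
  therefore belongs deterministically to the more northern block
  (`assignBlock(-20)` is in 20–24, since 19.999 °S is still 18–19).
* **Anemophilous override.** For a wind-pollinated donor the pollinator
  index is cancelled and replaced by 1: wind is assumed available
  everywhere at maximum effect. The override is keyed to the *donor's*
  syndrome — it is the donor's pollen being transported — and is reserved
  for strictly anemophilous donors: syndrome `"both"` falls through to the
  entomophilous ratio (the insect pathway is still the one being indexed)
  and the fall-through is noted in the result provenance. `"unknown"`
  likewise uses the ratio, which is the conservative-but-defined choice.
* Diet breadth (polylectic/oligolectic) is stored but not used by default;
  `dietFilter = "polylectic"` restricts counting to broad-diet taxa for
  sensitivity analyses.

An empty pollinator table makes $Pf_{\max} = 0$ and RPI undefined; this is
a degenerate-input error, never silently 0 or 1.

## Species distribution probability (SDP)

SDP answers "is the receptor there?" as a per-cell probability on a raster
(nominally ~1 km² cells; the fixtures use 1° cells for speed), queried at
the user's point by nearest-cell lookup under the floor convention
(half-open $[x, x + \text{cellsize})$ intervals, no interpolation — the
model is per geographic unit, so interpolating across cells would invent
precision). Three provenances:

* **Externally fitted grids** (any ESRI ASCII raster in $[0,1]$) are
  ingested directly — the package does not re-implement a full
  maximum-entropy niche modeler and will happily consume one's output.
* **The built-in Gaussian climate-envelope fitter** (`fitSuitability()`)
  serves desk-scale and testing use. For each climate covariate, the mean
  and standard deviation at the occurrence cells define a Gaussian kernel;
  a cell's score is the product of kernel densities (summed on the log
  scale to avoid underflow), max-normalized. A covariate with zero spread
  degenerates to an indicator of the observed value. The fitter is
  deliberately simple — unimodal, no interactions, no regularization — and
  is deterministic: no background sampling is drawn.
* **Census ratios** for cultivated receptors: within each agricultural
  district, SDP = hectares of the crop / total cultivated hectares, painted
  onto the district-ID raster. Crops are modeled only where farming is
  recorded: cells outside all districts, and districts with zero total
  area, get 0. By construction the shares over all crops sum to 1 in any
  district with complete listings.

Every surface is **max-normalized** (`normalizeGrid()`): the best cell has
probability exactly 1, making SDP a relative suitability, comparable across
species, not an absolute detection probability. Normalization is
idempotent; an all-zero grid is returned unchanged with a warning (there is
nothing to rescale) and an all-nodata grid is an error. A hook for
user-supplied weighting of occurrence probabilities prior to normalization
is deliberately not baked in: callers can transform `gridValues()`
themselves before `normalizeGrid()`.

**Eligibility filter.** Occurrence-based fitting requires at least 30
unique geographic locations per taxon (`filterOccurrences()`, `minRecords`
tunable). "Unique" is operationalized as *distinct occupied cells at the
working resolution*: 35 field records collapsing into 29 cells do not
qualify, which protects the envelope's moment estimates from
pseudo-replicated clusters.

## Modes, classification and reports

A screening query crosses a biological scope with a geographic scenario:

* scope **coexistence** — receptors are the cultivated (incl. GM) species;
  **biodiversity** — receptors are the native plus introduced wild flora.
  GM is a flag on cultivated records, not a third receptor class, and GM
  donors use the same trait values as their conventional counterparts
  unless the registry overrides them.
* scenario **national** — geography is ignored; RPI and SDP are set to 1
  and TOP ranks couples on biology alone; **local** — RPI and SDP are
  evaluated at the query point, so for any couple local TOP ≤ national TOP.

The donor's own record is excluded from its receptor list, with one
exception: in biodiversity scope a record also flagged native or introduced
represents a wild conspecific population and is retained (it is the
highest-risk receptor the method can produce: TOP ≥ 0.5 nationally). In
coexistence scope self-coupling is meaningless and the donor is always
excluded.

TOP is read on the quintile concept scale — Q1 $[0, 0.20]$ *very low*
through Q5 $(0.80, 1]$ *very high* — with upper-inclusive bins, so a value
sitting exactly on a boundary takes the lower label (0.20 is still *very
low*). Reports are sorted by TOP descending with lexicographic receptor
tie-breaks; together with the seeded generators this makes every report
byte-reproducible, and the CLI stamps each output with a provenance header
(package version and seed). `quintileDistribution()` and `genusSummary()`
provide the two standard aggregation views (label shares; per-genus count,
mean and maximum TOP).

## The synthetic-data generator

Real registry, climate and census data are not redistributed with the
package; instead `fixtureConfig()` + the `sim*()` family generate data with
the *statistical structure* the method expects:

* a flora registry with the four category flags, shared genera between the
  cultivated/GM and wild lists (`shared_genus_frac`) so congeneric couples
  exist, injectable conspecific overlaps, ~10% synonym carriers, and
  unknown-trait rates around 10–20%;
* a pollinator assemblage (default 508 taxa) whose range midpoints are
  drawn from a normal distribution centered at 32.5 °S with sd 8 °,
  truncated to 18–56 °S — producing the hump-shaped per-block richness
  profile, peaking in the central blocks, that drives RPI — with
  Hymenoptera-dominant order proportions (438:40:14:14 against Diptera,
  Lepidoptera, Coleoptera) and a ~98% endemic share;
* two climate covariates (a southward-cooling temperature analogue, a
  sinusoidal rainfall analogue) on a 39 × 6 one-degree grid spanning the
  territory;
* virtual-species occurrences sampled proportionally to a *known* Gaussian
  envelope, with the generating surface retained as truth so the fitter can
  be scored against it (the recovery requirement in the tests is Pearson
  $r \ge 0.8$ at $n = 200$ occurrences);
* a census whose per-district crop compositions are Dirichlet-distributed,
  so ratio invariants hold by construction.

All generators run under `set.seed()` with per-generator offsets from one
config seed: identical seeds give byte-identical files across runs. What
the generator does **not** emulate: real taxonomy and synonymy depth,
two-dimensional (longitudinal) pollinator structure, spatially
autocorrelated climate noise, multimodal niches, temporal crop rotation,
and the sheer size of a national flora. Green tests on these fixtures
therefore demonstrate the *mechanics* of the index — contracts, orderings,
invariants, recovery of known truth — not predictive validity on real
landscapes.

Test problem sizes were chosen for tight feedback loops: registries of
50–165 species, assemblages of 30–508 taxa, 100–200 occurrence points and
the 234-cell grid; the full suite runs in a few seconds.

## Degenerate inputs and error taxonomy

All user-facing failures are classed conditions (subclasses of
`TOPscreen_error`): schema violations name the missing column; duplicate
primary names, out-of-territory latitudes, out-of-range factors, ambiguous
synonyms, empty pollinator tables, all-nodata grids, sub-2-cell envelope
fits and invalid CLI flag combinations each carry their own class, so
callers (and the CLI wrapper, which maps them to nonzero exit codes) can
react programmatically rather than parse messages.

## Known limitations

* OP's rubric is a screening heuristic; its weights are defensible but not
  field-calibrated, which is why they are configurable and versioned.
* RPI is latitude-resolved only, and a richness ratio rather than an
  activity measure; two blocks with equal taxon counts but very different
  abundances score identically.
* The envelope fitter is unimodal and assumes covariate independence; for
  real multi-modal ranges an external niche model should supply the grid.
* Census SDP inherits the census's district resolution and its recording
  date; it ignores rotation and mixed cropping within a district.
* TOP is a relative ranking tool on $[0, 1]$; the quintile labels carry no
  calibrated probability of hybridization and must not be read as one.
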