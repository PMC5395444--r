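# TOPscreen

Screening the risk of pollen-mediated gene flow (outcrossing) from a
cultivated or genetically modified (GM) donor species to receptor species —
either other crops (*coexistence* screening) or the native and introduced
wild flora (*biodiversity* screening). The package is aimed at environmental
risk assessors, agronomists and ecologists who need a transparent,
reproducible desk tool for ranking donor–receptor couples before any field
decision.

## The model

For an ordered donor–receptor couple evaluated at a geographic point, the
**total outcrossing potential** is the product of three factors:

```
TOP = (OP / 100) × RPI × SDP          TOP ∈ [0, 1]
```

* **OP** (outcrossing potential, %) summarizes the biological compatibility
  of the couple. It is defined only within a genus (cross-genus couples
  score 0) and is the sum of a flowering-period overlap term (max 20
  points), a pollination-syndrome match (10), a breeding-system factor (10),
  a ploidy match (10), plus a 50-point bonus for conspecific couples — so a
  donor meeting a wild population of its own species never scores below 50%.
* **RPI** (regional pollinators index) is the pollinator richness of the
  query point's sectional latitude block relative to the richest block
  nationally, `RPI_i = Pf_i / Pf_max`, over the nine blocks 18–19, 20–24, …,
  55–56 degrees south. For a wind-pollinated (anemophilous) donor the index
  is cancelled and replaced by 1.
* **SDP** (species distribution probability) is the receptor's probability
  of occurrence in the ~1 km² cell containing the point: a max-normalized
  suitability surface for wild species (fitted here with a Gaussian
  climate-envelope model from occurrence records, 30 unique locations
  minimum), or the district crop-area ratio `hectares(crop) /
  hectares(all crops)` for cultivated species.

TOP values are read on a quintile concept scale: 0–0.20 *very low*,
0.20–0.40 *low*, 0.40–0.60 *medium*, 0.60–0.80 *high*, 0.80–1 *very high*.
In the *national* scenario geography is ignored (RPI = SDP = 1); in the
*local* scenario both are evaluated at a user-supplied latitude/longitude.

## Worked example

```r
library(TOPscreen)
cfg <- fixtureConfig(seed = 42, conspecific_overlaps = "Solanum tuberosum")
flora <- simFlora(cfg)
pollinators <- simPollinators(cfg)

blockTable(blockFrequencies(pollinators))
#>      id min_degS max_degS  Pf        RPI
#> 1 18-19       18       19  31 0.11567164
#> 2 20-24       20       24 132 0.49253731
#> 3 25-29       25       29 216 0.80597015
#> 4 30-34       30       34 268 1.00000000
#> 5 35-39       35       39 229 0.85447761
#> 6 40-44       40       44 159 0.59328358
#> 7 45-49       45       49  76 0.28358209
#> 8 50-54       50       54  24 0.08955224
#> 9 55-56       55       56   4 0.01492537
```

The synthetic pollinator assemblage peaks in the 30–34 °S block (`Pf_max =
268`), which therefore has RPI 1; richness — and with it the index — falls
away toward both ends of the territory.

```r
res <- runQuery("Solanum tuberosum", scope = "biodiversity",
                scenario = "national", flora = flora)
res[, c("receptor", "op_pct", "rpi", "sdp", "top", "label")]
#>            receptor op_pct rpi sdp  top     label
#> 1 Solanum tuberosum     95   1   1 0.95 very high
```

The donor was injected as a conspecific overlap (a record flagged both
cultivated+GM and native), so the screening's top receptor is the wild
population of the same species: OP = 95% (50 conspecific + 20 flowering +
10 syndrome + 5 breeding + 10 ploidy), and in the national scenario TOP =
0.95, labeled *very high*. `computeOP()` exposes the factor breakdown;
`quintileDistribution()` and `genusSummary()` aggregate a full screening
run into the label shares and genus ranking views.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/top.R simulate  --seed 42 --out fixtures/
Rscript inst/cli/top.R build-sdp --occurrences fixtures/occurrences.csv \
    --climate-dir fixtures/ --out fixtures/grids/
Rscript inst/cli/top.R run --donor "Solanum tuberosum" \
    --scope biodiversity --scenario local --lat -33.5 --lon -70.7 \
    --flora fixtures/flora.csv --pollinators fixtures/pollinators.csv \
    --sdp-dir fixtures/grids/ --out results.csv
Rscript inst/cli/top.R report --results results.csv --out report/
```

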