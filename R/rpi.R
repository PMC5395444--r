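#' Sectional latitude blocks
#'
#' The nine sectional latitude blocks used to aggregate pollinator richness:
#' 18-19, 20-24, 25-29, 30-34, 35-39, 40-44, 45-49, 50-54 and 55-56 degrees
#' south. Under the closure convention each block covers the half-open
#' interval `[min_degS, max_degS + 1)` except the last, which covers
#' `[55, 57)`; together they tile 18-57 degrees south without overlap.
#'
#' @return data.frame with columns `id`, `min_degS`, `max_degS` and the
#'   half-open coverage bounds `cov_lo`, `cov_hi`.
#' @export
latBlocks <- function() {
  lo <- c(18, 20, 25, 30, 35, 40, 45, 50, 55)
  hi <- c(19, 24, 29, 34, 39, 44, 49, 54, 56)
  data.frame(id = paste(lo, hi, sep = "-"), min_degS = lo, max_degS = hi,
             cov_lo = lo, cov_hi = c(hi[-9] + 1, 57),
             stringsAsFactors = FALSE)
}

#' Assign a latitude to its sectional block
#'
#' @param lat signed decimal degrees (WGS84; the territory is in the southern
#'   hemisphere so valid latitudes are negative, between -57 exclusive and
#'   -18 inclusive).
#' @return one row of [latBlocks()].
#' @examples
#' assignBlock(-33.5)$id   # "30-34"
#' @export
assignBlock <- function(lat) {
  if (!is.numeric(lat) || length(lat) != 1 || is.na(lat))
    .stop2("validation_error", "lat must be a single number")
  degS <- -lat
  blocks <- latBlocks()
  if (lat > -18 || degS >= 57)
    .stop2("out_of_range_error",
           "latitude %.4f outside the modeled 18-56.99 degS territory", lat)
  i <- findInterval(degS, blocks$cov_lo)
  blocks[i, , drop = FALSE]
}

#' Aggregate pollinator richness into latitude blocks
#'
#' Counts, for each sectional block, the pollinator taxa whose latitudinal
#' range intersects the block's coverage interval. Counting is per taxon
#' (deduplicated on genus + species), not per table row, so duplicated rows
#' do not inflate richness. The block with the highest count sets `PfMax`,
#' the reference denominator of the regional pollinators index.
#'
#' @param db a [PollinatorDB-class]; must be nonempty.
#' @param dietFilter `"all"` (default) or `"polylectic"` to count only
#'   broad-diet taxa.
#' @return a [BlockFrequencies-class].
#' @export
blockFrequencies <- function(db, dietFilter = c("all", "polylectic")) {
  dietFilter <- match.arg(dietFilter)
  rec <- db@records
  if (dietFilter == "polylectic")
    rec <- rec[rec$diet == "polylectic", , drop = FALSE]
  if (!nrow(rec))
    .stop2("degenerate_input_error",
           "empty pollinator table: RPI undefined when PfMax = 0")
  rec <- rec[!duplicated(paste(rec$genus, rec$species)), , drop = FALSE]
  blocks <- latBlocks()
  Pf <- vapply(seq_len(nrow(blocks)), function(i) {
    sum(rec$lat_min_degS < blocks$cov_hi[i] &
        rec$lat_max_degS >= blocks$cov_lo[i])
  }, integer(1))
  new("BlockFrequencies", blocks = blocks, Pf = Pf, PfMax = max(Pf))
}

#' Regional pollinators index at a point
#'
#' RPI for block *i* is the ratio `Pf_i / Pf_max` of that block's pollinator
#' taxon count to the national maximum. For an anemophilous (wind-pollinated)
#' donor the pollinator index is cancelled and replaced by 1, i.e. wind is
#' assumed to carry pollen at maximum effect everywhere. A donor with
#' syndrome `"both"` is treated as entomophilous (the override is reserved
#' for strictly wind-pollinated donors); `"unknown"` likewise falls through
#' to the block ratio.
#'
#' @param point list or data.frame row with elements `lat`, `lon` (signed
#'   decimal degrees, WGS84).
#' @param freqs a [BlockFrequencies-class].
#' @param donorSyndrome one of `"entomophilous"`, `"anemophilous"`, `"both"`,
#'   `"unknown"`.
#' @return a number in \[0, 1\].
#' @examples
#' db <- simPollinators(fixtureConfig(seed = 1, n_pollinators = 50))
#' bf <- blockFrequencies(db)
#' computeRPI(geoPoint(-33.5, -70.7), bf, "entomophilous")
#' computeRPI(geoPoint(-33.5, -70.7), bf, "anemophilous")  # always 1
#' @export
computeRPI <- function(point, freqs, donorSyndrome) {
  donorSyndrome <- match.arg(donorSyndrome, .SYNDROMES)
  if (donorSyndrome == "anemophilous") return(1)
  if (freqs@PfMax == 0L)
    .stop2("degenerate_input_error", "PfMax = 0: RPI undefined")
  blk <- assignBlock(point$lat)
  i <- match(blk$id, freqs@blocks$id)
  freqs@Pf[i] / freqs@PfMax
}

#' Export the block table with frequencies and RPI
#'
#' @param freqs a [BlockFrequencies-class].
#' @return data.frame `id, min_degS, max_degS, Pf, RPI` suitable for CSV
#'   export.
#' @export
blockTable <- function(freqs) {
  data.frame(id = freqs@blocks$id, min_degS = freqs@blocks$min_degS,
             max_degS = freqs@blocks$max_degS, Pf = freqs@Pf,
             RPI = if (freqs@PfMax > 0) freqs@Pf / freqs@PfMax else NA_real_,
             stringsAsFactors = FALSE)
}

#' Construct a geographic point
#'
#' @param lat,lon signed decimal degrees, WGS84 (south and west negative).
#' @return a list with class `GeoPoint`.
#' @export
geoPoint <- function(lat, lon) {
  if (!is.numeric(lat) || !is.numeric(lon) || is.na(lat) || is.na(lon) ||
      abs(lat) > 90 || abs(lon) > 180)
    .stop2("validation_error", "invalid WGS84 coordinates (%s, %s)",
           format(lat), format(lon))
  structure(list(lat = lat, lon = lon), class = "GeoPoint")
}

setMethod("show", "BlockFrequencies", function(object) {
  cat("BlockFrequencies over", nrow(object@blocks), "latitude blocks; PfMax =",
      object@PfMax, "\n")
  print(blockTable(object), row.names = FALSE)
})
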