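#' @import methods
NULL

.CATEGORIES <- c("native", "introduced", "cultivated", "gm")
.USE_CLASSES <- c("horticultural", "ornamental", "forestry", "other", "none")
.SYNDROMES <- c("entomophilous", "anemophilous", "both", "unknown")
.BREEDING <- c("outcrossing", "mixed", "selfing", "unknown")
.DIETS <- c("polylectic", "oligolectic", "unknown")
.ORIGINS <- c("endemic", "introduced")
.TOP_LABELS <- c("very low", "low", "medium", "high", "very high")

#' Flora registry
#'
#' An S4 container for the vascular-flora registry: one row per species with
#' its category flags (native / introduced / cultivated / gm; a species may
#' carry several), status flags, and the biological traits consumed by the
#' outcrossing-potential rubric. A synonym-aware name index maps any accepted
#' synonym to the primary binomial.
#'
#' The `records` slot is a `data.frame` with columns `name`, `genus`,
#' `epithet`, plus list-columns `categories`, `flowering_months` (integer
#' vectors, months 1-12, empty = unknown) and `synonyms`; logical columns
#' `endemic`, `naturalized`, `weedy`; character columns `use_class`,
#' `syndrome`, `breeding_system`; integer column `ploidy` (`NA` = unknown).
#'
#' @slot records data.frame of species records (see Details).
#' @slot nameIndex named character vector mapping normalized names (primary
#'   and synonyms) to primary binomials.
#' @seealso [readFlora()], [resolveSpecies()], [relativesOf()]
#' @exportClass FloraDB
setClass("FloraDB", representation(records = "data.frame",
                                   nameIndex = "character"))

setValidity("FloraDB", function(object) {
  rec <- object@records
  msgs <- character()
  need <- c("name", "genus", "epithet", "categories", "endemic", "naturalized",
            "weedy", "use_class", "syndrome", "breeding_system",
            "flowering_months", "ploidy", "synonyms")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(paste("records is missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$name))
    msgs <- c(msgs, "duplicate primary species names")
  if (nrow(rec)) {
    if (any(!nzchar(rec$genus)))
      msgs <- c(msgs, "empty genus")
    if (any(rec$name != paste(rec$genus, rec$epithet)))
      msgs <- c(msgs, "name must equal 'genus epithet'")
    bad_cat <- !vapply(rec$categories, function(x)
      length(x) > 0 && all(x %in% .CATEGORIES), logical(1))
    if (any(bad_cat))
      msgs <- c(msgs, "invalid category flags")
    bad_fm <- !vapply(rec$flowering_months, function(x)
      all(x %in% 1:12), logical(1))
    if (any(bad_fm))
      msgs <- c(msgs, "flowering months outside 1..12")
    if (!all(rec$syndrome %in% .SYNDROMES))
      msgs <- c(msgs, "invalid pollination syndrome")
    if (!all(rec$breeding_system %in% .BREEDING))
      msgs <- c(msgs, "invalid breeding system")
    if (!all(rec$use_class %in% .USE_CLASSES))
      msgs <- c(msgs, "invalid use class")
    syn <- unlist(rec$synonyms, use.names = FALSE)
    if (any(.normName(syn) %in% .normName(rec$name)))
      msgs <- c(msgs, "a synonym collides with another record's primary name")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Pollinator registry
#'
#' S4 container for the pollinator registry: one row per insect taxon with
#' taxonomy, origin (endemic / introduced), diet breadth (polylectic /
#' oligolectic) and a latitudinal range in positive degrees south. The study
#' territory spans 18-56 degrees south (continental; offshore islands are
#' excluded), so ranges must lie inside that band.
#'
#' @slot records data.frame with columns `order`, `family`, `genus`,
#'   `species`, `vernacular`, `origin`, `diet`, `lat_min_degS`,
#'   `lat_max_degS`.
#' @seealso [readPollinators()], [blockFrequencies()]
#' @exportClass PollinatorDB
setClass("PollinatorDB", representation(records = "data.frame"))

setValidity("PollinatorDB", function(object) {
  rec <- object@records
  need <- c("order", "family", "genus", "species", "vernacular", "origin",
            "diet", "lat_min_degS", "lat_max_degS")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    return(paste("records is missing column(s):", paste(miss, collapse = ", ")))
  msgs <- character()
  if (nrow(rec)) {
    if (!all(rec$origin %in% .ORIGINS))
      msgs <- c(msgs, "origin must be endemic or introduced")
    if (!all(rec$diet %in% .DIETS))
      msgs <- c(msgs, "diet must be polylectic, oligolectic or unknown")
    if (any(rec$lat_min_degS > rec$lat_max_degS))
      msgs <- c(msgs, "lat_min_degS greater than lat_max_degS")
    if (any(rec$lat_min_degS < 18 | rec$lat_max_degS > 56))
      msgs <- c(msgs,
        "latitudinal range outside the 18-56 degrees-south territory")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Georeferenced grids
#'
#' `RasterGrid` is a minimal single-band raster: a numeric matrix in row-major
#' order from the northern edge (row 1 = northernmost), with an ESRI
#' ASCII-style georeference (lower-left corner, square cells, nodata
#' sentinel). `SuitabilityGrid` extends it with the constraint that all
#' non-nodata values lie in \[0, 1\]: it is the species distribution
#' probability (SDP) surface of one species, max-normalized so that the best
#' cell has probability one (see [normalizeGrid()]).
#'
#' @slot values numeric matrix, `NA` for nodata cells.
#' @slot xll,yll numeric, lower-left corner coordinates (degrees).
#' @slot cellsize numeric, cell edge in degrees.
#' @slot nodata numeric, sentinel written on file output.
#' @seealso [readGrid()], [writeGrid()], [sdpAt()]
#' @aliases SuitabilityGrid-class
#' @exportClass RasterGrid
#' @exportClass SuitabilityGrid
setClass("RasterGrid", representation(values = "matrix", xll = "numeric",
                                      yll = "numeric", cellsize = "numeric",
                                      nodata = "numeric"))

setValidity("RasterGrid", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (length(object@cellsize) != 1 || object@cellsize <= 0)
    return("cellsize must be a positive scalar")
  if (length(object@xll) != 1 || length(object@yll) != 1)
    return("xll and yll must be scalars")
  TRUE
})

setClass("SuitabilityGrid", contains = "RasterGrid")

setValidity("SuitabilityGrid", function(object) {
  v <- object@values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    return("suitability values must lie in [0, 1]")
  TRUE
})

#' Per-block pollinator frequencies
#'
#' Pollinator taxon counts aggregated into the nine sectional latitude blocks
#' (18-19, 20-24, ..., 55-56 degrees south). `Pf` holds the taxon count of
#' each block; `PfMax` the largest count, used as the reference denominator of
#' the regional pollinators index RPI_i = Pf_i / Pf_max.
#'
#' @slot blocks data.frame of the nine blocks (`id`, `min_degS`, `max_degS`).
#' @slot Pf integer vector of per-block taxon counts (same order as blocks).
#' @slot PfMax integer, `max(Pf)`.
#' @seealso [blockFrequencies()], [computeRPI()], [latBlocks()]
#' @exportClass BlockFrequencies
setClass("BlockFrequencies", representation(blocks = "data.frame",
                                            Pf = "integer", PfMax = "integer"))

setValidity("BlockFrequencies", function(object) {
  if (nrow(object@blocks) != length(object@Pf))
    return("Pf length must match the block table")
  if (any(object@Pf < 0)) return("Pf counts must be nonnegative")
  if (length(object@Pf) && object@PfMax != max(object@Pf))
    return("PfMax must equal max(Pf)")
  TRUE
})

#' Outcrossing potential score
#'
#' The outcrossing potential (OP) of one ordered donor-receptor couple,
#' expressed as a percentage in \[0, 100\] with a factor-by-factor breakdown.
#' OP is defined only within a genus (cross-genus couples score 0); a
#' conspecific couple receives a 50-point bonus and hence never falls below
#' 50%.
#'
#' @slot value numeric percentage in \[0, 100\].
#' @slot conspecific logical, donor and receptor share the binomial.
#' @slot breakdown named numeric vector of contributed points per factor.
#' @slot rubricVersion character, identifier of the weight set used.
#' @seealso [computeOP()], [rubricWeights()]
#' @exportClass OPScore
setClass("OPScore", representation(value = "numeric", conspecific = "logical",
                                   breakdown = "numeric",
                                   rubricVersion = "character"))

setValidity("OPScore", function(object) {
  if (object@value < 0 || object@value > 100)
    return("OP value must lie in [0, 100]")
  if (object@conspecific && object@value < 50)
    return("conspecific couples must score at least 50")
  TRUE
})
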