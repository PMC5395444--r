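#' Construct an occurrence set
#'
#' @param species species binomial.
#' @param lat,lon numeric vectors of point coordinates (signed decimal
#'   degrees, WGS84).
#' @return a list of class `OccurrenceSet` with elements `species` and
#'   `points` (data.frame `lat`, `lon`).
#' @export
occurrenceSet <- function(species, lat, lon) {
  stopifnot(length(lat) == length(lon))
  structure(list(species = species,
                 points = data.frame(lat = lat, lon = lon)),
            class = "OccurrenceSet")
}

# distinct occupied cells of an occurrence set at a given resolution
.uniqueCells <- function(occ, cellsize, xll = 0, yll = 0) {
  cx <- floor((occ$points$lon - xll) / cellsize)
  cy <- floor((occ$points$lat - yll) / cellsize)
  sum(!duplicated(paste(cx, cy)))
}

#' Eligibility filter on occurrence counts
#'
#' A species qualifies for distribution modeling only with enough spatially
#' distinct evidence: "unique geographic locations" are operationalized as
#' distinct occupied grid cells at the working resolution, and a species is
#' eligible iff it occupies at least `minRecords` of them (default 30).
#'
#' @param occs list of `OccurrenceSet` objects.
#' @param minRecords minimum distinct occupied cells (default 30).
#' @param cellsize working resolution in degrees.
#' @param xll,yll grid origin used to discretize points.
#' @return list with `eligible` and `excluded` (sub-lists of `occs`) and
#'   `counts` (data.frame `species`, `n_points`, `n_cells`, `eligible`).
#' @export
filterOccurrences <- function(occs, minRecords = 30, cellsize = 0.01,
                              xll = 0, yll = 0) {
  if (inherits(occs, "OccurrenceSet")) occs <- list(occs)
  n_cells <- vapply(occs, .uniqueCells, numeric(1), cellsize = cellsize,
                    xll = xll, yll = yll)
  ok <- n_cells >= minRecords
  counts <- data.frame(
    species = vapply(occs, `[[`, character(1), "species"),
    n_points = vapply(occs, function(o) nrow(o$points), integer(1)),
    n_cells = as.integer(n_cells), eligible = ok, stringsAsFactors = FALSE)
  list(eligible = occs[ok], excluded = occs[!ok], counts = counts)
}

#' Gaussian climate-envelope suitability fitter
#'
#' A transparent desk-scale ecological niche model: for each climate
#' covariate the mean and standard deviation at the occurrence cells define a
#' Gaussian kernel, a cell's score is the product of the per-covariate kernel
#' densities (computed on the log scale for stability), and the surface is
#' rescaled with [normalizeGrid()] so its maximum is one. A covariate with
#' zero spread at the occurrences degenerates to an indicator of that value.
#' Deterministic: the fit uses occurrence cells only, no background
#' sampling.
#'
#' @param occs an `OccurrenceSet` (see [occurrenceSet()]); must supply at
#'   least 2 distinct occupied cells.
#' @param climate list of co-registered [RasterGrid-class] covariates.
#' @return a [SuitabilityGrid-class] on the covariates' georeference.
#' @export
fitSuitability <- function(occs, climate) {
  if (!length(climate))
    .stop2("validation_error", "at least one climate covariate is required")
  ref <- climate[[1]]
  for (g in climate[-1])
    if (!identical(dim(g@values), dim(ref@values)) ||
        g@cellsize != ref@cellsize || g@xll != ref@xll || g@yll != ref@yll)
      .stop2("coregistration_error", "climate covariates are not co-registered")
  cells <- lapply(seq_len(nrow(occs$points)), function(i)
    .cellAt(ref, occs$points$lat[i], occs$points$lon[i]))
  cells <- unique(Filter(Negate(is.null), cells))
  if (length(cells) < 2)
    .stop2("degenerate_fit_error",
           "fewer than 2 occurrence cells inside the covariate extent")
  ij <- do.call(rbind, cells)
  logscore <- matrix(0, nrow(ref@values), ncol(ref@values))
  for (g in climate) {
    at_occ <- g@values[ij]
    mu <- mean(at_occ, na.rm = TRUE)
    sd <- stats::sd(at_occ, na.rm = TRUE)
    if (is.na(sd) || sd == 0) {
      logscore <- logscore + ifelse(g@values == mu, 0, -Inf)
    } else {
      logscore <- logscore - 0.5 * ((g@values - mu) / sd)^2
    }
  }
  score <- exp(logscore - max(logscore[is.finite(logscore)], na.rm = TRUE))
  score[is.na(Reduce(`+`, lapply(climate, function(g) g@values)))] <- NA
  normalizeGrid(makeGrid(score, ref@xll, ref@yll, ref@cellsize, ref@nodata))
}

#' Read / write occurrence point sets
#'
#' Long-format CSV with columns `species,lat,lon`; one `OccurrenceSet` per
#' species on read.
#'
#' @param path CSV path.
#' @return `readOccurrences`: named list of `OccurrenceSet` objects.
#' @export
readOccurrences <- function(path) {
  if (!file.exists(path))
    .stop2("io_error", "occurrence file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("species", "lat", "lon"), names(raw))
  if (length(miss))
    .stop2("schema_error", "occurrence CSV is missing column(s): %s",
           paste(miss, collapse = ", "))
  sp <- split(raw, raw$species)
  lapply(sp, function(d) occurrenceSet(d$species[1], d$lat, d$lon))
}

#' @rdname readOccurrences
#' @param occs list of `OccurrenceSet` objects (or a single one).
#' @export
writeOccurrences <- function(occs, path) {
  if (inherits(occs, "OccurrenceSet")) occs <- list(occs)
  tabs <- lapply(occs, function(o)
    data.frame(species = o$species, lat = o$points$lat, lon = o$points$lon))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read a district crop-census table
#'
#' Columns: `district_id,species,hectares`. Hectares must be nonnegative.
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
readCensus <- function(path) {
  if (!file.exists(path))
    .stop2("io_error", "census file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("district_id", "species", "hectares"), names(raw))
  if (length(miss))
    .stop2("schema_error", "census CSV is missing column(s): %s",
           paste(miss, collapse = ", "))
  if (any(raw$hectares < 0))
    .stop2("validation_error", "negative cultivated area in census")
  raw
}

#' Census-ratio occurrence surface for a cultivated species
#'
#' For pollen receptors from the cultivated and GM lists the probability of
#' occurrence in a district is the ratio of the species' cultivated area
#' (hectares) to the district's total cultivated area. Every cell of a
#' district takes that ratio; districts with zero total cultivated area (and
#' cells outside any census district) get 0 -- crops are modeled only where
#' farming is recorded.
#'
#' @param census data.frame as returned by [readCensus()].
#' @param districts a [RasterGrid-class] of integer district IDs (`NA` =
#'   outside all districts).
#' @param species the crop's binomial.
#' @return a [SuitabilityGrid-class]; all-zero (with a warning) if the
#'   species is absent from the census.
#' @export
censusSDP <- function(census, districts, species) {
  ids <- unique(districts@values[!is.na(districts@values)])
  unknown <- setdiff(ids, census$district_id)
  if (length(unknown))
    .stop2("validation_error", "district id(s) in grid but not in census: %s",
           paste(unknown, collapse = ", "))
  tot <- tapply(census$hectares, census$district_id, sum)
  isSp <- .normName(census$species) == .normName(species)
  if (!any(isSp))
    warning(sprintf("species '%s' absent from census: all-zero surface",
                    species))
  own <- tapply(census$hectares[isSp], census$district_id[isSp], sum)
  ratio <- stats::setNames(rep(0, length(tot)), names(tot))
  pos <- tot > 0
  ratio[pos] <- ifelse(names(tot)[pos] %in% names(own),
                       own[match(names(tot)[pos], names(own))] / tot[pos], 0)
  ratio[is.na(ratio)] <- 0
  v <- matrix(0, nrow(districts@values), ncol(districts@values))
  hit <- !is.na(districts@values)
  v[hit] <- ratio[match(as.character(districts@values[hit]), names(ratio))]
  makeGrid(v, districts@xll, districts@yll, districts@cellsize,
           districts@nodata)
}
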