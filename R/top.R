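#' Total outcrossing potential
#'
#' Combines the three factors of an evaluation into the total outcrossing
#' potential `TOP = (OP / 100) * RPI * SDP`. OP enters as a fraction so the
#' result lies on the \[0, 1\] quintile scale; since every factor is at most
#' one, `TOP <= min(OP/100, RPI, SDP)`.
#'
#' @param op_pct outcrossing potential percentage in \[0, 100\].
#' @param rpi regional pollinators index in \[0, 1\].
#' @param sdp species distribution probability in \[0, 1\].
#' @return a number in \[0, 1\]. Vectorized over its arguments.
#' @examples
#' computeTOP(50, 1, 1)       # 0.5: conspecific floor, nationwide scenario
#' computeTOP(80, 0.5, 0.9)   # 0.36
#' @export
computeTOP <- function(op_pct, rpi, sdp) {
  if (any(op_pct < 0 | op_pct > 100, na.rm = FALSE) || anyNA(op_pct))
    .stop2("validation_error", "op_pct must lie in [0, 100]")
  if (any(rpi < 0 | rpi > 1) || anyNA(rpi))
    .stop2("validation_error", "rpi must lie in [0, 1]")
  if (any(sdp < 0 | sdp > 1) || anyNA(sdp))
    .stop2("validation_error", "sdp must lie in [0, 1]")
  (op_pct / 100) * rpi * sdp
}

#' Quintile concept scale for TOP values
#'
#' Classifies TOP on the quintile concept scale: Q1 (0-0.20) very low, Q2
#' (0.20-0.40) low, Q3 (0.40-0.60) medium, Q4 (0.60-0.80) high, Q5 (0.80-1)
#' very high. Bins are upper-inclusive, so a value sitting exactly on a
#' boundary takes the lower label (0.20 is "very low").
#'
#' @param top numeric vector of TOP values in \[0, 1\].
#' @return factor with levels `very low < low < medium < high < very high`.
#' @examples
#' classifyTOP(c(0, 0.2, 0.7, 1))
#' @export
classifyTOP <- function(top) {
  if (any(top < 0 | top > 1) || anyNA(top))
    .stop2("validation_error", "TOP values must lie in [0, 1]")
  cut(top, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1), labels = .TOP_LABELS,
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

#' Run a screening query
#'
#' Evaluates a cultivated or GM donor against a receptor set at one of four
#' screening modes: scope `"coexistence"` (receptors = other cultivated
#' species) or `"biodiversity"` (receptors = native plus introduced wild
#' flora), crossed with scenario `"national"` or `"local"`.
#'
#' In the national scenario the result depends only on the biological
#' compatibility of the couple, regardless of geography: RPI and SDP are both
#' set to 1 and `TOP = OP / 100`. In the local scenario RPI is evaluated at
#' the query point's latitude block (with the anemophilous-donor override,
#' see [computeRPI()]) and SDP is the receptor's distribution probability at
#' the point as given by `sdpProvider`.
#'
#' The donor's own record is excluded from the receptor list, except in
#' biodiversity scope when the record also carries a `native` or
#' `introduced` flag -- a conspecific wild population is then a legitimate
#' receptor (and scores the conspecific OP bonus). Cross-genus receptors
#' (OP = 0) are dropped unless `keepZeros = TRUE`. Results are sorted by TOP
#' descending, ties broken lexicographically by receptor name, so identical
#' inputs give byte-identical reports.
#'
#' @param donor donor species name; must resolve to a record flagged
#'   cultivated and/or gm.
#' @param scope `"coexistence"` or `"biodiversity"`.
#' @param scenario `"national"` or `"local"`.
#' @param flora a [FloraDB-class].
#' @param pollinators a [PollinatorDB-class] (required for local scenario).
#' @param sdpProvider function `(species, point) -> SDP in [0, 1]` (required
#'   for local scenario); `NA` returns are treated as 0 (species not
#'   modeled). See [gridSDPProvider()] and [censusSDPProvider()].
#' @param point a [geoPoint()]; required iff `scenario = "local"`.
#' @param weights a [rubricWeights()] list.
#' @param keepZeros keep cross-genus (TOP = 0) receptors in the report.
#' @param dietFilter passed to [blockFrequencies()].
#' @return data.frame with columns `donor, receptor, genus, op_pct, rpi,
#'   sdp, top, label, scope, scenario, lat, lon, note`.
#' @export
runQuery <- function(donor, scope = c("coexistence", "biodiversity"),
                     scenario = c("national", "local"), flora,
                     pollinators = NULL, sdpProvider = NULL, point = NULL,
                     weights = rubricWeights(), keepZeros = FALSE,
                     dietFilter = "all") {
  scope <- match.arg(scope)
  scenario <- match.arg(scenario)
  don <- resolveSpecies(flora, donor)
  if (!any(c("cultivated", "gm") %in% don$categories[[1]]))
    .stop2("mode_error",
           "donor '%s' is not flagged cultivated or gm", donor)
  if (scenario == "local") {
    if (is.null(point))
      .stop2("usage_error", "local scenario requires a query point")
    if (is.null(pollinators) || is.null(sdpProvider))
      .stop2("usage_error",
             "local scenario requires pollinators and an sdpProvider")
  }
  receptorCats <- if (scope == "coexistence") c("cultivated", "gm")
                  else c("native", "introduced")
  rec <- flora@records
  isReceptor <- vapply(rec$categories, function(x)
    any(x %in% receptorCats), logical(1))
  isDonorRow <- .normName(rec$name) == .normName(don$name)
  wildCats <- intersect(receptorCats, c("native", "introduced"))
  keepSelf <- length(wildCats) > 0 &&
    any(don$categories[[1]] %in% wildCats)
  isReceptor <- isReceptor & (!isDonorRow | keepSelf)
  receptors <- rec[isReceptor, , drop = FALSE]

  if (scenario == "local") {
    freqs <- blockFrequencies(pollinators, dietFilter = dietFilter)
    rpi <- computeRPI(point, freqs, don$syndrome)
  } else rpi <- 1

  n <- nrow(receptors)
  op <- numeric(n); sdp <- numeric(n); note <- character(n)
  for (i in seq_len(n)) {
    ri <- receptors[i, , drop = FALSE]
    op[i] <- if (ri$genus == don$genus) computeOP(don, ri, weights)@value else 0
    if (scenario == "local") {
      s <- sdpProvider(ri$name, point)
      if (is.na(s)) { s <- 0; note[i] <- "no-sdp" }
      sdp[i] <- s
    } else sdp[i] <- 1
  }
  if (don$syndrome == "both" && scenario == "local")
    note <- paste0(note, ifelse(nzchar(note), ";", ""),
                   "donor-syndrome-both-treated-entomophilous")
  top <- computeTOP(op, rep(rpi, n), sdp)
  out <- data.frame(
    donor = rep(don$name, n), receptor = receptors$name,
    genus = receptors$genus, op_pct = op, rpi = rep(rpi, n), sdp = sdp,
    top = top,
    label = as.character(classifyTOP(top)),
    scope = rep(scope, n), scenario = rep(scenario, n),
    lat = rep(if (is.null(point)) NA_real_ else point$lat, n),
    lon = rep(if (is.null(point)) NA_real_ else point$lon, n),
    note = note, stringsAsFactors = FALSE)
  if (!keepZeros) out <- out[out$genus == don$genus, , drop = FALSE]
  out <- out[order(-out$top, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SDP provider backed by per-species suitability grids
#'
#' @param grids named list of [SuitabilityGrid-class] objects, names =
#'   species binomials; or a directory of `.asc` files named
#'   `Genus_epithet.asc`.
#' @return a function `(species, point) -> SDP` returning `NA` for species
#'   without a grid and 0 for points outside a grid's extent.
#' @export
gridSDPProvider <- function(grids) {
  if (is.character(grids)) {
    files <- list.files(grids, pattern = "\\.asc$", full.names = TRUE)
    nms <- gsub("_", " ", sub("\\.asc$", "", basename(files)))
    grids <- stats::setNames(lapply(files, readGrid), nms)
  }
  names(grids) <- .normName(names(grids))
  function(species, point) {
    g <- grids[[.normName(species)]]
    if (is.null(g)) return(NA_real_)
    tryCatch(as.numeric(sdpAt(point, g)),
             out_of_extent_error = function(e) 0)
  }
}

#' SDP provider backed by the crop census
#'
#' @param census data.frame from [readCensus()].
#' @param districts district-ID [RasterGrid-class].
#' @return a function `(species, point) -> SDP`; species absent from the
#'   census get `NA`, points outside all districts get 0.
#' @export
censusSDPProvider <- function(census, districts) {
  cache <- new.env(parent = emptyenv())
  function(species, point) {
    key <- .normName(species)
    if (!any(.normName(census$species) == key)) return(NA_real_)
    if (is.null(cache[[key]]))
      cache[[key]] <- censusSDP(census, districts, species)
    tryCatch(as.numeric(sdpAt(point, cache[[key]])),
             out_of_extent_error = function(e) 0)
  }
}

#' Combine SDP providers with fallback
#'
#' Tries each provider in order and returns the first non-`NA` answer;
#' useful to serve wild receptors from suitability grids and cultivated
#' receptors from the census in one query.
#'
#' @param ... provider functions as returned by [gridSDPProvider()] or
#'   [censusSDPProvider()].
#' @return a provider function.
#' @export
combineSDPProviders <- function(...) {
  providers <- list(...)
  function(species, point) {
    for (p in providers) {
      s <- p(species, point)
      if (!is.na(s)) return(s)
    }
    NA_real_
  }
}

#' Quintile distribution of a screening report
#'
#' @param results data.frame from [runQuery()], or a numeric vector of TOP
#'   values.
#' @return named numeric vector of percentages over the five quintile labels,
#'   summing to 100.
#' @export
quintileDistribution <- function(results) {
  top <- if (is.numeric(results)) results else results$top
  if (!length(top))
    .stop2("degenerate_input_error", "no TOP values to classify")
  tab <- table(classifyTOP(top))
  stats::setNames(100 * as.vector(tab) / sum(tab), names(tab))
}

#' Per-genus summary of a screening report
#'
#' One row per receptor genus with the number of receptor species, the mean
#' and the maximum TOP, sorted by mean TOP descending (the genus-ranking
#' view of a screening run).
#'
#' @param results data.frame from [runQuery()].
#' @return data.frame `genus, n_species, mean_top, max_top`.
#' @export
genusSummary <- function(results) {
  if (!nrow(results))
    return(data.frame(genus = character(), n_species = integer(),
                      mean_top = numeric(), max_top = numeric(),
                      stringsAsFactors = FALSE))
  agg <- split(results$top, results$genus)
  out <- data.frame(genus = names(agg),
                    n_species = vapply(agg, length, integer(1)),
                    mean_top = vapply(agg, mean, numeric(1)),
                    max_top = vapply(agg, max, numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_top, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}
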