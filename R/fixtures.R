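# Seeded synthetic-data generator. Emulates the statistical structure of the
# study datasets (registry composition, the normal-shaped pollinator richness
# profile over latitude, climate covariates, virtual-species occurrences from
# known envelopes, district crop census) so every module is testable with no
# external download. Only structure is emulated, never real taxonomy,
# geography or climate.

# run code under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

.SYLL <- c("al", "ba", "ce", "do", "er", "fi", "go", "hu", "il", "ju", "ka",
           "lo", "mi", "ne", "or", "pa", "qui", "ro", "su", "ta", "ve", "xi")

.latinWords <- function(n, suffix = "a") {
  if (n == 0) return(character(0))
  raw <- vapply(seq_len(n), function(i)
    paste0(paste(sample(.SYLL, 3, replace = TRUE), collapse = ""),
           sample(suffix, 1)), character(1))
  # disambiguate collisions deterministically
  idx <- stats::ave(seq_along(raw), raw, FUN = seq_along)
  ifelse(idx > 1, paste0(raw, idx), raw)
}

#' Configuration for the synthetic-fixture generator
#'
#' Defaults mirror the structure of the study datasets: 508 pollinator taxa
#' with a normal-shaped latitudinal richness profile centered at 32.5 degrees
#' south (sd 8), Hymenoptera-dominant order proportions, a flora registry
#' whose cultivated/GM genera partly overlap the wild genera so within-genus
#' donor-receptor couples exist, a degree-resolution grid spanning the 18-56
#' degS territory, and a handful of census districts.
#'
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param n_native,n_introduced,n_cultivated,n_gm registry counts per
#'   category; GM records are a flagged subset of cultivated (`n_gm <=
#'   n_cultivated`).
#' @param n_pollinators pollinator taxon count (study default 508).
#' @param pollinator_center,pollinator_sd center and spread (degrees south)
#'   of the normal richness profile.
#' @param shared_genus_frac fraction of cultivated/GM genera drawn from the
#'   wild genus pool.
#' @param conspecific_overlaps binomials to inject as single records flagged
#'   both cultivated+gm and native (conspecific donor-receptor coincidence).
#' @param grid_nrows,grid_ncols,grid_xll,grid_yll,grid_cellsize georeference
#'   of all generated rasters.
#' @param n_districts number of census districts (contiguous latitude bands).
#' @param n_covariates number of synthetic climate covariates.
#' @return a list of class `FixtureConfig`.
#' @export
fixtureConfig <- function(seed = 1, n_native = 100, n_introduced = 40,
                          n_cultivated = 25, n_gm = 5, n_pollinators = 508,
                          pollinator_center = 32.5, pollinator_sd = 8,
                          shared_genus_frac = 0.2,
                          conspecific_overlaps = character(),
                          grid_nrows = 39, grid_ncols = 6, grid_xll = -75,
                          grid_yll = -57, grid_cellsize = 1,
                          n_districts = 6, n_covariates = 2) {
  if (n_gm > n_cultivated)
    .stop2("validation_error", "n_gm must not exceed n_cultivated")
  if (any(c(n_native, n_introduced, n_cultivated, n_gm, n_pollinators) < 0))
    .stop2("validation_error", "fixture counts must be nonnegative")
  structure(as.list(environment()), class = "FixtureConfig")
}

#' Generate a synthetic flora registry
#'
#' Wild (native/introduced) species are spread over a genus pool; a
#' configurable fraction of the cultivated/GM genera is drawn from that same
#' pool so congeneric donor-receptor couples exist. GM records are a subset
#' of the cultivated records carrying an extra `gm` flag. Conspecific
#' overlaps listed in the config are injected as single records flagged
#' `cultivated;gm;native`.
#'
#' @param cfg a [fixtureConfig()].
#' @return a [FloraDB-class].
#' @export
simFlora <- function(cfg) .withSeed(cfg$seed + 101L, {
  nWild <- cfg$n_native + cfg$n_introduced
  nGenera <- max(1L, ceiling(nWild / 3))
  wildGenera <- .latinWords(nGenera, suffix = c("us", "um", "ia"))
  substr(wildGenera, 1, 1) <- toupper(substr(wildGenera, 1, 1))
  nCult <- cfg$n_cultivated
  nCultGen <- max(1L, ceiling(nCult / 2))
  nShared <- min(nGenera, round(cfg$shared_genus_frac * nCultGen))
  cultGenera <- c(sample(wildGenera, nShared),
                  { g <- .latinWords(nCultGen - nShared, suffix = c("us", "um"))
                    substr(g, 1, 1) <- toupper(substr(g, 1, 1)); g })

  mkSpecies <- function(n, genera, cats) {
    if (n == 0)
      return(NULL)
    genus <- sample(genera, n, replace = TRUE)
    epithet <- .latinWords(n, suffix = c("a", "is", "um", "ensis"))
    data.frame(genus = genus, epithet = epithet, cat = cats,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(mkSpecies(cfg$n_native, wildGenera, "native"),
               mkSpecies(cfg$n_introduced, wildGenera, "introduced"),
               mkSpecies(nCult, cultGenera, "cultivated"))
  if (is.null(tab))
    return(FloraDB())
  # global uniqueness of binomials
  nm <- paste(tab$genus, tab$epithet)
  idx <- stats::ave(seq_along(nm), nm, FUN = seq_along)
  tab$epithet <- ifelse(idx > 1, paste0(tab$epithet, idx), tab$epithet)
  categories <- as.list(tab$cat)
  cult_rows <- which(tab$cat == "cultivated")
  gm_rows <- if (cfg$n_gm > 0 && length(cult_rows))
    sample(cult_rows, min(cfg$n_gm, length(cult_rows))) else integer(0)
  for (i in gm_rows) categories[[i]] <- c("cultivated", "gm")

  n <- nrow(tab)
  flowering <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.1) return(integer(0))  # unknown
    start <- sample(1:12, 1); len <- sample(2:6, 1)
    sort(unique(((start:(start + len - 1)) - 1) %% 12 + 1))
  })
  syndrome <- sample(.SYNDROMES, n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.1, 0.1))
  breeding <- sample(.BREEDING, n, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1))
  ploidy <- ifelse(stats::runif(n) < 0.15, NA_integer_,
                   sample(c(2L, 4L, 6L), n, replace = TRUE,
                          prob = c(0.6, 0.3, 0.1)))
  # ~10% of species carry one synonym
  synonyms <- lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.1)
      paste(tab$genus[i], .latinWords(1, suffix = "oides"))
    else character(0)
  })
  db <- FloraDB(
    name = paste(tab$genus, tab$epithet), genus = tab$genus,
    epithet = tab$epithet, categories = categories,
    endemic = tab$cat == "native" & stats::runif(n) < 0.4,
    naturalized = tab$cat == "introduced" & stats::runif(n) < 0.5,
    weedy = stats::runif(n) < 0.1,
    use_class = ifelse(tab$cat == "cultivated",
                       sample(c("horticultural", "ornamental", "forestry"),
                              n, replace = TRUE), "none"),
    syndrome = syndrome, breeding_system = breeding,
    flowering_months = flowering, ploidy = ploidy, synonyms = synonyms)
  for (sp in cfg$conspecific_overlaps) db <- .injectConspecific(db, sp)
  db
})

# add (or re-flag) a record carrying cultivated+gm and native together
.injectConspecific <- function(db, binomial) {
  rec <- db@records
  parts <- strsplit(trimws(binomial), "[[:space:]]+")[[1]]
  hit <- .normName(rec$name) == .normName(binomial)
  if (any(hit)) {
    rec$categories[[which(hit)]] <-
      unique(c(rec$categories[[which(hit)]], "cultivated", "gm", "native"))
  } else {
    row <- data.frame(name = binomial, genus = parts[1],
                      epithet = paste(parts[-1], collapse = " "),
                      endemic = FALSE, naturalized = FALSE, weedy = FALSE,
                      use_class = "horticultural", syndrome = "entomophilous",
                      breeding_system = "mixed", ploidy = 4L,
                      stringsAsFactors = FALSE)
    row$categories <- list(c("cultivated", "gm", "native"))
    row$flowering_months <- list(9:12)
    row$synonyms <- list(character(0))
    rec <- rbind(rec, row[, names(rec)])
  }
  FloraDB(name = rec$name, genus = rec$genus, epithet = rec$epithet,
          categories = rec$categories, endemic = rec$endemic,
          naturalized = rec$naturalized, weedy = rec$weedy,
          use_class = rec$use_class, syndrome = rec$syndrome,
          breeding_system = rec$breeding_system,
          flowering_months = rec$flowering_months, ploidy = rec$ploidy,
          synonyms = rec$synonyms)
}

#' Generate a synthetic pollinator assemblage
#'
#' Latitudinal range midpoints are drawn from a normal distribution centered
#' at `pollinator_center` degrees south (default 32.5, sd 8), truncated to
#' the 18-56 degS territory, yielding the hump-shaped per-block richness
#' profile of the study region; orders are sampled with
#' Hymenoptera-dominant proportions (438:40:14:14 Hymenoptera, Diptera,
#' Lepidoptera, Coleoptera).
#'
#' @param cfg a [fixtureConfig()].
#' @return a [PollinatorDB-class].
#' @export
simPollinators <- function(cfg) .withSeed(cfg$seed + 202L, {
  n <- cfg$n_pollinators
  mid <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      m <- stats::rnorm(1, cfg$pollinator_center, cfg$pollinator_sd)
      if (m >= 18 && m <= 56) break
    }
    mid[i] <- m
  }
  half <- stats::runif(n, 0.5, 6)
  lmin <- pmax(18, mid - half)
  lmax <- pmin(56, mid + half)
  orders <- sample(c("Hymenoptera", "Diptera", "Lepidoptera", "Coleoptera"),
                   n, replace = TRUE, prob = c(438, 40, 14, 14))
  genus <- .latinWords(n, suffix = c("us", "a"))
  substr(genus, 1, 1) <- toupper(substr(genus, 1, 1))
  PollinatorDB(data.frame(
    order = orders, family = paste0(orders, "idae"), genus = genus,
    species = .latinWords(n, suffix = c("a", "is")), vernacular = "",
    origin = sample(.ORIGINS, n, replace = TRUE, prob = c(0.98, 0.02)),
    diet = sample(.DIETS, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    lat_min_degS = round(lmin, 3), lat_max_degS = round(lmax, 3),
    stringsAsFactors = FALSE))
})

#' Generate synthetic climate covariates
#'
#' Each covariate is a smooth latitudinal gradient plus seeded noise
#' (temperature-like decreasing southward, precipitation-like sinusoidal),
#' on the config's georeference.
#'
#' @param cfg a [fixtureConfig()].
#' @return list of [RasterGrid-class] covariates.
#' @export
simClimate <- function(cfg) .withSeed(cfg$seed + 303L, {
  nr <- cfg$grid_nrows; nc <- cfg$grid_ncols
  lat_row <- cfg$grid_yll + (nr - seq_len(nr) + 0.5) * cfg$grid_cellsize
  lapply(seq_len(cfg$n_covariates), function(k) {
    base <- if (k %% 2 == 1) 25 + 0.6 * (lat_row + 18)       # temperature-like
            else 500 + 300 * sin((lat_row + 57) / 39 * pi)   # rainfall-like
    v <- matrix(rep(base, nc), nrow = nr) +
      matrix(stats::rnorm(nr * nc, 0, if (k %% 2 == 1) 1 else 30), nrow = nr)
    makeGrid(v, cfg$grid_xll, cfg$grid_yll, cfg$grid_cellsize,
             class = "RasterGrid")
  })
})

#' Gaussian envelope truth surface
#'
#' The generating suitability surface of a virtual species: per-covariate
#' Gaussian kernels multiplied and max-normalized. Retained as truth for
#' recovery tests of [fitSuitability()].
#'
#' @param climate list of co-registered [RasterGrid-class] covariates.
#' @param mu,sigma numeric vectors (one entry per covariate) of envelope
#'   optima and widths.
#' @return a [SuitabilityGrid-class].
#' @export
envelopeSurface <- function(climate, mu, sigma) {
  stopifnot(length(mu) == length(climate), length(sigma) == length(climate))
  ref <- climate[[1]]
  logscore <- matrix(0, nrow(ref@values), ncol(ref@values))
  for (k in seq_along(climate))
    logscore <- logscore - 0.5 * ((climate[[k]]@values - mu[k]) / sigma[k])^2
  normalizeGrid(makeGrid(exp(logscore - max(logscore, na.rm = TRUE)),
                         ref@xll, ref@yll, ref@cellsize, ref@nodata))
}

#' Sample virtual-species occurrences from a known envelope
#'
#' Cells are sampled with probability proportional to the envelope surface;
#' points are placed at cell centers. The generating surface is returned
#' alongside the points so fitted models can be scored against the truth.
#'
#' @param cfg a [fixtureConfig()] (supplies the seed).
#' @param climate covariate list (see [simClimate()]).
#' @param mu,sigma envelope parameters (see [envelopeSurface()]).
#' @param n number of occurrence points.
#' @param species name attached to the occurrence set.
#' @return list with `occurrences` (an `OccurrenceSet`) and `truth` (a
#'   [SuitabilityGrid-class]).
#' @export
simOccurrences <- function(cfg, climate, mu, sigma, n = 200,
                           species = "Virtualis exemplaris") {
  truth <- envelopeSurface(climate, mu, sigma)
  .withSeed(cfg$seed + 404L + as.integer(sum(utf8ToInt(species))), {
    v <- truth@values
    nr <- nrow(v); nc <- ncol(v)
    p <- as.vector(v); p[is.na(p)] <- 0
    cell <- sample.int(nr * nc, n, replace = TRUE, prob = p)
    row <- (cell - 1) %% nr + 1
    col <- (cell - 1) %/% nr + 1
    lat <- truth@yll + (nr - row + 0.5) * truth@cellsize
    lon <- truth@xll + (col - 0.5) * truth@cellsize
    list(occurrences = occurrenceSet(species, lat, lon), truth = truth)
  })
}

#' Generate a synthetic district crop census
#'
#' Districts are contiguous latitude bands of the config grid, identified by
#' integer IDs. Per-district hectares over the supplied crops are drawn from
#' a Dirichlet-distributed composition (so within-district crop ratios sum to
#' one) scaled by a district total.
#'
#' @param cfg a [fixtureConfig()].
#' @param crops character vector of cultivated species names.
#' @return list with `census` (data.frame `district_id,species,hectares`) and
#'   `districts` (district-ID [RasterGrid-class]).
#' @export
simCensus <- function(cfg, crops) .withSeed(cfg$seed + 505L, {
  nr <- cfg$grid_nrows; nc <- cfg$grid_ncols; nd <- cfg$n_districts
  band <- cut(seq_len(nr), nd, labels = FALSE)
  v <- matrix(rep(band, nc), nrow = nr)
  districts <- makeGrid(v, cfg$grid_xll, cfg$grid_yll, cfg$grid_cellsize,
                        class = "RasterGrid")
  rows <- do.call(rbind, lapply(seq_len(nd), function(d) {
    k <- length(crops)
    w <- stats::rgamma(k, shape = 1)
    total <- stats::runif(1, 500, 5000)
    data.frame(district_id = d, species = crops,
               hectares = round(total * w / sum(w), 2),
               stringsAsFactors = FALSE)
  }))
  list(census = rows, districts = districts)
})

#' Write a complete fixture set to disk
#'
#' Runs all generators and writes `flora.csv`, `pollinators.csv`,
#' `climate_<k>.asc`, `occurrences.csv`, `census.csv`, `districts.asc`, the
#' generating envelope surfaces under `truth/`, and a `manifest.yaml`
#' recording the seed and configuration.
#'
#' @param cfg a [fixtureConfig()].
#' @param dir output directory (created if missing).
#' @param n_modeled number of wild species to equip with virtual occurrences.
#' @param n_occ occurrence points per modeled species.
#' @return `dir`, invisibly.
#' @export
simFixtures <- function(cfg, dir, n_modeled = 3, n_occ = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  flora <- simFlora(cfg)
  writeFlora(flora, file.path(dir, "flora.csv"))
  writePollinators(simPollinators(cfg), file.path(dir, "pollinators.csv"))
  climate <- simClimate(cfg)
  for (k in seq_along(climate))
    writeGrid(climate[[k]], file.path(dir, sprintf("climate_%d.asc", k)))

  rec <- records(flora)
  wild <- rec$name[vapply(rec$categories, function(x)
    any(x %in% c("native", "introduced")), logical(1))]
  modeled <- utils::head(sort(wild), n_modeled)
  occs <- list(); truths <- list()
  for (sp in modeled) {
    # envelope optima derived deterministically from the species name
    h <- (sum(utf8ToInt(sp)) %% 7 - 3) / 10
    mu <- vapply(climate, function(g) mean(g@values, na.rm = TRUE) +
                   h * stats::sd(g@values, na.rm = TRUE), 0)
    sigma <- vapply(climate, function(g)
      0.5 * stats::sd(g@values, na.rm = TRUE), 0)
    sim <- simOccurrences(cfg, climate, mu, sigma, n = n_occ, species = sp)
    occs[[sp]] <- sim$occurrences
    writeGrid(sim$truth,
              file.path(dir, "truth", paste0(gsub(" ", "_", sp), ".asc")))
  }
  if (length(occs))
    writeOccurrences(occs, file.path(dir, "occurrences.csv"))
  crops <- rec$name[vapply(rec$categories, function(x)
    "cultivated" %in% x, logical(1))]
  if (length(crops)) {
    cen <- simCensus(cfg, sort(crops))
    utils::write.csv(cen$census, file.path(dir, "census.csv"),
                     row.names = FALSE)
    writeGrid(cen$districts, file.path(dir, "districts.asc"))
  }
  manifest <- c(sprintf("seed: %d", cfg$seed),
                sprintf("n_species: %d", nSpecies(flora)),
                sprintf("n_pollinators: %d", cfg$n_pollinators),
                sprintf("modeled: [%s]", paste(modeled, collapse = ", ")),
                sprintf("generated: TOPscreen %s",
                        as.character(utils::packageVersion("TOPscreen"))))
  writeLines(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
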