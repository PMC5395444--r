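#' Read a flora registry from CSV
#'
#' Parses a flora registry table into a [FloraDB-class] object. The CSV
#' schema is one row per species with columns `name,genus,epithet,categories,
#' endemic,naturalized,weedy,use_class,syndrome,breeding_system,
#' flowering_months,ploidy,synonyms`. `categories` and `synonyms` are
#' semicolon-separated; `flowering_months` accepts ranges (`"9-12"`,
#' wrapping across December) or lists (`"1;2;12"`). Empty trait cells become
#' the explicit `unknown` value (empty month set, `NA` ploidy) -- missing
#' data are never silently defaulted to a biological value.
#'
#' @param path path to the CSV file.
#' @return a [FloraDB-class].
#' @examples
#' db <- simFlora(fixtureConfig(seed = 1, n_native = 5, n_cultivated = 3))
#' f <- tempfile(fileext = ".csv")
#' writeFlora(db, f)
#' db2 <- readFlora(f)
#' nSpecies(db2)
#' @export
readFlora <- function(path) {
  if (!file.exists(path))
    .stop2("io_error", "flora file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        comment.char = "#")
  need <- c("name", "genus", "epithet", "categories", "endemic", "naturalized",
            "weedy", "use_class", "syndrome", "breeding_system",
            "flowering_months", "ploidy", "synonyms")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    .stop2("schema_error", "flora CSV is missing mandatory column(s): %s",
           paste(miss, collapse = ", "))
  FloraDB(
    name = trimws(raw$name),
    genus = trimws(raw$genus),
    epithet = trimws(raw$epithet),
    categories = .splitCell(tolower(raw$categories)),
    endemic = .parseLogical(raw$endemic, "endemic"),
    naturalized = .parseLogical(raw$naturalized, "naturalized"),
    weedy = .parseLogical(raw$weedy, "weedy"),
    use_class = .enumOrUnknown(raw$use_class, .USE_CLASSES, "use_class"),
    syndrome = .enumOrUnknown(raw$syndrome, .SYNDROMES, "syndrome"),
    breeding_system = .enumOrUnknown(raw$breeding_system, .BREEDING,
                                     "breeding_system"),
    flowering_months = .parseMonths(raw$flowering_months),
    ploidy = suppressWarnings(as.integer(raw$ploidy)),
    synonyms = .splitCell(raw$synonyms)
  )
}

#' Construct a FloraDB from vectors
#'
#' Low-level constructor used by [readFlora()] and the fixture generator.
#' `categories`, `flowering_months` and `synonyms` are lists of vectors
#' (one element per species). Duplicate primary names raise a
#' duplicate-record error.
#'
#' @param name,genus,epithet character vectors.
#' @param categories list of character vectors over
#'   `native,introduced,cultivated,gm`.
#' @param endemic,naturalized,weedy logical vectors.
#' @param use_class,syndrome,breeding_system character vectors.
#' @param flowering_months list of integer vectors (subsets of 1:12).
#' @param ploidy integer vector, `NA` = unknown.
#' @param synonyms list of character vectors of accepted synonyms.
#' @return a [FloraDB-class].
#' @export
FloraDB <- function(name = character(), genus = character(),
                    epithet = character(), categories = list(),
                    endemic = logical(), naturalized = logical(),
                    weedy = logical(), use_class = character(),
                    syndrome = character(), breeding_system = character(),
                    flowering_months = list(), ploidy = integer(),
                    synonyms = list()) {
  if (anyDuplicated(.normName(name))) {
    dup <- name[duplicated(.normName(name))]
    .stop2("duplicate_record_error", "duplicate primary species name(s): %s",
           paste(unique(dup), collapse = ", "))
  }
  rec <- data.frame(name = name, genus = genus, epithet = epithet,
                    endemic = endemic, naturalized = naturalized,
                    weedy = weedy, use_class = use_class, syndrome = syndrome,
                    breeding_system = breeding_system, ploidy = ploidy,
                    stringsAsFactors = FALSE)
  rec$categories <- categories
  rec$flowering_months <- flowering_months
  rec$synonyms <- synonyms
  idx <- .buildNameIndex(rec)
  new("FloraDB", records = rec, nameIndex = idx)
}

.buildNameIndex <- function(rec) {
  primary <- .normName(rec$name)
  idx <- stats::setNames(rec$name, primary)
  for (i in seq_len(nrow(rec))) {
    syn <- .normName(rec$synonyms[[i]])
    syn <- setdiff(syn, primary)
    if (length(syn)) {
      clash <- intersect(syn, names(idx))
      # a synonym shared by >=2 records is kept but marked ambiguous
      for (s in clash)
        if (idx[[s]] != rec$name[i]) idx[[s]] <- NA_character_
      fresh <- setdiff(syn, clash)
      idx[fresh] <- rec$name[i]
    }
  }
  idx
}

#' Write a flora registry to CSV
#'
#' Inverse of [readFlora()]: the written file re-reads to a cell-for-cell
#' identical table after normalization.
#'
#' @param db a [FloraDB-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFlora <- function(db, path) {
  rec <- db@records
  out <- data.frame(
    name = rec$name, genus = rec$genus, epithet = rec$epithet,
    categories = vapply(rec$categories, paste, character(1), collapse = ";"),
    endemic = rec$endemic, naturalized = rec$naturalized, weedy = rec$weedy,
    use_class = rec$use_class, syndrome = rec$syndrome,
    breeding_system = rec$breeding_system,
    flowering_months = .formatMonths(rec$flowering_months),
    ploidy = ifelse(is.na(rec$ploidy), "", as.character(rec$ploidy)),
    synonyms = vapply(rec$synonyms, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a pollinator registry from CSV
#'
#' Columns: `order,family,genus,species,vernacular,origin,diet,lat_min_degS,
#' lat_max_degS`. Latitudinal ranges are validated against the 18-56
#' degrees-south continental territory (offshore islands excluded).
#'
#' @param path path to the CSV file.
#' @return a [PollinatorDB-class].
#' @export
readPollinators <- function(path) {
  if (!file.exists(path))
    .stop2("io_error", "pollinator file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        comment.char = "#")
  need <- c("order", "family", "genus", "species", "vernacular", "origin",
            "diet", "lat_min_degS", "lat_max_degS")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    .stop2("schema_error", "pollinator CSV is missing mandatory column(s): %s",
           paste(miss, collapse = ", "))
  lmin <- suppressWarnings(as.numeric(raw$lat_min_degS))
  lmax <- suppressWarnings(as.numeric(raw$lat_max_degS))
  if (anyNA(lmin) || anyNA(lmax))
    .stop2("format_error", "non-numeric latitudinal bound in pollinator CSV")
  PollinatorDB(data.frame(
    order = trimws(raw$order), family = trimws(raw$family),
    genus = trimws(raw$genus), species = trimws(raw$species),
    vernacular = raw$vernacular,
    origin = .enumOrUnknown(raw$origin, .ORIGINS, "origin"),
    diet = .enumOrUnknown(raw$diet, .DIETS, "diet"),
    lat_min_degS = lmin, lat_max_degS = lmax, stringsAsFactors = FALSE))
}

#' Construct a PollinatorDB from a data.frame
#'
#' @param records data.frame with the pollinator schema (see
#'   [PollinatorDB-class]).
#' @return a [PollinatorDB-class]. Ranges violating `18 <= min <= max <= 56`
#'   raise a validation error.
#' @export
PollinatorDB <- function(records) {
  if (nrow(records)) {
    if (any(records$lat_min_degS > records$lat_max_degS))
      .stop2("validation_error",
             "pollinator range with lat_min_degS > lat_max_degS")
    if (any(records$lat_min_degS < 18 | records$lat_max_degS > 56))
      .stop2("validation_error",
             "pollinator range outside 18-56 degrees south")
  }
  new("PollinatorDB", records = records)
}

#' Write a pollinator registry to CSV
#'
#' @param db a [PollinatorDB-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePollinators <- function(db, path) {
  utils::write.csv(db@records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Resolve a species name against the registry
#'
#' Matches `name` (whitespace- and case-normalized) against primary binomials
#' and synonym lists, returning the one-row record of the primary species. A
#' synonym carried by two or more records raises an ambiguity error; an
#' unmatched name raises an unknown-species error. Resolution is idempotent:
#' resolving any synonym gives the same record as resolving the primary name.
#'
#' @param db a [FloraDB-class].
#' @param name binomial string (primary name or synonym).
#' @return a one-row `data.frame` (the species record, list-columns included).
#' @examples
#' db <- simFlora(fixtureConfig(seed = 1, n_native = 5))
#' resolveSpecies(db, speciesNames(db)[1])$genus
#' @export
resolveSpecies <- function(db, name) {
  key <- .normName(name)
  if (!key %in% names(db@nameIndex))
    .stop2("unknown_species_error", "unknown species: '%s'", name)
  primary <- unname(db@nameIndex[[key]])
  if (is.na(primary)) {
    cands <- db@records$name[vapply(db@records$synonyms, function(s)
      key %in% .normName(s), logical(1))]
    .stop2("ambiguity_error",
           "ambiguous synonym '%s' matches several records: %s", name,
           paste(cands, collapse = ", "))
  }
  db@records[.normName(db@records$name) == .normName(primary), , drop = FALSE]
}

#' Congeneric relatives by category
#'
#' All registry records of `genus` whose category flags intersect
#' `categories`, sorted by name. An empty result is valid (e.g. an absent
#' genus).
#'
#' @param db a [FloraDB-class].
#' @param genus genus name.
#' @param categories character vector over
#'   `c("native","introduced","cultivated","gm")`.
#' @return a `data.frame` of matching records (possibly zero rows).
#' @export
relativesOf <- function(db, genus, categories) {
  rec <- db@records
  keep <- rec$genus == genus &
    vapply(rec$categories, function(x) any(x %in% categories), logical(1))
  out <- rec[keep, , drop = FALSE]
  out[order(out$name), , drop = FALSE]
}

#' @describeIn FloraDB-class number of species records.
#' @param db a `FloraDB` or `PollinatorDB`.
#' @export
nSpecies <- function(db) nrow(db@records)

#' @describeIn FloraDB-class primary binomials.
#' @export
speciesNames <- function(db) db@records$name

#' @describeIn FloraDB-class the underlying records `data.frame`.
#' @param x a `FloraDB` or `PollinatorDB`.
#' @export
records <- function(x) x@records

setMethod("show", "FloraDB", function(object) {
  rec <- object@records
  cnt <- vapply(.CATEGORIES, function(cat)
    sum(vapply(rec$categories, function(x) cat %in% x, logical(1))),
    integer(1))
  cat("FloraDB with", nrow(rec), "species records\n")
  cat("  categories:", paste(sprintf("%s=%d", names(cnt), cnt),
                             collapse = ", "), "\n")
  cat("  synonyms indexed:", length(object@nameIndex) - nrow(rec), "\n")
})

setMethod("show", "PollinatorDB", function(object) {
  rec <- object@records
  cat("PollinatorDB with", nrow(rec), "pollinator taxa\n")
  if (nrow(rec)) {
    tab <- sort(table(rec$order), decreasing = TRUE)
    cat("  orders:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
    cat(sprintf("  latitudinal span: %.1f-%.1f degS\n",
                min(rec$lat_min_degS), max(rec$lat_max_degS)))
  }
})
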