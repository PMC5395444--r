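# shared helpers: hand-built species records and small in-code fixtures

# a one-row species record shaped like resolveSpecies() output
makeRecord <- function(genus, epithet, categories = "native",
                       syndrome = "unknown", breeding = "unknown",
                       months = integer(0), ploidy = NA_integer_,
                       synonyms = character(0)) {
  rec <- data.frame(name = paste(genus, epithet), genus = genus,
                    epithet = epithet, endemic = FALSE, naturalized = FALSE,
                    weedy = FALSE, use_class = "none", syndrome = syndrome,
                    breeding_system = breeding, ploidy = ploidy,
                    stringsAsFactors = FALSE)
  rec$categories <- list(categories)
  rec$flowering_months <- list(months)
  rec$synonyms <- list(synonyms)
  rec
}

# FloraDB built from a list of makeRecord() rows
makeFlora <- function(...) {
  rows <- list(...)
  FloraDB(
    name = vapply(rows, function(r) r$name, character(1)),
    genus = vapply(rows, function(r) r$genus, character(1)),
    epithet = vapply(rows, function(r) r$epithet, character(1)),
    categories = lapply(rows, function(r) r$categories[[1]]),
    endemic = vapply(rows, function(r) r$endemic, logical(1)),
    naturalized = vapply(rows, function(r) r$naturalized, logical(1)),
    weedy = vapply(rows, function(r) r$weedy, logical(1)),
    use_class = vapply(rows, function(r) r$use_class, character(1)),
    syndrome = vapply(rows, function(r) r$syndrome, character(1)),
    breeding_system = vapply(rows, function(r) r$breeding_system,
                             character(1)),
    flowering_months = lapply(rows, function(r) r$flowering_months[[1]]),
    ploidy = vapply(rows, function(r) r$ploidy, integer(1)),
    synonyms = lapply(rows, function(r) r$synonyms[[1]]))
}

# a single-taxon pollinator table with the given latitudinal range
makePollinators <- function(lmin, lmax, diet = "polylectic") {
  n <- length(lmin)
  PollinatorDB(data.frame(
    order = rep("Hymenoptera", n), family = rep("Apidae", n),
    genus = paste0("Bombus", seq_len(n), recycle0 = TRUE),
    species = paste0("sp", seq_len(n), recycle0 = TRUE),
    vernacular = rep("", n),
    origin = rep("endemic", n), diet = rep_len(diet, n),
    lat_min_degS = lmin, lat_max_degS = lmax, stringsAsFactors = FALSE))
}

# random trait draw for property-style OP tests
randomTraits <- function() {
  months <- if (runif(1) < 0.2) integer(0) else
    sort(sample(1:12, sample(1:6, 1)))
  list(syndrome = sample(c("entomophilous", "anemophilous", "both",
                           "unknown"), 1),
       breeding = sample(c("outcrossing", "mixed", "selfing", "unknown"), 1),
       months = months,
       ploidy = if (runif(1) < 0.2) NA_integer_ else
         sample(c(2L, 4L, 6L), 1))
}
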