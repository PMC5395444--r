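#' Rubric weights for the outcrossing-potential score
#'
#' The OP percentage is a sum of trait-factor contributions plus a fixed
#' 50-point conspecific bonus. The four non-conspecific factor maxima must
#' sum to 50 so that a fully compatible conspecific couple reaches exactly
#' 100%. Defaults: flowering overlap 20, pollination-syndrome match 10,
#' breeding system 10, ploidy match 10. Weights are configurable so
#' alternative published rubrics can be plugged in.
#'
#' @param flowering_overlap_max,syndrome_match_max,breeding_system_max,ploidy_match_max
#'   nonnegative factor maxima, summing to 50.
#' @param version identifier stored in each [OPScore-class].
#' @return a named list of class `RubricWeights`.
#' @export
rubricWeights <- function(flowering_overlap_max = 20, syndrome_match_max = 10,
                          breeding_system_max = 10, ploidy_match_max = 10,
                          version = "default-1") {
  w <- list(flowering_overlap_max = flowering_overlap_max,
            syndrome_match_max = syndrome_match_max,
            breeding_system_max = breeding_system_max,
            ploidy_match_max = ploidy_match_max,
            conspecific_bonus = 50, version = version)
  if (any(unlist(w[1:4]) < 0))
    .stop2("validation_error", "rubric weights must be nonnegative")
  if (abs(sum(unlist(w[1:4])) - 50) > 1e-9)
    .stop2("validation_error",
           "non-conspecific factor maxima must sum to 50 (got %g)",
           sum(unlist(w[1:4])))
  structure(w, class = "RubricWeights")
}

#' Flowering-period overlap
#'
#' Fraction of the shorter flowering period shared by both species:
#' `|a intersect b| / min(|a|, |b|)`. An empty month set means the flowering
#' period is unknown and scores 0 (conservative: no imputation).
#'
#' @param a,b integer vectors of month indices (subsets of 1:12; possibly
#'   empty).
#' @return a number in \[0, 1\].
#' @examples
#' floweringOverlap(c(9, 10, 11, 12), c(11, 12, 1))  # 2/3
#' @export
floweringOverlap <- function(a, b) {
  stopifnot(all(a %in% 1:12), all(b %in% 1:12))
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / min(length(a), length(b))
}

.syndromeSet <- function(s) {
  switch(s, entomophilous = "entomophilous", anemophilous = "anemophilous",
         both = c("entomophilous", "anemophilous"), character(0))
}

.breedingScore <- function(s) {
  switch(s, outcrossing = 1, mixed = 0.5, selfing = 0.1, 0)
}

#' Outcrossing potential of a donor-receptor couple
#'
#' Scores the biological compatibility of an ordered donor-receptor couple as
#' a percentage. OP is defined only within a genus: cross-genus couples score
#' 0 with an empty breakdown. Within a genus the score is the sum of
#' * conspecific bonus (50) if donor and receptor share the binomial after
#'   synonym resolution -- a conspecific couple therefore never scores below
#'   50%;
#' * flowering overlap ([floweringOverlap()]) times its weight;
#' * syndrome match (full weight iff the pollination syndrome sets intersect,
#'   `"both"` counting as either, `"unknown"` as neither);
#' * breeding-system factor: mean of the per-species scores (outcrossing 1,
#'   mixed 0.5, selfing 0.1, unknown 0) times its weight;
#' * ploidy match (full weight iff ploidy levels are equal and both known).
#'
#' Unknown traits contribute 0 points; the value is clamped to \[0, 100\].
#'
#' @param donor,receptor one-row species records as returned by
#'   [resolveSpecies()] (synonyms already collapsed).
#' @param weights a [rubricWeights()] list.
#' @return an [OPScore-class].
#' @examples
#' db <- simFlora(fixtureConfig(seed = 1, n_native = 10, n_cultivated = 5,
#'                              shared_genus_frac = 1))
#' don <- resolveSpecies(db, speciesNames(db)[1])
#' computeOP(don, don)  # conspecific: >= 50
#' @export
computeOP <- function(donor, receptor, weights = rubricWeights()) {
  if (donor$genus != receptor$genus)
    return(new("OPScore", value = 0, conspecific = FALSE,
               breakdown = stats::setNames(numeric(0), character(0)),
               rubricVersion = weights$version))
  conspecific <- .normName(donor$name) == .normName(receptor$name)
  fo <- floweringOverlap(donor$flowering_months[[1]],
                         receptor$flowering_months[[1]])
  syn <- as.numeric(length(intersect(.syndromeSet(donor$syndrome),
                                     .syndromeSet(receptor$syndrome))) > 0)
  br <- mean(c(.breedingScore(donor$breeding_system),
               .breedingScore(receptor$breeding_system)))
  pl <- as.numeric(!is.na(donor$ploidy) && !is.na(receptor$ploidy) &&
                   donor$ploidy == receptor$ploidy)
  breakdown <- c(
    conspecific = if (conspecific) weights$conspecific_bonus else 0,
    flowering_overlap = fo * weights$flowering_overlap_max,
    syndrome_match = syn * weights$syndrome_match_max,
    breeding_system = br * weights$breeding_system_max,
    ploidy_match = pl * weights$ploidy_match_max)
  new("OPScore", value = min(100, max(0, sum(breakdown))),
      conspecific = conspecific, breakdown = breakdown,
      rubricVersion = weights$version)
}

#' @describeIn OPScore-class the OP percentage.
#' @param x an `OPScore`.
#' @export
opValue <- function(x) x@value

#' @describeIn OPScore-class the per-factor point breakdown.
#' @export
opBreakdown <- function(x) x@breakdown

#' Batch OP evaluation
#'
#' One OP score per ordered donor-receptor pair. Cross-genus pairs
#' short-circuit to 0 without trait evaluation.
#'
#' @param db a [FloraDB-class] used to resolve names.
#' @param donors,receptors character vectors of species names (primary or
#'   synonym).
#' @param weights a [rubricWeights()] list.
#' @return data.frame with columns `donor`, `receptor`, `op_pct`,
#'   `conspecific` (one row per ordered pair, donors varying slowest).
#' @export
opMatrix <- function(db, donors, receptors, weights = rubricWeights()) {
  drec <- lapply(donors, function(n) resolveSpecies(db, n))
  rrec <- lapply(receptors, function(n) resolveSpecies(db, n))
  grid <- expand.grid(r = seq_along(rrec), d = seq_along(drec))
  grid <- grid[order(grid$d, grid$r), ]
  res <- mapply(function(d, r) {
    if (drec[[d]]$genus != rrec[[r]]$genus) c(0, 0)
    else {
      s <- computeOP(drec[[d]], rrec[[r]], weights)
      c(s@value, as.numeric(s@conspecific))
    }
  }, grid$d, grid$r)
  data.frame(donor = vapply(drec, `[[`, character(1), "name")[grid$d],
             receptor = vapply(rrec, `[[`, character(1), "name")[grid$r],
             op_pct = res[1, ], conspecific = as.logical(res[2, ]),
             stringsAsFactors = FALSE, row.names = NULL)
}

setMethod("show", "OPScore", function(object) {
  cat(sprintf("OPScore: %.1f%%%s [rubric %s]\n", object@value,
              if (object@conspecific) " (conspecific)" else "",
              object@rubricVersion))
  if (length(object@breakdown)) {
    for (nm in names(object@breakdown))
      cat(sprintf("  %-18s %6.2f\n", nm, object@breakdown[[nm]]))
  } else cat("  cross-genus couple: outside the rubric's domain\n")
})
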