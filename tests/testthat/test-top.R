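test_that("TOP is the product of its three factors on the [0,1] scale", {
  expect_equal(computeTOP(50, 1, 1), 0.5)
  expect_equal(computeTOP(80, 0.5, 0.9), 0.36)
  expect_equal(computeTOP(0, 1, 1), 0)
  expect_error(computeTOP(120, 1, 1), class = "validation_error")
  expect_error(computeTOP(50, 1.2, 1), class = "validation_error")
  expect_error(computeTOP(50, 1, -0.1), class = "validation_error")
})

test_that("TOP never exceeds its smallest factor", {
  set.seed(17)
  op <- runif(1e4, 0, 100); rpi <- runif(1e4); sdp <- runif(1e4)
  top <- computeTOP(op, rpi, sdp)
  expect_true(all(top <= pmin(op / 100, rpi, sdp) + 1e-12))
  expect_true(all(top >= 0 & top <= 1))
})

test_that("quintile labels use upper-inclusive bins", {
  expect_equal(as.character(classifyTOP(c(0, 0.2, 0.21, 0.4, 0.55, 0.7,
                                          0.8, 0.81, 1))),
               c("very low", "very low", "low", "low", "medium", "high",
                 "high", "very high", "very high"))
  expect_error(classifyTOP(1.2), class = "validation_error")
  expect_error(classifyTOP(-0.1), class = "validation_error")
})

# one fixture registry shared by the query tests
.queryFlora <- function() makeFlora(
  makeRecord("Solanum", "tuberosum", categories = c("cultivated", "gm"),
             syndrome = "entomophilous", breeding = "mixed",
             months = 9:12, ploidy = 4L),
  makeRecord("Solanum", "etuberosum", categories = "native",
             syndrome = "entomophilous", breeding = "outcrossing",
             months = 10:12, ploidy = 4L),
  makeRecord("Solanum", "nigrum", categories = "introduced",
             syndrome = "both", breeding = "selfing",
             months = c(11, 12, 1), ploidy = 2L),
  makeRecord("Hordeum", "vulgare", categories = "cultivated",
             syndrome = "anemophilous", breeding = "selfing",
             months = 10:12, ploidy = 2L),
  makeRecord("Quercus", "robur", categories = "native",
             syndrome = "anemophilous", breeding = "outcrossing",
             months = 4:5, ploidy = 2L))

test_that("query validation rejects bad donors and incomplete local setups", {
  db <- .queryFlora()
  expect_error(runQuery("Quercus robur", "biodiversity", "national", db),
               class = "mode_error")        # donor not cultivated/gm
  expect_error(runQuery("Ficus carica", "biodiversity", "national", db),
               class = "unknown_species_error")
  expect_error(runQuery("Solanum tuberosum", "biodiversity", "local", db),
               class = "usage_error")       # local needs a point
})

test_that("national biodiversity screening ranks congeners biologically", {
  db <- .queryFlora()
  res <- runQuery("Solanum tuberosum", "biodiversity", "national", db)
  expect_equal(res$receptor, c("Solanum etuberosum", "Solanum nigrum"))
  expect_true(all(res$rpi == 1 & res$sdp == 1))
  expect_equal(res$top, res$op_pct / 100)
  # zeros dropped by default, retained under keepZeros
  resz <- runQuery("Solanum tuberosum", "biodiversity", "national", db,
                   keepZeros = TRUE)
  expect_equal(nrow(resz), 3)
  expect_equal(resz$top[resz$receptor == "Quercus robur"], 0)
})

test_that("a conspecific wild population ranks first with TOP >= 0.5", {
  db <- makeFlora(
    makeRecord("Solanum", "tuberosum",
               categories = c("cultivated", "gm", "native"),
               syndrome = "entomophilous", breeding = "mixed",
               months = 9:12, ploidy = 4L),
    makeRecord("Solanum", "etuberosum", categories = "native",
               syndrome = "entomophilous", breeding = "outcrossing",
               months = 10:12, ploidy = 4L))
  res <- runQuery("Solanum tuberosum", "biodiversity", "national", db)
  expect_equal(res$receptor[1], "Solanum tuberosum")
  expect_gte(res$top[1], 0.5)
  expect_true(res$label[1] %in% c("medium", "high", "very high"))
  # the donor's own record is never a coexistence receptor
  resc <- runQuery("Solanum tuberosum", "coexistence", "national", db,
                   keepZeros = TRUE)
  expect_false("Solanum tuberosum" %in% resc$receptor)
})

test_that("coexistence with no congeneric crop yields an empty report", {
  db <- .queryFlora()
  res <- runQuery("Solanum tuberosum", "coexistence", "national", db)
  expect_equal(nrow(res), 0)
})

test_that("local TOP never exceeds the national TOP of the same couple", {
  cfg <- fixtureConfig(seed = 31, n_native = 60, n_introduced = 20,
                       n_cultivated = 15, n_gm = 5, n_pollinators = 120,
                       shared_genus_frac = 1)
  db <- simFlora(cfg)
  pol <- simPollinators(cfg)
  rec <- records(db)
  crops <- rec$name[vapply(rec$categories, function(x)
    "cultivated" %in% x, logical(1))]
  cen <- simCensus(cfg, sort(crops))
  wild <- sort(rec$name[vapply(rec$categories, function(x)
    any(x %in% c("native", "introduced")), logical(1))])
  grids <- lapply(seq_along(wild) %% 5 / 5 + 0.1, function(s)
    makeGrid(matrix(s, cfg$grid_nrows, cfg$grid_ncols), cfg$grid_xll,
             cfg$grid_yll, cfg$grid_cellsize))
  names(grids) <- wild
  prov <- combineSDPProviders(gridSDPProvider(grids),
                              censusSDPProvider(cen$census, cen$districts))
  pt <- geoPoint(-33.5, -72.5)
  found <- 0L
  for (donor in crops) {
    nat <- runQuery(donor, "biodiversity", "national", db, keepZeros = TRUE)
    loc <- runQuery(donor, "biodiversity", "local", db, pollinators = pol,
                    sdpProvider = prov, point = pt, keepZeros = TRUE)
    m <- match(loc$receptor, nat$receptor)
    expect_false(anyNA(m))
    expect_true(all(loc$top <= nat$top[m] + 1e-12))
    found <- found + nrow(loc)
  }
  expect_gt(found, 0)
})

test_that("quintile shares equal a brute-force histogram and sum to 100", {
  expect_equal(unname(quintileDistribution(rep(0, 20))),
               c(100, 0, 0, 0, 0))
  set.seed(13)
  top <- runif(1000)
  q <- quintileDistribution(top)
  expect_equal(sum(q), 100, tolerance = 1e-9)
  # independent tally with explicit upper-inclusive bin logic
  oracle <- c(sum(top <= 0.2), sum(top > 0.2 & top <= 0.4),
              sum(top > 0.4 & top <= 0.6), sum(top > 0.6 & top <= 0.8),
              sum(top > 0.8)) / 10
  expect_equal(unname(q), oracle)
  expect_true(all(abs(q - 20) < 5))  # uniform draw: ~20% per bin
  expect_error(quintileDistribution(numeric(0)),
               class = "degenerate_input_error")
})

test_that("genus summary equals a brute-force group-by", {
  res <- data.frame(
    receptor = c("A a", "A b", "B c", "B d", "C e"),
    genus = c("A", "A", "B", "B", "C"),
    top = c(0.2, 0.4, 0.9, 0.1, 0.5))
  g <- genusSummary(res)
  expect_equal(g$genus, c("B", "C", "A"))       # mean-descending, tie by name
  expect_equal(g$mean_top, c(0.5, 0.5, 0.3))
  expect_equal(g$n_species, c(2L, 1L, 2L))
  expect_equal(g$max_top, c(0.9, 0.5, 0.4))
  expect_equal(nrow(genusSummary(res[0, ])), 0)
})
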