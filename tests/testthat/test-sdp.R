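test_that("ESRI ASCII grids round-trip losslessly", {
  g <- makeGrid(matrix(c(0.1, 0.2, NA, 0.9), 2, 2), xll = -71, yll = -34,
                cellsize = 0.5)
  f <- withr::local_tempfile(fileext = ".asc")
  writeGrid(g, f)
  g2 <- readGrid(f)
  expect_equal(gridValues(g2), gridValues(g))
  expect_equal(g2@xll, -71)
  expect_equal(g2@cellsize, 0.5)
})

test_that("malformed grids are rejected", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "0 1", "0 0"), f)       # header lacks NODATA
  expect_error(readGrid(f), "nodata", class = "format_error")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "0 1 0"), f)
  expect_error(readGrid(f), "expected 4 values", class = "format_error")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "0 1", "0 1.5"), f)
  expect_error(readGrid(f), class = "range_error")   # suitability > 1
  # the same file is fine as an unconstrained raster
  expect_s4_class(readGrid(f, class = "RasterGrid"), "RasterGrid")
})

test_that("normalizeGrid rescales to max 1 and is idempotent", {
  g <- makeGrid(matrix(c(0.1, 0.2, 0.4, 0.3), 2, 2))
  n1 <- normalizeGrid(g)
  expect_equal(max(gridValues(n1)), 1)
  expect_equal(gridValues(n1), gridValues(g) * 2.5)
  expect_equal(gridValues(normalizeGrid(n1)), gridValues(n1))
  expect_warning(z <- normalizeGrid(makeGrid(matrix(0, 2, 2))), "all-zero")
  expect_equal(max(gridValues(z)), 0)
  expect_error(normalizeGrid(makeGrid(matrix(NA_real_, 2, 2))),
               class = "degenerate_input_error")
})

test_that("occurrence eligibility counts distinct cells at resolution", {
  # 30 points in 30 distinct unit cells -> eligible
  a <- occurrenceSet("Eligibilis prima", lat = -(18 + 0:29) - 0.5,
                     lon = rep(-70.5, 30))
  # 35 raw points collapsing to 29 unique cells -> excluded
  b <- occurrenceSet("Collapsa secunda",
                     lat = c(-(18 + 0:28) - 0.5, rep(-20.3, 6)),
                     lon = rep(-70.5, 35))
  flt <- filterOccurrences(list(a, b), minRecords = 30, cellsize = 1)
  expect_equal(flt$counts$n_cells, c(30L, 29L))
  expect_equal(flt$counts$eligible, c(TRUE, FALSE))
  expect_equal(vapply(flt$eligible, `[[`, "", "species"), "Eligibilis prima")
  # counts conserved: eligible and excluded partition the input
  expect_equal(length(flt$eligible) + length(flt$excluded), 2L)
  # identity filter
  expect_length(filterOccurrences(list(a, b), minRecords = 0)$eligible, 2)
})

test_that("the climate-envelope fitter recovers a known generating surface", {
  cfg <- fixtureConfig(seed = 21)
  climate <- simClimate(cfg)
  mu <- vapply(climate, function(g) mean(gridValues(g)), 0)
  sigma <- vapply(climate, function(g) 0.5 * sd(gridValues(g)), 0)
  sim <- simOccurrences(cfg, climate, mu, sigma, n = 200)
  fit <- fitSuitability(sim$occurrences, climate)
  expect_equal(max(gridValues(fit), na.rm = TRUE), 1)
  r <- cor(as.vector(gridValues(fit)), as.vector(gridValues(sim$truth)),
           use = "complete.obs")
  expect_gte(r, 0.8)
  # fitted argmax lies within the truth's 1-sigma envelope region
  amax <- which(gridValues(fit) == 1, arr.ind = TRUE)[1, ]
  z <- vapply(seq_along(climate), function(k)
    abs(gridValues(climate[[k]])[amax[1], amax[2]] - mu[k]) / sigma[k], 0)
  expect_true(all(z <= 1.5))
})

test_that("the fitter handles degenerate and mismatched inputs", {
  flat <- makeGrid(matrix(7, 4, 4), class = "RasterGrid")
  occ <- occurrenceSet("Planta plana", lat = c(0.5, 1.5, 2.5),
                       lon = c(0.5, 1.5, 2.5))
  fit <- fitSuitability(occ, list(flat))  # zero spread -> indicator envelope
  expect_true(all(gridValues(fit) == 1))
  one <- occurrenceSet("Sola cella", lat = 0.5, lon = 0.5)
  expect_error(fitSuitability(one, list(flat)),
               class = "degenerate_fit_error")
  other <- makeGrid(matrix(1, 3, 3), class = "RasterGrid")
  expect_error(fitSuitability(occ, list(flat, other)),
               class = "coregistration_error")
})

test_that("census ratios give the cultivated-area share per district", {
  census <- data.frame(
    district_id = c(1, 1, 1, 2, 3),
    species = c("Vitis vinifera", "Zea mays", "Prunus avium",
                "Vitis vinifera", "Zea mays"),
    hectares = c(30, 60, 30, 80, 0))
  districts <- makeGrid(matrix(c(1, 1, 2, 3), 2, 2), class = "RasterGrid")
  g <- censusSDP(census, districts, "Vitis vinifera")
  v <- gridValues(g)
  expect_equal(v[v == 0.25], c(0.25, 0.25))   # 30 / 120 in district 1
  expect_equal(v[1, 2], 1)                    # single-crop district 2
  expect_equal(v[2, 2], 0)                    # zero-total district 3
  # shares over all crops sum to 1 wherever total area is positive
  tot <- Reduce(`+`, lapply(unique(census$species), function(sp)
    gridValues(censusSDP(census, districts, sp))))
  expect_equal(tot[, 1], c(1, 1))
  expect_equal(tot[1, 2], 1)
  expect_warning(z <- censusSDP(census, districts, "Carica papaya"),
                 "absent")
  expect_true(all(gridValues(z) == 0))
  bad <- makeGrid(matrix(c(1, 9, 2, 3), 2, 2), class = "RasterGrid")
  expect_error(censusSDP(census, bad, "Zea mays"), class = "validation_error")
})

test_that("point lookup uses the floor convention without interpolation", {
  g <- makeGrid(matrix(c(0.73, 0.2, 0.5, 1), 2, 2, byrow = TRUE),
                xll = -71, yll = -34, cellsize = 1)
  # row 1 (north) covers lat [-33, -32); col 1 covers lon [-71, -70)
  expect_equal(sdpAt(geoPoint(-32.5, -70.5), g), 0.73)
  expect_equal(sdpAt(geoPoint(-33.5, -70.2), g), 0.5)
  # a cell-edge point belongs to the cell whose half-open interval starts there
  expect_equal(sdpAt(geoPoint(-33, -70), g), 0.2)
  expect_error(sdpAt(geoPoint(-35, -70.5), g), class = "out_of_extent_error")
  gn <- makeGrid(matrix(c(NA, 0.2, 0.5, 1), 2, 2, byrow = TRUE),
                 xll = -71, yll = -34, cellsize = 1)
  v <- sdpAt(geoPoint(-32.5, -70.5), gn)
  expect_equal(as.numeric(v), 0)
  expect_equal(attr(v, "note"), "nodata")
})

test_that("occurrence CSVs round-trip by species", {
  occs <- list(occurrenceSet("Alpha a", -30.5, -70.5),
               occurrenceSet("Beta b", c(-31.5, -32.5), c(-70.5, -70.5)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeOccurrences(occs, f)
  back <- readOccurrences(f)
  expect_setequal(names(back), c("Alpha a", "Beta b"))
  expect_equal(nrow(back[["Beta b"]]$points), 2)
})
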