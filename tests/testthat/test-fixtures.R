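test_that("generators are byte-identical under a fixed seed", {
  cfg <- fixtureConfig(seed = 42, n_native = 30, n_introduced = 10,
                       n_cultivated = 8, n_gm = 2, n_pollinators = 60)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simFixtures(cfg, d1, n_modeled = 2, n_occ = 60)
  simFixtures(cfg, d2, n_modeled = 2, n_occ = 60)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed changes the registry
  other <- simFlora(fixtureConfig(seed = 43, n_native = 30))
  expect_false(identical(speciesNames(other),
                         speciesNames(simFlora(cfg))))
})

test_that("the flora generator honors counts, GM subset and overlaps", {
  cfg <- fixtureConfig(seed = 5, n_native = 40, n_introduced = 15,
                       n_cultivated = 12, n_gm = 4, shared_genus_frac = 0.5,
                       conspecific_overlaps = "Solanum tuberosum")
  db <- simFlora(cfg)
  rec <- records(db)
  has <- function(cat) vapply(rec$categories, function(x) cat %in% x,
                              logical(1))
  expect_equal(sum(has("native")), 41)  # 40 + injected overlap record
  expect_equal(sum(has("introduced")), 15)
  expect_equal(sum(has("cultivated")), 13)
  expect_equal(sum(has("gm")), 5)
  # gm is a subset of cultivated
  expect_true(all(has("cultivated")[has("gm")]))
  # the conspecific overlap is one record flagged on both sides
  st <- resolveSpecies(db, "Solanum tuberosum")
  expect_true(all(c("cultivated", "gm", "native") %in% st$categories[[1]]))
  # generated registries satisfy the class validator and round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  writeFlora(db, f)
  expect_equal(records(readFlora(f)), rec)
  # zero counts give an empty, header-only registry
  empty <- simFlora(fixtureConfig(seed = 1, n_native = 0, n_introduced = 0,
                                  n_cultivated = 0, n_gm = 0))
  expect_equal(nSpecies(empty), 0)
  writeFlora(empty, f)
  expect_equal(length(readLines(f)), 1)
})

test_that("pollinator assemblages are Hymenoptera-dominant and in range", {
  cfg <- fixtureConfig(seed = 8)
  db <- simPollinators(cfg)
  rec <- records(db)
  expect_equal(nrow(rec), 508)
  frac <- mean(rec$order == "Hymenoptera")
  expect_gt(frac, 0.80)   # target proportion 438/506
  expect_lt(frac, 0.92)
  expect_true(all(rec$lat_min_degS >= 18 & rec$lat_max_degS <= 56))
  expect_true(all(rec$lat_min_degS <= rec$lat_max_degS))
  # a zero-spread profile concentrates richness in one block with RPI 1
  tight <- simPollinators(fixtureConfig(seed = 8, n_pollinators = 30,
                                        pollinator_sd = 1e-9))
  tab <- blockTable(blockFrequencies(tight))
  expect_equal(tab$Pf[tab$id == "30-34"], 30L)
  expect_equal(tab$RPI[tab$id == "30-34"], 1)
})

test_that("census compositions are Dirichlet: ratios sum to one", {
  cfg <- fixtureConfig(seed = 12, n_districts = 4)
  cen <- simCensus(cfg, c("Zea mays", "Vitis vinifera", "Prunus avium"))
  sums <- tapply(cen$census$hectares, cen$census$district_id, sum)
  for (d in names(sums)) {
    share <- cen$census$hectares[cen$census$district_id == d] / sums[[d]]
    expect_equal(sum(share), 1)
  }
  expect_setequal(unique(as.vector(gridValues(cen$districts))), 1:4)
})

test_that("virtual occurrences respect the envelope and the count filter", {
  cfg <- fixtureConfig(seed = 33)
  climate <- simClimate(cfg)
  expect_length(climate, 2)
  mu <- vapply(climate, function(g) mean(gridValues(g)), 0)
  sigma <- vapply(climate, function(g) 0.5 * sd(gridValues(g)), 0)
  sim <- simOccurrences(cfg, climate, mu, sigma, n = 200)
  expect_equal(nrow(sim$occurrences$points), 200)
  expect_equal(max(gridValues(sim$truth), na.rm = TRUE), 1)
  # by construction 200 points in a small grid pass the 30-cell filter
  flt <- filterOccurrences(sim$occurrences, minRecords = 30,
                           cellsize = cfg$grid_cellsize, xll = cfg$grid_xll,
                           yll = cfg$grid_yll)
  expect_true(flt$counts$eligible)
  # occurrences fall where the envelope is favorable: mean truth value at
  # occupied cells beats the grid average
  at <- vapply(seq_len(200), function(i)
    sdpAt(geoPoint(sim$occurrences$points$lat[i],
                   sim$occurrences$points$lon[i]), sim$truth), 0)
  expect_gt(mean(at), mean(gridValues(sim$truth), na.rm = TRUE))
})

test_that("fixture configs validate their counts", {
  expect_error(fixtureConfig(n_gm = 10, n_cultivated = 5),
               class = "validation_error")
  expect_error(fixtureConfig(n_native = -1), class = "validation_error")
})
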