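test_that("degenerate zero-rate configuration yields all-zero wells", {
  cfg <- simConfig(nChemicals = 4, baselineGfpRate = 0, nActive = 0,
                   deadRateParams = list(shape1 = 0, shape2 = 30,
                                         edgeShift = 0),
                   ectopicRate = 0, seed = 42)
  wells <- simulateScreen(cfg)
  expect_equal(nrow(wells), 4 * 4 * 4 * 2)
  expect_true(all(wells$n_gfp_pos == 0))
  expect_true(all(wells$n_dead == 0))
  expect_false(any(wells$ectopic))
})

test_that("a single seed fully determines all three tables", {
  cfg <- simConfig(nChemicals = 6, seed = 99)
  expect_identical(simulateScreen(cfg), simulateScreen(cfg))
  expect_identical(simulateLethality(cfg), simulateLethality(cfg))
  expect_identical(simulateAssays(cfg), simulateAssays(cfg))
  cfg2 <- simConfig(nChemicals = 6, seed = 100)
  expect_false(identical(simulateScreen(cfg), simulateScreen(cfg2)))
})

test_that("control wells realize the stated baseline GFP+ rate", {
  # 10,000 control wells at 100 worms and rate 0.002: mean GFP+ worms per
  # well must fall within 3 standard errors of 0.2
  cfg <- simConfig(nChemicals = 1, concentrations = 100,
                   nBioRepeats = 100, nTechReplicates = 100,
                   nActive = 0,
                   deadRateParams = list(shape1 = 0, shape2 = 30,
                                         edgeShift = 0),
                   ectopicRate = 0, seed = 7)
  wells <- simulateScreen(cfg)
  expect_equal(nrow(wells), 10000)
  se <- sqrt(100 * 0.002 * 0.998) / sqrt(10000)
  expect_lt(abs(mean(wells$n_gfp_pos) - 0.2), 3 * se)
})

test_that("well count invariants hold across seeds", {
  for (s in 1:5) {
    wells <- simulateScreen(simConfig(nChemicals = 10, seed = s,
                                      deadRateParams = list(
                                        shape1 = 1.5, shape2 = 10,
                                        edgeShift = 0.05)))
    expect_true(all(wells$n_dead >= 0 & wells$n_dead <= wells$n_total))
    expect_true(all(wells$n_gfp_pos >= 0 &
                      wells$n_gfp_pos <= wells$n_total - wells$n_dead))
  }
})

test_that("the two plate layouts place a chemical at different positions", {
  wells <- simulateScreen(simConfig(nChemicals = 10, seed = 1))
  one <- wells[wells$chemical_id == "chem003" & wells$concentration == 30, ]
  posA <- unique(one$well_position[one$tech_replicate == 1])
  posB <- unique(one$well_position[one$tech_replicate == 2])
  expect_length(posA, 1)
  expect_length(posB, 1)
  expect_false(posA == posB)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simConfig(nChemicals = 3, ectopicRate = 1.5), "ectopicRate")
  expect_error(simConfig(nChemicals = 3, concentrations = c(10, 10)),
               "concentrations")
  expect_error(simConfig(nChemicals = 3, wormsPerWell = 0), "wormsPerWell")
  expect_error(simConfig(nChemicals = 3, embryosPerPlate = 0),
               "embryosPerPlate")
  expect_error(simConfig(nChemicals = 3, baselineGfpRate = -0.1),
               "baselineGfpRate")
  expect_error(simConfig(nChemicals = 3,
                         assayParams = list(familyNames = character())),
               "familyNames")
})

test_that("lethality generator matches its truth parameters", {
  cfg0 <- simConfig(nChemicals = 3, seed = 5,
                    lethalityTruth = c(DMSO = 0, chem001 = 0,
                                      chem002 = 0, chem003 = 0))
  plates <- simulateLethality(cfg0)
  expect_equal(plates$n_hatched, plates$n_embryos)
  expect_equal(sum(plates$chemical_id == "DMSO"), 9)

  # 20% lethality, 300 plates: mean lethality within 3 SE of 0.20
  cfg2 <- simConfig(nChemicals = 1, seed = 11,
                    lethalityTruth = c(DMSO = 0.2, chem001 = 0.2),
                    nLethalityExperiments = 30L,
                    platesPerExperiment = 10L)
  plates2 <- simulateLethality(cfg2, chemicals = "chem001")
  frac <- plateLethality(plates2)
  se <- sqrt(0.2 * 0.8 / 100) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.20), 3 * se)

  expect_error(simulateLethality(cfg2, chemicals = "nope"),
               "lethalityTruth")
})

test_that("assay generator honours hit-rate and family settings", {
  cfg <- simConfig(nChemicals = 4, seed = 3,
                   assayParams = list(hitRate = 0))
  assays <- simulateAssays(cfg)
  expect_true(all(!assays$hit_call))
  bio <- bioactivitySummary(assays)
  expect_true(all(bio$bioactivity_ratio == 0))
  expect_true(all(is.na(assays$ac50_uM)))

  # family frequencies set to the published marginals: the largest
  # family's observed count lies within 3 binomial SE of expectation
  fam <- publishedFamilyCounts()
  w <- fam$count_bottom + fam$count_top
  cfg2 <- simConfig(nChemicals = 10, seed = 8,
                    assayParams = list(hitRate = 1,
                                       nAssaysRange = c(1000L, 1000L),
                                       familyNames = fam$family,
                                       familyWeights = w))
  assays2 <- simulateAssays(cfg2)
  n <- nrow(assays2)
  p <- w[fam$family == "Cell cycle"] / sum(w)
  obs <- sum(assays2$intended_target_family == "Cell cycle")
  expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("configuration JSON round-trips to identical simulations", {
  cfg <- simConfig(nChemicals = 5, seed = 21)
  path <- tempfile(fileext = ".json")
  writeSimConfig(cfg, path)
  cfg2 <- readSimConfig(path)
  expect_identical(simulateScreen(cfg), simulateScreen(cfg2))
  expect_identical(simulateAssays(cfg), simulateAssays(cfg2))
})

test_that("writeSimTables emits the three CSVs plus provenance", {
  dir <- file.path(tempdir(), "simtab")
  paths <- writeSimTables(simConfig(nChemicals = 3, seed = 2), dir)
  expect_true(all(file.exists(paths)))
  prov <- jsonlite::read_json(paths[["provenance"]])
  expect_equal(prov$seed, 2)
  expect_match(prov$config_hash, "^[0-9a-f]{8}$")
})
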