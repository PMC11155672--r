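makeWell <- function(n_dead = 0, ectopic = FALSE, n_gfp = 2,
                     n_total = 100, chem = "a", conc = 100) {
  data.frame(chemical_id = chem, concentration = conc, bio_repeat = 1L,
             tech_replicate = 1L, plate_id = "P1", well_position = "B02",
             n_total = n_total, n_dead = n_dead, n_gfp_pos = n_gfp,
             ectopic = ectopic, stringsAsFactors = FALSE)
}

test_that("qcFilter applies the >10% dead and ectopic rules", {
  wells <- rbind(makeWell(n_dead = 15),               # excluded: dead
                 makeWell(n_dead = 0),                # kept
                 makeWell(n_dead = 5, ectopic = TRUE),# excluded: ectopic
                 makeWell(n_dead = 10),               # kept: exactly 10%
                 makeWell(n_dead = 11))               # excluded: dead
  res <- qcFilter(wells)
  expect_equal(nrow(res$kept), 2)
  expect_equal(res$excluded$reason, c("dead_fraction", "ectopic",
                                      "dead_fraction"))
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(wells))
})

test_that("qcFilter rejects empty and invalid inputs", {
  expect_error(qcFilter(makeWell()[0, ]), "non-empty")
  expect_error(qcFilter(makeWell(n_total = 0, n_gfp = 0)), "n_total")
})

test_that("wellRatio returns GFP+ worms over total worms", {
  expect_equal(wellRatio(makeWell(n_gfp = 5)), 0.05)
  expect_equal(wellRatio(makeWell(n_gfp = 0)), 0)
  expect_error(wellRatio(makeWell(n_gfp = 101)), "n_gfp_pos")
  expect_error(wellRatio(makeWell(n_total = 0)), "n_total")
})

test_that("summarizeScreen averages technical then biological replicates", {
  # one repeat, duplicates 0.02 and 0.04 -> x = 0.03
  w1 <- rbind(makeWell(n_gfp = 2), makeWell(n_gfp = 4))
  w1$tech_replicate <- 1:2
  expect_equal(summarizeScreen(w1)$x, 0.03)
  # two repeats with repeat means 0.0 and 0.1 -> x = 0.05
  w2 <- rbind(makeWell(n_gfp = 0), makeWell(n_gfp = 10))
  w2$bio_repeat <- 1:2
  s2 <- summarizeScreen(w2)
  expect_equal(s2$x, 0.05)
  expect_equal(s2$n_repeats_used, 2)
  # unbalanced design: repeat means first, then unweighted repeat average
  w3 <- rbind(makeWell(n_gfp = 2), makeWell(n_gfp = 4), makeWell(n_gfp = 9))
  w3$tech_replicate <- c(1L, 2L, 1L)
  w3$bio_repeat <- c(1L, 1L, 2L)
  expect_equal(summarizeScreen(w3)$x, (0.03 + 0.09) / 2)
})

test_that("a fully excluded chemical-concentration pair becomes NDA", {
  wells <- do.call(rbind, lapply(1:4, function(i) {
    ch <- paste0("c", i)
    rbind(makeWell(chem = ch, conc = 30, n_gfp = i),
          makeWell(chem = ch, conc = 50, n_gfp = 2 * i))
  }))
  wells$ectopic[wells$chemical_id == "c3" & wells$concentration == 50] <- TRUE
  qc <- qcFilter(wells)
  zmat <- computeZScores(summarizeScreen(qc$kept),
                         tested = unique(wells[, c("chemical_id",
                                                   "concentration")]))
  st <- statusMatrix(zmat)
  expect_equal(st["c3", "50"], "NDA")
  expect_equal(st["c3", "30"], "OK")
  expect_true(is.na(zMatrix(zmat)["c3", "50"]))
})

test_that("computeZScores fixes the sigma convention on {0.1, 0.2, 0.3}", {
  s <- data.frame(chemical_id = c("a", "b", "c"), concentration = 10,
                  x = c(0.1, 0.2, 0.3), n_repeats_used = 4L)
  zs <- computeZScores(s)
  expect_equal(unname(zMatrix(zs)[, 1]), c(-1, 0, 1))
  expect_equal(concStats(zs)$mu, 0.2)
  expect_equal(concStats(zs)$sigma, 0.1)
  zp <- computeZScores(s, sigmaConvention = "population")
  expect_equal(unname(zMatrix(zp)[, 1]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
})

test_that("degenerate Z-score groups raise errors", {
  s0 <- data.frame(chemical_id = c("a", "b", "c"), concentration = 10,
                   x = c(0.2, 0.2, 0.2), n_repeats_used = 1L)
  expect_error(computeZScores(s0), "zero standard deviation")
  s1 <- data.frame(chemical_id = c("a", "b"), concentration = 10,
                   x = c(0.1, 0.2), n_repeats_used = 1L)
  expect_error(computeZScores(s1), "fewer than 3 chemicals")
})

test_that("Z-normalization identity holds on random inputs", {
  set.seed(404)
  for (i in 1:10) {
    s <- expand.grid(chemical_id = sprintf("c%02d", 1:20),
                     concentration = c(10, 30, 100),
                     stringsAsFactors = FALSE)
    s$x <- runif(nrow(s), 0, 0.2)
    s$n_repeats_used <- 4L
    conv <- if (i %% 2) "sample" else "population"
    zs <- computeZScores(s, sigmaConvention = conv)
    z <- zMatrix(zs)
    for (j in seq_len(ncol(z))) {
      v <- z[, j]
      expect_lt(abs(mean(v)), 1e-9)
      sdv <- if (conv == "population") sqrt(mean((v - mean(v))^2)) else sd(v)
      expect_lt(abs(sdv - 1), 1e-9)
    }
    expect_true(validObject(zs))
  }
})

test_that("classification reproduces published example rows", {
  z <- rbind(diazinon = c(NA, 0.857304437, NA, 1.416176111),
             monobenzyl = c(-0.384659645, -0.081544854, -0.425217575,
                            -0.614814203),
             zeros = c(0, 0, 0, 0),
             tie = c(0.2, 1, 0.5, NA))
  cls <- classifyChemicals(z)
  expect_equal(cls$label,
               c("high", "low", "low", "unclassified"))
  expect_equal(cls$max_z[1], 1.416176111)
  expect_equal(cls$n_concs_above_threshold[1], 1)
  expect_true(all(table(cls$label) >= 0))  # labels partition chemicals
  expect_equal(sum(table(cls$label)), nrow(z))
})

test_that("all-missing rows are unclassified with a warning", {
  z <- rbind(a = c(1.5, 0.2), b = c(NA_real_, NA_real_))
  expect_warning(cls <- classifyChemicals(z), "unclassified")
  expect_equal(cls$label, c("high", "unclassified"))
  expect_true(is.na(cls$max_z[2]))
})

test_that("countAbove counts multi-concentration exceedances", {
  z <- rbind(a = c(2, 3, 0.5, 1.5), b = c(0, 1.2, 0, 0),
             c = c(NA, 1.1, NA, 1.01), d = c(0, 0, 0, 0))
  expect_equal(countAbove(z, 1, 1), 3)
  expect_equal(countAbove(z, 1, 2), 2)
  expect_equal(countAbove(z, 1, 3), 1)
  expect_equal(countAbove(z, Inf, 1), 0)
})

test_that("pipeline matches a spreadsheet-style recomputation", {
  wells <- tinyWells()
  for (conv in c("sample", "population")) {
    zs <- computeZScores(summarizeScreen(wells), sigmaConvention = conv)
    oracle <- tinyOracle(wells, sigma = conv)
    expect_equal(xMatrix(zs), oracle$x, tolerance = 1e-12)
    expect_equal(zMatrix(zs), oracle$z, tolerance = 1e-12)
  }
  cls <- classifyChemicals(computeZScores(summarizeScreen(wells)))
  oz <- tinyOracle(wells)$z
  expect_equal(cls$label,
               unname(ifelse(apply(oz, 1, max) > 1, "high", "low")))
})

test_that("raising a chemical's GFP+ counts never lowers its Z-score", {
  # holds whenever z^2 <= n-1; with 20 chemicals and moderate effects the
  # condition is comfortably met
  set.seed(11)
  base <- expand.grid(chemical_id = sprintf("c%02d", 1:20),
                      concentration = 30, bio_repeat = 1:2,
                      tech_replicate = 1:2, stringsAsFactors = FALSE)
  base$plate_id <- "P1"; base$well_position <- "A01"
  base$n_total <- 100L; base$n_dead <- 0L
  base$n_gfp_pos <- rbinom(nrow(base), 100, 0.02)
  base$ectopic <- FALSE
  target <- "c07"
  zprev <- -Inf
  for (bump in c(0L, 2L, 5L, 10L, 20L)) {
    w <- base
    w$n_gfp_pos[w$chemical_id == target] <-
      pmin(100L, w$n_gfp_pos[w$chemical_id == target] + bump)
    z <- zMatrix(computeZScores(summarizeScreen(w)))[target, "30"]
    expect_gte(z, zprev)
    zprev <- z
  }
})

test_that("Z-score matrices round-trip through CSV with NT/NDA markers", {
  zmat <- publishedZScores()
  path <- tempfile(fileext = ".csv")
  writeZScoreMatrix(zmat, path)
  back <- readZScoreMatrix(path)
  expect_equal(statusMatrix(back), statusMatrix(zmat))
  expect_equal(zMatrix(back), zMatrix(zmat), tolerance = 1e-7)
})
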